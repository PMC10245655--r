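category	terms
Brain	brain, nerve, microglia, hippocampus
Digestive	digestive, gut, gutendoderm, intestine, colon, ileum
Development	development, gastrulation, embryo
Lung	lung, airway
Eye	eye, retina
Endothelium	endothelium
Muscle	muscle
Hair follicle	hairfollicle
Kidney	kidney
Immune	immune, monocytes, nk, tcell, pbmc
Prostate	prostate
Blood	blood, heme, fetalblood
Adipocyte	adipocyte
Heart	heart, aorta
Thymus	thymus
Pancreas	pancreas, islets, pancreasductal
Liver	liver
Testis	testis
Synovial fibroblast	synovialfibroblast
Bladder	bladder
Placenta	placenta
Bone marrow	bonemarrow
CSF	csf
Lymph nodes	lymphnodes
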