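gene	chrom	informative_1	informative_2	noise_1	noise_2	noise_3
gene0001	1	0.49435261264641617	0.92325566121401115	-0.36723464274097534	1.5127070098049282	1.2009653755984941
gene0002	2	-1.7996474882946356	-0.61138013563960514	0.18523056486560932	0.25792143753203084	1.0447510871677252
gene0003	3	0.055057242728962452	0.83321849505799372	0.58182372736550669	0.088440229159586353	-1.003208646839848
gene0004	4	1.3629028905786593	-0.26137175536568563	1.3997368272926782	-0.12089653753908947	1.8484819016727465
gene0005	5	1.8070594914582654	-0.92335917506080667	-0.72729205947446507	-1.1943288951605282	-0.66677340875781721
gene0006	6	-0.41828310643936922	0.30399474965685452	1.3025426320441438	0.61199689804038693	0.10551381245606943
gene0007	7	0.61264768554871474	0.14903445784466418	0.33584811975207446	-0.21713984574652084	-0.42225588186885599
gene0008	8	-1.5270149642535689	1.1563749093389937	1.0385060986976211	-0.18275670633192173	-0.12235017195497132
gene0009	9	1.4904812637951983	0.74456240736730106	0.92072856829064631	0.93334632857116007	0.18819303450149788
gene0010	10	NA	0.51420444879967653	0.72087816286686246	NA	0.11916095799700638
gene0011	11	1.0957634564181156	0.98404854514969231	-1.043118938567855	NA	-0.025092550867402877
gene0012	12	1.8421564878657262	0.59664055352223844	-0.090186386610706687	-0.47617392305467421	0.10807272794203257
gene0013	13	0.10531940492520175	0.55763789328796032	0.62351816199954357	0.65034856072630509	-0.4854352358466677
gene0014	14	-0.66216325377041763	0.38518925381526664	-0.95352335777234398	1.3911104563900005	-0.50421713068790353
gene0015	15	0.3494526635174563	0.0020760416262008974	-0.54282881457385668	-1.1107888794478988	-1.661099079914812
gene0016	16	NA	0.57970333404426344	NA	-0.8607925868778421	-0.38233372687381795
gene0017	17	-0.8120172318620098	0.41264206176877744	0.76817873783459101	-1.1317386808537699	-0.51265025787780039
gene0018	18	-2.1669209273581984	-1.3798409717675391	0.4637675885401672	-1.4592139995023958	2.7018910003447982
gene0019	19	-3.3565698240892781	-3.840897616015774	-0.88577629740967945	0.079982553241161172	-1.3621162311897186
gene0020	20	0.75327819916099692	0.96140603738010966	-1.0997808986478557	0.65320433964919	0.13725621855860692
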