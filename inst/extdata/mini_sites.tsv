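gene	site_id	chrom_class	mu	AC	AN	misannotated
gene0001	gene0001_s1	autosome	1.5848931924611141e-06	0	100	TRUE
gene0001	gene0001_s2	autosome	1.5848931924611141e-06	0	100	FALSE
gene0001	gene0001_s3	autosome	3.9810717055349691e-06	0	100	FALSE
gene0001	gene0001_s4	autosome	2.5118864315095823e-07	0	100	FALSE
gene0001	gene0001_s5	autosome	3.9810717055349691e-06	0	100	FALSE
gene0002	gene0002_s1	autosome	2.5118864315095823e-07	0	100	FALSE
gene0002	gene0002_s2	autosome	3.9810717055349691e-06	0	100	FALSE
gene0002	gene0002_s3	autosome	2.5118864315095823e-07	0	100	FALSE
gene0002	gene0002_s4	autosome	1.0000000000000001e-05	0	100	FALSE
gene0002	gene0002_s5	autosome	1.0000000000000001e-05	0	100	FALSE
gene0003	gene0003_s1	autosome	9.9999999999999995e-08	0	100	FALSE
gene0003	gene0003_s2	autosome	9.9999999999999995e-08	0	100	FALSE
gene0003	gene0003_s3	autosome	3.9810717055349691e-06	0	100	FALSE
gene0003	gene0003_s4	autosome	1.5848931924611141e-06	0	100	FALSE
gene0003	gene0003_s5	autosome	6.3095734448019296e-07	0	100	FALSE
gene0004	gene0004_s1	autosome	3.9810717055349691e-06	0	100	FALSE
gene0004	gene0004_s2	autosome	1.0000000000000001e-05	0	100	FALSE
gene0004	gene0004_s3	autosome	1.0000000000000001e-05	0	100	FALSE
gene0004	gene0004_s4	autosome	1.5848931924611141e-06	0	100	FALSE
gene0004	gene0004_s5	autosome	9.9999999999999995e-08	0	100	FALSE
gene0005	gene0005_s1	autosome	6.3095734448019296e-07	0	100	FALSE
gene0005	gene0005_s2	autosome	1.0000000000000001e-05	0	100	FALSE
gene0005	gene0005_s3	autosome	6.3095734448019296e-07	0	100	FALSE
gene0005	gene0005_s4	autosome	3.9810717055349691e-06	0	100	FALSE
gene0005	gene0005_s5	autosome	9.9999999999999995e-08	0	100	TRUE
gene0006	gene0006_s1	autosome	9.9999999999999995e-08	0	100	FALSE
gene0006	gene0006_s2	autosome	1.0000000000000001e-05	0	100	FALSE
gene0006	gene0006_s3	autosome	2.5118864315095823e-07	0	100	TRUE
gene0006	gene0006_s4	autosome	1.5848931924611141e-06	0	100	FALSE
gene0006	gene0006_s5	autosome	1.5848931924611141e-06	0	100	FALSE
gene0007	gene0007_s1	autosome	1.5848931924611141e-06	0	100	FALSE
gene0007	gene0007_s2	autosome	6.3095734448019296e-07	0	100	FALSE
gene0007	gene0007_s3	autosome	3.9810717055349691e-06	0	100	FALSE
gene0007	gene0007_s4	autosome	9.9999999999999995e-08	0	100	FALSE
gene0007	gene0007_s5	autosome	2.5118864315095823e-07	0	100	FALSE
gene0008	gene0008_s1	autosome	9.9999999999999995e-08	0	100	FALSE
gene0008	gene0008_s2	autosome	1.0000000000000001e-05	0	100	FALSE
gene0008	gene0008_s3	autosome	9.9999999999999995e-08	0	100	TRUE
gene0008	gene0008_s4	autosome	1.5848931924611141e-06	0	100	FALSE
gene0008	gene0008_s5	autosome	2.5118864315095823e-07	0	100	FALSE
gene0009	gene0009_s1	autosome	6.3095734448019296e-07	0	100	FALSE
gene0009	gene0009_s2	autosome	1.0000000000000001e-05	0	100	FALSE
gene0009	gene0009_s3	autosome	2.5118864315095823e-07	0	100	FALSE
gene0009	gene0009_s4	autosome	1.0000000000000001e-05	0	100	FALSE
gene0009	gene0009_s5	autosome	1.0000000000000001e-05	0	100	FALSE
gene0010	gene0010_s1	autosome	1.0000000000000001e-05	0	100	FALSE
gene0010	gene0010_s2	autosome	1.5848931924611141e-06	0	100	TRUE
gene0010	gene0010_s3	autosome	3.9810717055349691e-06	0	100	FALSE
gene0010	gene0010_s4	autosome	9.9999999999999995e-08	0	100	FALSE
gene0010	gene0010_s5	autosome	3.9810717055349691e-06	0	100	FALSE
gene0011	gene0011_s1	autosome	3.9810717055349691e-06	0	100	FALSE
gene0011	gene0011_s2	autosome	6.3095734448019296e-07	0	100	FALSE
gene0011	gene0011_s3	autosome	1.0000000000000001e-05	0	100	FALSE
gene0011	gene0011_s4	autosome	1.5848931924611141e-06	0	100	FALSE
gene0011	gene0011_s5	autosome	1.5848931924611141e-06	0	100	FALSE
gene0012	gene0012_s1	autosome	6.3095734448019296e-07	0	100	FALSE
gene0012	gene0012_s2	autosome	2.5118864315095823e-07	0	100	FALSE
gene0012	gene0012_s3	autosome	9.9999999999999995e-08	0	100	FALSE
gene0012	gene0012_s4	autosome	9.9999999999999995e-08	0	100	FALSE
gene0012	gene0012_s5	autosome	2.5118864315095823e-07	0	100	FALSE
gene0013	gene0013_s1	autosome	6.3095734448019296e-07	0	100	TRUE
gene0013	gene0013_s2	autosome	3.9810717055349691e-06	0	100	FALSE
gene0013	gene0013_s3	autosome	3.9810717055349691e-06	0	100	FALSE
gene0013	gene0013_s4	autosome	1.0000000000000001e-05	0	100	FALSE
gene0013	gene0013_s5	autosome	1.5848931924611141e-06	0	100	FALSE
gene0014	gene0014_s1	autosome	1.0000000000000001e-05	0	100	TRUE
gene0014	gene0014_s2	autosome	9.9999999999999995e-08	0	100	FALSE
gene0014	gene0014_s3	autosome	2.5118864315095823e-07	0	100	FALSE
gene0014	gene0014_s4	autosome	6.3095734448019296e-07	0	100	FALSE
gene0014	gene0014_s5	autosome	6.3095734448019296e-07	0	100	FALSE
gene0015	gene0015_s1	autosome	9.9999999999999995e-08	0	100	TRUE
gene0015	gene0015_s2	autosome	3.9810717055349691e-06	0	100	FALSE
gene0015	gene0015_s3	autosome	3.9810717055349691e-06	0	100	FALSE
gene0015	gene0015_s4	autosome	6.3095734448019296e-07	0	100	FALSE
gene0015	gene0015_s5	autosome	9.9999999999999995e-08	0	100	FALSE
gene0016	gene0016_s1	autosome	3.9810717055349691e-06	0	100	FALSE
gene0016	gene0016_s2	autosome	2.5118864315095823e-07	0	100	FALSE
gene0016	gene0016_s3	autosome	3.9810717055349691e-06	0	100	FALSE
gene0016	gene0016_s4	autosome	3.9810717055349691e-06	0	100	FALSE
gene0016	gene0016_s5	autosome	2.5118864315095823e-07	0	100	FALSE
gene0017	gene0017_s1	autosome	3.9810717055349691e-06	0	100	FALSE
gene0017	gene0017_s2	autosome	1.0000000000000001e-05	0	100	FALSE
gene0017	gene0017_s3	autosome	1.5848931924611141e-06	0	100	FALSE
gene0017	gene0017_s4	autosome	3.9810717055349691e-06	0	100	FALSE
gene0017	gene0017_s5	autosome	2.5118864315095823e-07	0	100	FALSE
gene0018	gene0018_s1	autosome	3.9810717055349691e-06	0	100	FALSE
gene0018	gene0018_s2	autosome	1.0000000000000001e-05	0	100	FALSE
gene0018	gene0018_s3	autosome	1.5848931924611141e-06	0	100	FALSE
gene0018	gene0018_s4	autosome	1.0000000000000001e-05	0	100	FALSE
gene0018	gene0018_s5	autosome	2.5118864315095823e-07	0	100	FALSE
gene0019	gene0019_s1	autosome	9.9999999999999995e-08	0	100	FALSE
gene0019	gene0019_s2	autosome	9.9999999999999995e-08	0	100	FALSE
gene0019	gene0019_s3	autosome	1.5848931924611141e-06	0	100	FALSE
gene0019	gene0019_s4	autosome	6.3095734448019296e-07	0	100	FALSE
gene0019	gene0019_s5	autosome	2.5118864315095823e-07	0	100	FALSE
gene0020	gene0020_s1	autosome	2.5118864315095823e-07	0	100	FALSE
gene0020	gene0020_s2	autosome	1.5848931924611141e-06	0	100	FALSE
gene0020	gene0020_s3	autosome	9.9999999999999995e-08	0	100	TRUE
gene0020	gene0020_s4	autosome	6.3095734448019296e-07	0	100	FALSE
gene0020	gene0020_s5	autosome	6.3095734448019296e-07	0	100	FALSE
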