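gene	chrom	m	sTrue
gene0001	1	-0.71898466146358542	0.068065622122583172
gene0002	2	-2.5749057853560551	0.00096374800535794136
gene0003	3	-1.0737700172840916	0.091968837839531803
gene0004	4	-0.97361974950708552	0.053381221830009963
gene0005	5	-1.1115546593963908	0.077250012133781243
gene0006	6	-1.6674059855299896	0.015999866170126747
gene0007	7	-0.94035462986979357	0.075083392678801833
gene0008	8	-1.7961244245641619	0.0039488644095446845
gene0009	9	-0.44040229933616959	0.15565867006640319
gene0010	10	-1.6639055737029076	0.024544226984426029
gene0011	11	-0.47579964320154833	0.49486476788563755
gene0012	12	-0.42326664836945849	0.26845416453111531
gene0013	13	-1.0992572246279873	0.079572250396484176
gene0014	14	-1.7555876652009872	0.038131090684360422
gene0015	15	-1.1875920287372859	0.17553539228306636
gene0016	16	-1.83177434810222	0.0069038527737492524
gene0017	17	-1.8040693667103169	0.014478873215247573
gene0018	18	-2.7849261405893317	0.0037629060884496234
gene0019	19	-3.0592953307384958	0.00063064621725990322
gene0020	20	-0.59230284134271416	0.24657912843264679
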