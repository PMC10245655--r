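chrom	pos	ref	alt	gene	consequence	lof_confidence	flagged	pext	depth	segdup	AC	AN	mu
1	100	C	T	GENEA	stop_gained	HC	FALSE	0.9	35	FALSE	1	1000	1e-08
1	200	G	A	GENEA	missense	HC	FALSE	0.8	30	FALSE	2	998	2e-08
1	300	A	T	GENEA	splice_donor	LC	FALSE	0.7	28	FALSE	0	NA	5e-09
2	400	C	A	GENEB	splice_acceptor	HC	FALSE	0.04	40	FALSE	3	1000	1e-07
2	500	T	A	GENEB	stop_gained	HC	FALSE	0.95	2	FALSE	1	996	3e-08
7	600	G	T	GENEC	stop_gained	HC	FALSE	0.5	31	TRUE	0	NA	8e-08
7	700	C	T	GENEC	synonymous	HC	FALSE	0.6	33	FALSE	5	1000	1e-08
12	800	A	T	GENED	splice_donor	HC	FALSE	NA	25	FALSE	2	990	2e-08
X	900	G	A	GENEE	stop_gained	HC	FALSE	0.99	38	FALSE	1	500	4e-08
X	1000	C	T	GENEE	splice_acceptor	HC	TRUE	0.9	30	FALSE	0	NA	6e-08
5	1100	T	A	GENEF	stop_gained	HC	FALSE	0.2	29	FALSE	4	1000	1e-08
5	1200	A	G	GENEF	stop_gained	HC	FALSE	0.85	27	FALSE	0	NA	9e-09
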