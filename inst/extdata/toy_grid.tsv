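s	prior	loglik
1e-04	0.1	-2
0.001	0.2	-1
0.01	0.4	-0.5
0.1	0.2	-1.5
1	0.1	-3
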