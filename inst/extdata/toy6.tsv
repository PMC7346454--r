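U	A	R_A	A_star	Y	A_imp
0	1.2	1	1.2	2.0	1.2
0	0.4	0		0.1	-0.5
0	0.3	1	0.3	-1.3	0.3
1	2.0	1	2.0	3.4	2.0
1	-0.9	0		0.2	-1.0
1	0.7	1	0.7	1.1	0.7
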