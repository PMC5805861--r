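g1	g2	weight
0	0	0
1	0	1.6
2	0	2
0	1	1.5
1	1	3.3
2	1	2.7
0	2	1.9
1	2	2.6
2	2	2.2
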