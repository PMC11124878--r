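class	recall	precision	f1
0	0.92	1.00	0.96
1	0.97	0.95	0.96
2	1.00	1.00	1.00
3	0.97	0.95	0.96
4	1.00	0.97	0.99
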