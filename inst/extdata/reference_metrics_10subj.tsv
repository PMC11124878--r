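class	recall	precision	f1
0	0.98	0.94	0.96
1	1.00	0.93	0.97
2	1.00	0.97	0.99
3	0.90	1.00	0.95
4	0.96	1.00	0.98
5	0.90	1.00	0.95
6	0.85	0.97	0.90
7	1.00	0.90	0.95
8	0.95	1.00	0.97
9	1.00	0.89	0.94
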