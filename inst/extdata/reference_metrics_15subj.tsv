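class	recall	precision	f1
0	0.92	0.87	0.89
1	0.98	0.98	0.98
2	1.00	0.80	0.89
3	0.50	1.00	0.67
4	0.86	1.00	0.92
5	0.60	1.00	0.75
6	0.74	1.00	0.85
7	0.84	0.84	0.84
8	1.00	0.97	0.99
9	0.76	1.00	0.87
10	1.00	0.54	0.70
11	1.00	0.74	0.85
12	0.93	0.97	0.95
13	0.96	0.88	0.92
14	0.87	0.93	0.90
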