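class	recall	precision	f1
0	0.89	0.62	0.73
1	1.00	1.00	1.00
2	0.97	0.49	0.65
3	0.57	1.00	0.73
4	0.73	1.00	0.85
5	0.64	1.00	0.78
6	0.93	0.87	0.90
7	0.67	1.00	1.00
8	1.00	1.00	1.00
9	0.51	1.00	0.68
10	0.94	0.78	0.85
11	0.77	0.83	0.80
12	1.00	0.91	0.96
13	0.87	0.95	0.91
14	0.86	0.94	0.90
15	0.95	0.67	0.79
16	0.90	1.00	0.95
17	0.91	0.97	0.94
18	1.00	0.67	0.80
19	0.39	1.00	0.56
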