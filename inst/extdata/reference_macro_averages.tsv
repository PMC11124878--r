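table	recall	precision	f1	accuracy
5subj	0.97	0.97	0.97	0.97
10subj	0.95	0.96	0.96	0.96
15subj	0.86	0.90	0.86	0.87
20subj	0.83	0.88	0.83	0.82
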