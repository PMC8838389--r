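feature_id	waxy_57	waxy_78	waxy_99	waxy_120	waxy_150	russet_57	russet_78	russet_99	russet_120	russet_150
MDP0000285074	16.35	10.52	24.23	22.81	11.37	10.84	5.03	9.44	14.46	6.51
MDP0000304369	5.98	4.45	8.75	8.04	1.25	6.90	0	0	0	0
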