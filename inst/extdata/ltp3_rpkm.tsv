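feature_id	waxy_57	waxy_78	waxy_99	waxy_120	waxy_150	russet_57	russet_78	russet_99	russet_120	russet_150
MDP0000285074	23540.0	29906.7	49936.6	32077.5	64941.5	6517.5	5625.1	2116.9	2379.1	19183.5
MDP0000304369	543.4	284.9	245.1	150.0	778.1	194.2	62.9	25.3	26.6	539.6
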