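feature_id	waxy_57	waxy_78	waxy_99	waxy_120	waxy_150	russet_57	russet_78	russet_99	russet_120	russet_150
phloretin	68	89	129	687	864	1281	1449	5384	10097	8984
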