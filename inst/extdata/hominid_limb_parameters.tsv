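network	N	K	D	C	L	H
Homo_sapiens_forelimb	94	193	0.044	0.380	3.10	0.923
Pan_troglodytes_forelimb	99	245	0.051	0.405	3.313	0.788
Pan_paniscus_forelimb	95	217	0.049	0.423	3.296	0.845
Homo_sapiens_hindlimb	91	207	0.051	0.378	3.222	0.909
Pan_troglodytes_hindlimb	97	217	0.047	0.381	3.320	0.962
Pan_paniscus_hindlimb	98	222	0.047	0.391	3.305	0.974
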