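domain	measure	group	n	mean	se	sd
Cognitive flexibility	TMTA	High Flex	15	38	3.2	12.4
Cognitive flexibility	TMTA	Low Flex	15	37.2	2.54	9.84
Cognitive flexibility	TMTB	High Flex	15	100.47	12.9	50
Cognitive flexibility	TMTB	Low Flex	15	89.8	5.11	19.8
Cognitive flexibility	TMTBA	High Flex	15	62.6	10.5	40.5
Cognitive flexibility	TMTBA	Low Flex	15	52.6	4.27	16.5
Cognitive flexibility	ACE-R	High Flex	15	94.73	0.54	2.09
Cognitive flexibility	ACE-R	Low Flex	15	94.6	0.7	2.72
Cognitive flexibility	ACE AO	High Flex	15	17.67	0.21	0.82
Cognitive flexibility	ACE AO	Low Flex	15	17.93	0.07	0.26
Cognitive flexibility	ACE M	High Flex	15	24.8	0.26	1.01
Cognitive flexibility	ACE M	Low Flex	15	24.67	0.39	1.5
Cognitive flexibility	ACE VS	High Flex	15	15.27	0.27	1.03
Cognitive flexibility	ACE VS	Low Flex	15	14.8	0.22	0.86
Cognitive flexibility	MOCA	High Flex	15	26.4	0.68	2.64
Cognitive flexibility	MOCA	Low Flex	15	27	0.56	2.17
Cognitive function	CFI self	High Flex	15	2.57	0.45	1.74
Cognitive function	CFI self	Low Flex	15	3.2	0.45	1.73
Cognitive function	CFI partner	High Flex	15	1.37	0.26	1.03
Cognitive function	CFI partner	Low Flex	15	1.33	0.37	1.44
Cognitive function	CFI self-partner	High Flex	15	1.2	0.53	2.04
Cognitive function	CFI self-partner	Low Flex	15	1.87	0.47	1.84
Cognitive decline	CIRS sev	High Flex	15	1.33	0.04	0.17
Cognitive decline	CIRS sev	Low Flex	15	1.36	0.03	0.14
Cognitive decline	CIRS com	High Flex	15	1.13	0.19	0.74
Cognitive decline	CIRS com	Low Flex	15	1.47	0.22	0.83
Affective	BDI	High Flex	15	6.33	1.63	6.31
Affective	BDI	Low Flex	15	6.87	1.67	6.48
Affective	HARS	High Flex	15	7.6	1.37	5.3
Affective	HARS	Low Flex	15	7.33	1.41	5.46
Affective	ERQ R	High Flex	15	32.07	1.36	5.28
Affective	ERQ R	Low Flex	15	27.4	1.13	4.37
Affective	ERQ S	High Flex	15	17.47	1.04	4.02
Affective	ERQ S	Low Flex	15	18	1.29	5.01
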