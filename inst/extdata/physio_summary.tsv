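domain	measure	group	n	mean	se	sd
HRV temporal	RMSSD	High Flex	14	25.12	2.18	8.14
HRV temporal	RMSSD	Low Flex	13	37.70	15.91	57.37
HRV temporal	SDNN	High Flex	14	24.01	2.18	8.16
HRV temporal	SDNN	Low Flex	13	33.04	10.10	36.43
HRV temporal	Max HR	High Flex	14	83.62	2.04	7.62
HRV temporal	Max HR	Low Flex	13	84.78	5.44	19.60
HRV temporal	NN50	High Flex	14	178.50	44.95	168.20
HRV temporal	NN50	Low Flex	13	293.00	153.65	553.98
HRV frequency	VLF pow FFT	High Flex	14	43.99	12.00	44.91
HRV frequency	VLF pow FFT	Low Flex	13	70.89	24.12	86.98
HRV frequency	LF pow FFT	High Flex	14	305.53	66.88	250.22
HRV frequency	LF pow FFT	Low Flex	13	934.41	529.39	1908.74
HRV frequency	HF pow FFT	High Flex	14	222.51	59.00	220.76
HRV frequency	HF pow FFT	Low Flex	13	806.51	631.68	2277.57
HRV frequency	LF HF ratio FFT	High Flex	14	1.48	0.13	0.49
HRV frequency	LF HF ratio FFT	Low Flex	13	2.02	0.28	1.02
HRV nonlinear	SD1	High Flex	14	17.76	1.54	5.76
HRV nonlinear	SD1	Low Flex	13	26.66	11.25	40.58
HRV nonlinear	SD2	High Flex	14	28.76	2.83	10.58
HRV nonlinear	SD2	Low Flex	13	37.40	9.16	33.02
HRV nonlinear	SD2 SD1 ratio	High Flex	14	1.65	0.10	0.36
HRV nonlinear	SD2 SD1 ratio	Low Flex	13	1.79	0.13	0.46
Facial EMG	mean EMG1/EMG2	High Flex	14	2.99	0.38	1.44
Facial EMG	mean EMG1/EMG2	Low Flex	14	3.15	0.39	1.46
Facial EMG	mean EMG2/EMG1	High Flex	14	1.58	0.90	3.39
Facial EMG	mean EMG2/EMG1	Low Flex	14	1.97	1.17	4.38
Facial EMG	StD EMG1/EMG2	High Flex	14	3.83	2.25	8.43
Facial EMG	StD EMG1/EMG2	Low Flex	14	9.07	6.17	23.08
Facial EMG	StD EMG2/EMG1	High Flex	14	19.81	14.76	55.23
Facial EMG	StD EMG2/EMG1	Low Flex	14	19.75	17.65	66.03
Facial EMG	RMS EMG1/EMG2	High Flex	14	5.50	2.17	8.12
Facial EMG	RMS EMG1/EMG2	Low Flex	14	10.52	6.06	22.69
Facial EMG	RMS EMG2/EMG1	High Flex	14	20.08	14.77	55.25
Facial EMG	RMS EMG2/EMG1	Low Flex	14	20.05	17.67	66.11
Skin conductance	Mean SC	High Flex	13	2.38	1.37	0.38
Skin conductance	Mean SC	Low Flex	14	2.35	0.92	0.25
Skin conductance	StD SC	High Flex	13	0.30	0.23	0.06
Skin conductance	StD SC	Low Flex	14	0.29	0.13	0.04
Skin conductance	RMS SC	High Flex	13	2.41	1.37	0.38
Skin conductance	RMS SC	Low Flex	14	2.37	0.92	0.25
Respiration	Mean RSP Rate	High Flex	14	29.83	0.80	3.00
Respiration	Mean RSP Rate	Low Flex	14	31.85	1.64	6.14
Respiration	StD RSP Rate	High Flex	14	10.52	0.44	1.66
Respiration	StD RSP Rate	Low Flex	14	12.26	0.87	3.27
Respiration	RMS RSP Rate	High Flex	14	31.68	0.76	2.84
Respiration	RMS RSP Rate	Low Flex	14	34.26	1.67	6.26
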