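analysis	node	sex	state	prob	hm	lbf
life_history	Root	NA	DD	0.90	-44.29	0.00
life_history	Root	NA	BI	0.10	-46.82	5.05
life_history	Root	NA	PD	0.00	-52.36	16.15
life_history	A	NA	DD	0.01	-51.65	15.35
life_history	A	NA	BI	0.98	-43.98	0.00
life_history	A	NA	PD	0.01	-51.52	15.09
life_history	B	NA	DD	0.00	-55.13	21.74
life_history	B	NA	BI	0.96	-44.26	0.00
life_history	B	NA	PD	0.04	-51.07	13.65
life_history	C	NA	DD	0.00	-55.49	22.55
life_history	C	NA	BI	0.75	-44.22	0.00
life_history	C	NA	PD	0.25	-49.65	10.86
life_history	D	NA	DD	0.00	-59.97	31.26
life_history	D	NA	BI	0.00	-48.95	9.23
life_history	D	NA	PD	1.00	-44.33	0.00
life_history	E	NA	DD	0.00	-65.99	43.89
life_history	E	NA	BI	0.00	-53.00	17.92
life_history	E	NA	PD	1.00	-44.04	0.00
maturation	A	male	0-11	0.14	-106.89	10.63
maturation	A	male	12-23	0.28	-104.19	5.21
maturation	A	male	24-35	0.39	-101.58	0.00
maturation	A	male	36-47	0.16	-104.97	6.78
maturation	A	male	48-59	0.03	-105.72	8.27
maturation	A	male	60+	0.00	-107.79	12.43
maturation	A	female	0-11	0.08	-105.06	9.80
maturation	A	female	12-23	0.14	-102.58	4.84
maturation	A	female	24-35	0.27	-102.08	0.00
maturation	A	female	36-47	0.25	-100.15	3.85
maturation	A	female	48-59	0.17	-102.60	4.88
maturation	A	female	60+	0.09	-102.72	5.13
maturation	B	male	0-11	0.77	-100.86	0.00
maturation	B	male	12-23	0.20	-101.57	1.40
maturation	B	male	24-35	0.03	-102.59	3.45
maturation	B	male	36-47	0.00	-109.53	17.33
maturation	B	male	48-59	0.00	-112.52	23.31
maturation	B	male	60+	0.00	-112.69	23.65
maturation	B	female	0-11	0.67	-101.08	0.00
maturation	B	female	12-23	0.27	-103.66	5.15
maturation	B	female	24-35	0.06	-104.03	5.90
maturation	B	female	36-47	0.00	-105.84	9.52
maturation	B	female	48-59	0.00	-110.84	19.52
maturation	B	female	60+	0.00	-112.07	21.98
maturation	C	male	0-11	0.75	-100.58	0.00
maturation	C	male	12-23	0.22	-101.17	1.18
maturation	C	male	24-35	0.03	-104.83	8.50
maturation	C	male	36-47	0.00	-111.80	22.45
maturation	C	male	48-59	0.00	-112.65	24.13
maturation	C	male	60+	0.00	-112.73	24.29
maturation	C	female	0-11	0.68	-99.76	0.00
maturation	C	female	12-23	0.27	-101.37	3.21
maturation	C	female	24-35	0.05	-104.48	9.44
maturation	C	female	36-47	0.00	-108.16	16.79
maturation	C	female	48-59	0.00	-111.86	24.19
maturation	C	female	60+	0.00	-112.35	25.16
maturation	D	male	0-11	0.64	-100.58	0.00
maturation	D	male	12-23	0.35	-102.10	3.04
maturation	D	male	24-35	0.01	-108.61	16.06
maturation	D	male	36-47	0.00	-112.55	23.95
maturation	D	male	48-59	0.00	-112.769	24.37
maturation	D	male	60+	0.00	-112.79	24.42
maturation	D	female	0-11	0.61	-99.37	0.00
maturation	D	female	12-23	0.36	-103.36	7.97
maturation	D	female	24-35	0.03	-106.49	14.2
maturation	D	female	36-47	0.00	-111.76	24.78
maturation	D	female	48-59	0.00	-112.64	26.53
maturation	D	female	60+	0.00	-112.74	26.74
maturation	E	male	0-11	0.32	-101.58	0.90
maturation	E	male	12-23	0.64	-101.13	0.00
maturation	E	male	24-35	0.04	-107.75	13.23
maturation	E	male	36-47	0.00	-112.74	23.22
maturation	E	male	48-59	0.00	-112.80	23.34
maturation	E	male	60+	0.00	-112.81	23.36
maturation	E	female	0-11	0.34	-102.28	0.77
maturation	E	female	12-23	0.61	-101.89	0.00
maturation	E	female	24-35	0.05	-106.87	9.95
maturation	E	female	36-47	0.00	-112.44	21.09
maturation	E	female	48-59	0.00	-112.78	21.77
maturation	E	female	60+	0.00	-112.79	21.79
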