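study	country	n_nonhealthy	n_healthy	avg_depth_gb	accession	note
Cov19	China	15	15	4.39	PRJNA624223	.
SCZ	China	90	81	10.94	PRJEB29127	.
SF	Italy	5	5	1.57	PRJNA418941	.
AS	China	97	114	3.73	PRJNA375935	.
PCOS	China	14	14	6.22	PRJNA549764	.
PCOS	China	50	43	8.78	PRJNA530971	.
GD	China	102	62	8.07	PRJNA602729	.
T2D	China	71	74	2.51	PRJNA422434	.
CRC	China	8	12	6.45	PRJNA663646	.
CRC	Japan	40	40	6.42	DRA006684	.
CRC	Italy	32	28	3.89	SRP136711	.
CRC	Austria	46	63	4.84	ERP008729	.
BC	China	62	71	10.94	PRJNA718520	.
UC	American_Holland	76	56	4.01	PRJNA400072	.
CD	American_Holland	88	0	4.34	PRJNA400072	shares_UC_control_group
LC	China	123	114	1.74	PRJEB6337	.
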