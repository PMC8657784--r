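# Published SD-OCT macular thickness summaries (microns) by group and decade
# of age: number of eyes, mean and sample SD at the fovea and at 1500/3000 um
# temporal (T1500, T3000) and 1500 um nasal (N1500) of the fovea.  SD is NA
# where only one eye was measured; rows with n_eyes = 0 carry NA means.
# These are simulation parameters: the underlying per-eye measurements were
# never published, so the summaries cannot be recomputed from real data.
group	decade	n_eyes	fovea_mean	fovea_sd	t1500_mean	t1500_sd	t3000_mean	t3000_sd	n1500_mean	n1500_sd
Controls	Global	28	226.79	20.71	321.46	19.03	257.89	17.08	347.21	19.29
Controls	[0;10]	0	NA	NA	NA	NA	NA	NA	NA	NA
Controls	]10;20]	2	266.50	0.71	310.00	2.83	260.00	1.41	341.00	1.41
Controls	]20;30]	10	218.30	14.58	322.90	18.04	261.40	12.31	352.50	21.08
Controls	]30;40]	4	234.25	20.65	305.75	6.55	242.50	2.38	330.25	13.74
Controls	]40;50]	4	204.25	7.32	312.25	6.70	244.25	7.37	337.50	9.54
Controls	>50	8	235.00	14.92	335.00	22.37	267.50	23.19	355.50	19.89
Maculopathy	Global	14	106.57	23.64	284.43	47.00	232.36	28.32	308.79	33.24
Maculopathy	[0;10]	0	NA	NA	NA	NA	NA	NA	NA	NA
Maculopathy	]10;20]	0	NA	NA	NA	NA	NA	NA	NA	NA
Maculopathy	]20;30]	4	108.00	5.29	248.50	31.27	214.00	28.01	281.00	14.88
Maculopathy	]30;40]	6	96.33	21.92	299.67	45.45	255.00	20.28	335.00	23.16
Maculopathy	]40;50]	2	108.00	1.41	263.00	9.90	208.50	2.12	304.00	36.77
Maculopathy	>50	2	133.00	52.33	332.00	57.98	225.00	18.38	290.50	41.72
RP	Global	21	272.95	150.51	353.48	49.72	344.76	75.15	382.67	42.48
RP	[0;10]	8	296.50	211.71	360.88	67.27	358.38	100.29	396.88	53.90
RP	]10;20]	4	266.75	112.23	356.75	12.34	343.00	38.76	372.00	21.02
RP	]20;30]	6	242.67	115.77	362.50	35.14	364.83	58.33	384.17	38.92
RP	]30;40]	0	NA	NA	NA	NA	NA	NA	NA	NA
RP	]40;50]	1	177.00	NA	257.00	NA	250.00	NA	314.00	NA
RP	>50	2	330.00	93.34	338.50	20.51	281.00	4.24	377.00	0.00
EORD	Global	17	268.94	169.17	363.71	55.83	332.53	58.25	415.29	70.12
EORD	[0;10]	10	290.30	201.05	388.10	51.25	355.10	61.94	434.00	71.05
EORD	]10;20]	2	403.00	21.21	342.50	3.54	318.00	12.73	464.50	6.36
EORD	]20;30]	2	190.50	61.52	374.00	18.38	324.50	30.41	404.50	27.58
EORD	]30;40]	1	185.00	NA	311.00	NA	257.00	NA	348.00	NA
EORD	]40;50]	0	NA	NA	NA	NA	NA	NA	NA	NA
EORD	>50	2	148.50	31.82	279.00	41.01	280.00	42.43	317.00	1.41
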