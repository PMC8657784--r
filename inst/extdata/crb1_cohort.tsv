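patient_id	family_id	sex	phenotype	nystagmus	onset_age	age_first_visit	age_final_visit	followup_months	topography	erg	allele1_cdna	allele1_protein	allele2_cdna	allele2_protein	initial_bcva_od	initial_bcva_os	drusen	pparpe	coats	edema
M-1640-1	M-1640	M	EORD	No	3	46.5	53	82	generalized	indiscernible	c.1562C>T	p.Ala521Val	c.1562C>T	p.Ala521Val	2.3 (HM)	2.3 (HM)	No	No	No	No
M-2129	M-2129	M	EORD	No	1.5	9.5	15	66	generalized	indiscernible	c.2234C>T	p.Thr745Met	c.2234C>T	p.Thr745Met	0.3 (20/40)	1.0 (20/200)	No	Yes	No	No
M-567	M-567	M	EORD	No	3	4	11	84	generalized	indiscernible	c.2290C>T	p.Arg764Cys	c.1445_1453del	p.Ile482_Thr484del	0 (20/20)	0 (20/20)	Yes	No	No	Yes
M-116	M-116	F	EORD	No	5	43.5	ND	ND	generalized	indiscernible	c.687G>A	p.Trp229*	c.4219T>A	p.Ter1407Lysext*111	0.7 (20/100)	0.7 (20/100)	ND	ND	ND	ND
M-3361	M-3361	M	EORD	No	4.5	5	7.5	25	generalized	indiscernible	c.2290C>T	p.Arg764Cys	c.2290C>T	p.Arg764Cys	0.1 (20/25)	0.4 (20/50)	Yes	No	No	Yes
M-3591	M-3591	M	EORD	No	1	4.5	6	23	generalized	indiscernible	c.2290C>T	p.Arg764Cys	c.2401A>T	p.Lys801*	0.7 (20/100)	0.7 (20/100)	No	Yes	No	Yes
M-2897	M-2897	F	EORD	No	5	34	ND	ND	generalized	indiscernible	c.2548G>A	p.Gly850Ser	c.2843G>A	p.Cys948Tyr	2.3 (HM)	1.7 (20/1000)	No	No	No	No
M-3235	M-3235	M	EORD	No	4	17.5	ND	ND	generalized	indiscernible	c.2290C>T	p.Arg764Cys	c.4214del	p.Leu1405Argfs*82	0.7 (20/100)	0.7 (20/100)	Yes	Yes	No	Yes
M-1316-4	M-1316	F	EORD	No	5	7	ND	ND	generalized	indiscernible	c.2243del	p.Pro748Hisfs*6	c.2243del	p.Pro748Hisfs*6	0.4 (20/50)	0.7 (20/100)	No	Yes	No	No
M-340	M-340	F	EORD	No	1	5	22	200	generalized	indiscernible	c.2290C>T	p.Arg764Cys	c.2479G>T	p.Gly827*	1.0 (20/200)	1.0 (20/200)	Yes	Yes	No	No
L-15090708	L-15090708	M	EORD	No	1	4	8	48	generalized	indiscernible	c.2401A>T	p.Lys801*	c.3713G>T	p.Cys1238Phe	1.3 (20/400)	1.0 (20/200)	No	Yes	No	No
L-14061710	L-14061710	F	EORD	No	1	4	11	84	generalized	indiscernible	c.2548G>A	p.Gly850Ser	c.4142C>G	p.Pro1381Arg	0.7 (20/100)	0.7 (20/100)	Yes	No	No	No
XZ-372875	XZ-372875	F	EORD	No	4	4	10	72	generalized	indiscernible	c.3686G>C	p.Cys1229Ser	c.3320T>C	p.Leu1107Pro	0.8 (20/125)	0.9 (20/160)	No	Yes	No	No
M-1316-1	M-1316	F	EORD	No	3.5	4.5	17	116	generalized	indiscernible	c.2243del	p.Pro748Hisfs*6	c.2243del	p.Pro748Hisfs*6	1.2 (20/320)	1.0 (20/200)	No	Yes	No	No
M-3324	M-3324	F	EORD	No	1.5	27	ND	ND	generalized	indiscernible	c.1084C>T	p.Gln362*	c.2401A>T	p.Lys801*	2.3 (HM)	2.3 (HM)	No	No	No	No
M-2427	M-2427	M	EORD	No	<5	5	7	26	generalized	indiscernible	c.2234C>T	p.Thr745Met	c.4073T>A	p.Ile1358Asn	2.3 (HM)	2.3 (HM)	No	No	No	No
M-4621-1	M-4621	F	EORD	No	2.5	3	4.5	21	generalized	indiscernible	c.4142C>G	p.Pro1381Arg	c.4142C>G	p.Pro1381Arg	ND	ND	No	Yes	No	No
M-1580	M-1580	F	EORD	No	1	17	21	47	generalized	indiscernible	c.3164T>A	p.Val1055Glu	c.3320T>C	p.Leu1107Pro	2.3 (HM)	2.3 (HM)	Yes	Yes	No	No
M-2123	M-2123	M	EORD	Yes	0.5	0.5	ND	ND	generalized	indiscernible	c.3999_4005+4delinsAAAGGAGAGC	p.?	c.3999_4005+4delinsAAAGGAGAGC	p.?	ND	ND	No	No	No	No
M-2123-2	M-2123	M	EORD	Yes	0.4	0.5	ND	ND	generalized	indiscernible	c.3999_4005+4delinsAAAGGAGAGC	p.?	c.3999_4005+4delinsAAAGGAGAGC	p.?	ND	ND	No	No	No	No
M-2186	M-2186	F	EORD	Yes	0.5	1	7	76	generalized	indiscernible	c.1971del	p.Asn657Lysfs*8	c.1971del	p.Asn657Lysfs*8	2.3 (HM)	2.3 (HM)	No	No	No	ND
M-2184	M-2184	F	EORD	Yes	4	9	16	82	generalized	indiscernible	c.2401A>T	p.Lys801*	c.2843G>A	p.Cys948Tyr	1.0 (20/200)	1.3 (20/400)	Yes	Yes	Yes	Yes
XZ-301265-1	XZ-301265	F	EORD	Yes	5	26	31	60	generalized	indiscernible	c.2291G>A	p.Arg764His	c.2291G>A	p.Arg764His	2.3 (HM)	2.3 (HM)	No	No	No	No
XZ-301265-2	XZ-301265	M	EORD	Yes	ND	34	42	96	generalized	indiscernible	c.2291G>A	p.Arg764His	c.2291G>A	p.Arg764His	2.6 (LP)	2.6 (LP)	No	No	No	No
XZ-010621	XZ-010621	M	EORD	Yes	0.5	12	31	228	generalized	indiscernible	c.2843G>A	p.Cys948Tyr	c.2234C>A	p.Thr745Lys	0.7 (20/100)	0.5 (20/63)	No	No	No	Yes
XZ-344444	XZ-344444	F	EORD	Yes	0.5	28	30	24	generalized	indiscernible	c.506del	p.Gly169Valfs*3	c.2498G>A	p.Gly833Asp	2.6 (LP)	2.6 (LP)	Yes	No	No	No
M-1861	M-1861	M	EORD	No	5	17	ND	ND	generalized	indiscernible	c.54_55insT	p.Leu19Serfs*11	c.2639A>G	p.Asn880Ser	1.5 (20/600)	1.2 (20/320)	Yes	Yes	No	No
M-1732	M-1732	F	EORD	No	3	23.5	26.5	39	generalized	indiscernible	c.974G>T	p.Cys325Phe	c.2401A>T	p.Lys801*	0.7 (20/100)	0.7 (20/100)	Yes	No	No	No
M-3530	M-3530	M	RP	No	3	25	28	36	generalized	reduced	c.2234C>T	p.Thr745Met	c.2234C>T	p.Thr745Met	1.0 (20/200)	1.3 (20/400)	Yes	Yes	No	No
XZ-381491	XZ-381491	F	RP	No	9	26	27	12	generalized	reduced	c.3307G>A	p.Gly1103Arg	c.2843G>A	p.Cys948Tyr	0.6 (20/80)	0.9 (20/160)	No	No	No	No
M-731	M-731	M	RP	No	6	8	23	182	generalized	reduced	c.3308G>T	p.Gly1103Val	c.2290C>T	p.Arg764Cys	0.5 (20/63)	0.4 (20/50)	No	Yes	No	Yes
M-2804-1	M-2804	M	RP	No	9	9.5	12	32	generalized	reduced	c.2308G>A	p.Gly770Ser	c.2308G>A	p.Gly770Ser	0.4 (20/50)	0.3 (20/40)	No	No	No	Yes
M-2804-2	M-2804	F	RP	No	7	32	ND	ND	generalized	reduced	c.2308G>A	p.Gly770Ser	c.2308G>A	p.Gly770Ser	ND	ND	No	No	No	Yes
M-2121	M-2121	M	RP	No	14	17.5	21	37	generalized	reduced	c.613_619del	p.Ile205Aspfs*13	c.1817G>C	p.Cys606Ser	0.4 (20/50)	0.4 (20/50)	No	No	No	Yes
M-2415	M-2415	F	RP	No	6	23.5	28	54	generalized	reduced	c.2423A>G	p.Tyr808Cys	c.2843G>A	p.Cys948Tyr	0.2 (20/32)	0.2 (20/32)	Yes	No	No	Yes
M-699	M-699	F	RP	No	7	80	ND	ND	generalized	reduced	c.2290C>T	p.Arg764Cys	c.2290C>T	p.Arg764Cys	2.6 (LP)	2.6 (LP)	ND	ND	ND	ND
M-4075	M-4075	F	RP	No	6	7	ND	ND	generalized	reduced	c.653-1G>T	p.?	c.3299T>C	p.Ile1100Thr	0.4 (20/50)	0.1 (20/25)	No	No	No	Yes
M-4463	M-4463	F	RP	No	6	48	ND	ND	generalized	reduced	c.2843G>A	p.Cys948Tyr	c.2843G>A	p.Cys948Tyr	2.6 (LP)	2.6 (LP)	No	No	No	No
M-4570-1	M-4570	F	RP	No	6	10	12	29	generalized	reduced	c.2290C>T	p.Arg764Cys	c.2506C>A	p.Pro836Thr	0.2 (20/32)	0.5 (20/63)	No	No	No	Yes
M-3915	M-3915	M	RP	No	>5	61.5	ND	ND	generalized	reduced	c.3482A>G	p.Tyr1161Cys	c.613_619del	p.Ile205Aspfs*13	0.7 (20/100)	0.2 (20/32)	No	No	No	Yes
XZ-332989	XZ-332989	F	RP	No	5	7	16	108	generalized	reduced	c.2585T>G	p.Leu862Arg	c.2549G>C	p.Gly850Arg	0.6 (20/80)	0.6 (20/80)	No	No	No	Yes
L-93112991	L-93112991	M	MD	No	ND	44	ND	ND	macula_restricted	discernible	c.498_506del	p.Ile167_Gly169del	c.2843G>A	p.Cys948Tyr	0.5 (20/63)	0.7 (20/100)	No	No	No	ND
L-13010924	L-13010924	M	MD	No	22	23	28	60	macula_restricted	discernible	c.498_506del	p.Ile167_Gly169del	c.2843G>A	p.Cys948Tyr	0.6 (20/80)	0.2 (20/32)	No	No	No	No
M-1640-4	M-1640	F	MD	No	42	42	45	36	macula_restricted	discernible	c.1562C>T	p.Ala521Val	c.1562C>T	p.Ala521Val	0.7 (20/100)	1.0 (20/200)	No	No	No	No
M-3989	M-3989	M	MD	No	17	33	ND	ND	macula_restricted	discernible	c.498_506del	p.Ile167_Gly169del	c.2843G>A	p.Cys948Tyr	1.3 (20/400)	0.1 (20/25)	No	No	No	Yes
M-2183	M-2183	M	MD	No	21	33	ND	ND	macula_restricted	reduced	c.498_506del	p.Ile167_Gly169del	c.946T>C	p.Cys316Arg	2.3 (HM)	2.3 (HM)	No	No	No	No
M-3073-1	M-3073	M	MD	No	34	37	ND	ND	macula_restricted	discernible	c.498_506del	p.Ile167_Gly169del	c.2401A>T	p.Lys801*	0.5 (20/63)	0.4 (20/50)	No	No	No	No
M-3073-3	M-3073	F	MD	No	ND	46	ND	ND	macula_restricted	discernible	c.498_506del	p.Ile167_Gly169del	c.2401A>T	p.Lys801*	ND	ND	ND	ND	ND	ND
M-3377	M-3377	M	MD	No	40	53.5	ND	ND	macula_restricted	discernible	c.498_506del	p.Ile167_Gly169del	c.3014A>T	p.Asp1005Val	1.3 (20/400)	1.3 (20/400)	No	No	No	Yes
M-3343	M-3343	M	MD	No	16	29.5	ND	ND	macula_restricted	discernible	c.498_506del	p.Ile167_Gly169del	c.4142C>G	p.Pro1381Arg	0.4 (20/50)	0.7 (20/100)	No	No	No	No
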