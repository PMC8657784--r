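# Published per-allele isoform impacts and per-cell-type dosage labels for the
# 50-patient cohort, transcribed cell-for-cell.  Only typography was
# normalised at ingest (stray spaces inside HGVS strings removed); label text,
# including inconsistent hyphenation and capitalisation, is kept as printed.
# "?" means the published table left the impact undetermined.
patient_id	allele1	impact_a1	impact_b1	allele2	impact_a2	impact_b2	muller	photoreceptor
M-1640-1	p.Ala521Val	Laminin G-like 1	Laminin G-like 1	p.Ala521Val	Laminin G-like 1	Laminin G-like 1	100% mutated	100% mutated
M-2129	p.Thr745Met	Laminin G-like 2	Laminin G-like 2	p.Thr745Met	Laminin G-like 2	Laminin G-like 2	100% mutated	100% mutated
M-567	p.Arg764Cys	Laminin G-like 2	Laminin G-like 2	p.Ile482_Thr484del	Deletion between EGF-like 11 and Lam G-like 1	Deletion between EGF-like 11 and Lam G-like 1	100% mutated	100% mutated
M-116	p.Trp229*	NMD	WT	p.Ter1407Lysext*111	Cytoplasmic C-term	WT	50% mutated/0% WT	100% WT
M-3361	p.Arg764Cys	Laminin G-like 2	Laminin G-like 2	p.Arg764Cys	Laminin G-like 2	Laminin G-like 2	100% mutated	100% mutated
M-3591	p.Arg764Cys	Laminin G-like 2	Laminin G-like 2	p.Lys801*	NMD	NMD	50% mutated/0% WT	50% mutated/0% WT
M-2897	p.Gly850Ser	Laminin G-like 2	Laminin G-like 2	p.Cys948Tyr	EGF-like 14	EGF-like 14	100% mutated	100% mutated
M-3235	p.Arg764Cys	Laminin G-like 2	Laminin G-like 2	p.Leu1405Argfs*82	Cytoplasmic C-term	WT	100% mutated	50% mutated/50% WT
M-1316-4	p.Pro748Hisfs*6	NMD	NMD	p.Pro748Hisfs*6	NMD	NMD	No protein	No protein
M-340	p.Arg764Cys	Laminin G-like 2	Laminin G-like 2	p.Gly827*	NMD	NMD	50% mutated/0% WT	50% mutated/0% WT
L-15090708	p.Lys801*	NMD	NMD	p.Cys1238Phe	EGF-like-17	EGF-like-17	50% mutated/0% WT	50% mutated/0% WT
L-14061710	p.Gly850Ser	Laminin G-like 2	Laminin G-like 2	p.Pro1381Arg	Cytoplasmic C-term	WT	100% mutated	50% mutated/50% WT
XZ-372875	p.Cys1229Ser	EGF-like 19	EGF-like 19	p.Leu1107Pro	Laminin G-like 3	Laminin G-like 3	100% mutated	100% mutated
M-1316-1	p.Pro748Hisfs*6	NMD	NMD	p.Pro748Hisfs*6	NMD	NMD	No protein	No protein
M-3324	p.Gln362*	NMD	WT	p.Lys801*	NMD	NMD	No protein	0% mutated/50% WT
M-2427	p.Thr745Met	Laminin G-like 2	Laminin G-like 2	p.Ile1358Asn	Cytoplasmic C-term	WT	100% mutated	50% mutated/50% WT
M-4621-1	p.Pro1381Arg	Cytoplasmic C-term	WT	p.Pro1381Arg	Cytoplasmic C-term	WT	100% mutated	100% WT
M-1580	p.Val1055Glu	Laminin G-like 3	Laminin G-like 3	p.Leu1107Pro	Laminin G-like 3	Laminin G-like 3	100% mutated	100% mutated
M-2123	c.3999_4005+4delinsAAAGGAGAGC	?	Cytoplasmic C-term	c.3999_4005+4delinsAAAGGAGAGC	?	Cytoplasmic C-term	100% mutated	100% mutated
M-2123-2	c.3999_4005+4delinsAAAGGAGAGC	?	Cytoplasmic C-term	c.3999_4005+4delinsAAAGGAGAGC	?	Cytoplasmic C-term	100% mutated	100% mutated
M-2186	p.Asn657Lysfs*8	NMD	NMD	p.Asn657Lysfs*8	NMD	NMD	No protein	no protein
M-2184	p.Lys801*	NMD	NMD	p.Cys948Tyr	EGF-like 14	EGF-like 14	50% mutated/0% WT	50% mutated/0% WT
XZ-301265-1	p.Arg764His	Laminin G-like 2	Laminin G-like 2	p.Arg764His	Laminin G-like 2	Laminin G-like 2	100% mutated	100% mutated
XZ-301265-2	p.Arg764His	Laminin G-like 2	Laminin G-like 2	p.Arg764His	Laminin G-like 2	Laminin G-like 2	100% mutated	100% mutated
XZ-010621	p.Cys948Tyr	EGF-like 14	EGF-like 14	p.Thr745Lys	Laminin G-like 2	Laminin G-like 2	100% mutated	100% mutated
XZ-344444	p.Gly169Valfs*3	NMD	WT	p.Gly833Asp	Laminin G-like 2	Laminin G-like 2	50% mutated/0% WT	50% mutated/50% WT
M-1861	p.Leu19Serfs*11	NMD	WT	p.Asn880Ser	Laminin G-like 2	Laminin G-like 2	50% mutated/0% WT	50% mutated/50% WT
M-1732	p.Cys325Phe	EGF-like 8	WT	p.Lys801*	NMD	NMD	50% mutated/0% WT	0% mutated/50% WT
M-3530	p.Thr745Met	Laminin G-like 2	Laminin G-like 2	p.Thr745Met	Laminin G-like 2	Laminin G-like 2	100% mutated	100% mutated
XZ-381491	p.Gly1103Arg	Laminin G-like 3	Laminin G-like 3	p.Cys948Tyr	EGF-like 14	EGF-like 14	100% mutated	100% mutated
M-731	p.Gly1103Val	Laminin G-like 3	Laminin G-like 3	p.Arg764Cys	Laminin G-like 2	Laminin G-like 2	100% mutated	100% mutated
M-2804-1	p.Gly770Ser	Laminin G-like 2	Laminin G-like 2	p.Gly770Ser	Laminin G-like 2	Laminin G-like 2	100% mutated	100% mutated
M-2804-2	p.Gly770Ser	Laminin G-like 2	Laminin G-like 2	p.Gly770Ser	Laminin G-like 2	Laminin G-like 2	100% mutated	100% mutated
M-2121	p.Ile205Aspfs*13	NMD	WT	p.Cys606Ser	Laminin G-like 1	Laminin G-like 1	50% mutated/0% WT	50% mutated/50% WT
M-2415	p.Tyr808Cys	Laminin G-like 2	Laminin G-like 2	p.Cys948Tyr	EGF-like 14	EGF-like 14	100% mutated	100% mutated
M-699	p.Arg764Cys	Laminin G-like 2	Laminin G-like 2	p.Arg764Cys	Laminin G-like 2	Laminin G-like 2	100% mutated	100% mutated
M-4075	c.653-1G>T	?	WT	p.Ile1100Thr	Laminin G-like 3	Laminin G-like 3	Unknown	50% mutated/50% WT
M-4463	p.Cys948Tyr	EGF-like 14	EGF-like 14	p.Cys948Tyr	EGF-like 14	EGF-like 14	100% mutated	100% mutated
M-4570-1	p.Arg764Cys	Laminin G-like 2	Laminin G-like 2	p.Pro836Thr	Laminin G-like 2	Laminin G-like 2	100% mutated	100% mutated
M-3915	p.Tyr1161Cys	EGF-like 15	EGF-like 15	p.Ile205Aspfs*13	NMD	WT	50% mutated/0% WT	50% mutated/50% WT
XZ-332989	p.Leu862Arg	Laminin G-like 2	Laminin G-like 2	p.Gly850Arg	Laminin G-like 2	Laminin G-like 2	100% mutated	100% mutated
L-93112991	p.Ile167_Gly169del	EGF-like 4	WT	p.Cys948Tyr	EGF-like 14	EGF-like 14	100% mutated	50% mutated/50% WT
L-13010924	p.Ile167_Gly169del	EGF-like 4	WT	p.Cys948Tyr	EGF-like 14	EGF-like 14	100% mutated	50% mutated/50% WT
M-1640-4	p.Ala521Val	Laminin G-like 1	Laminin G-like 1	p.Ala521Val	Laminin G-like 1	Laminin G-like 1	100% mutated	100% mutated
M-3989	p.Ile167_Gly169del	EGF-like 4	WT	p.Cys948Tyr	EGF-like 14	EGF-like 14	100% mutated	50% mutated/50% WT
M-2183	p.Ile167_Gly169del	EGF-like 4	WT	p.Cys316Arg	EGF-like 8	WT	100% mutated	100% WT
M-3073-1	p.Ile167_Gly169del	EGF-like 4	WT	p.Lys801*	NMD	NMD	50% mutated/0% WT	0% mutated/50% WT
M-3073-3	p.Ile167_Gly169del	EGF-like 4	WT	p.Lys801*	NMD	NMD	50% mutated/0% WT	0% mutated/50% WT
M-3377	p.Ile167_Gly169del	EGF-like 4	WT	p.Asp1005Val	Laminin G-like 3	Laminin G-like 3	100% mutated	50% mutated/50% WT
M-3343	p.Ile167_Gly169del	EGF-like 4	WT	p.Pro1381Arg	Cytoplasmic C-term	WT	100% mutated	100% WT
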