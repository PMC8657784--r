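# Published table of the 17 novel CRB1 variants: cDNA/protein relative to
# NM_201253.3, exon number, variant type and impacted domain in the canonical
# protein, transcribed as printed (HGVS whitespace normalised at ingest).
# Domain "ND" = not determined in the published table (the in-frame deletion
# p.Ile482_Thr484del falls between EGF-like 11 and laminin G-like 1).
cdna	protein	exon	type	acmg	domain
c.54_55insT	p.Leu19Serfs*11	1	Indel	P	Signal peptide
c.687G>A	p.Trp229*	3	Nonsense	P	EGF-like-6
c.946T>C	p.Cys316Arg	4	Missense	LP	EGF-like-8
c.974G>T	p.Cys325Phe	4	Missense	LP	EGF-like-8
c.1445_1453del	p.Ile482_Thr484del	6	Del	LP	ND
c.1562C>T	p.Ala521Val	6	Missense	LP	Laminin G-like-1
c.1817G>C	p.Cys606Ser	6	Missense	LP	Laminin G-like-1
c.1971del	p.Asn657Lysfs*8	6	Del	P	Laminin G-like-1
c.2243del	p.Pro748Hisfs*6	7	Del	P	Laminin G-like-2
c.2423A>G	p.Tyr808Cys	7	Missense	LP	Laminin G-like-2
c.2549G>C	p.Gly850Arg	7	Missense	LP	Laminin G-like-2
c.2585T>G	p.Leu862Arg	7	Missense	LP	Laminin G-like-2
c.3164T>A	p.Val1055Glu	9	Missense	LP	Laminin G-like-3
c.3713G>T	p.Cys1238Phe	9	Missense	LP	EGF-like-17
c.3999_4005+4delinsAAAGGAGAGC	p.?	11	Indel	P	EGF-like-18/TM domain
c.4214del	p.Leu1405Argfs*82	12	Del	LP	Intracellular tail
c.4219T>A	p.Ter1407Lysext*111	12	Stop loss	LP	Intracellular tail
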