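# Published residue -> domain facts (impact and novel-variant tables) that
# the packaged domain map must satisfy; labels are compared after
# typography normalisation.
residue	expected
19	signal peptide
167	EGF-like 4
169	EGF-like 4
229	EGF-like 6
316	EGF-like 8
325	EGF-like 8
521	Laminin G-like 1
606	Laminin G-like 1
657	Laminin G-like 1
745	Laminin G-like 2
748	Laminin G-like 2
764	Laminin G-like 2
770	Laminin G-like 2
801	Laminin G-like 2
808	Laminin G-like 2
827	Laminin G-like 2
833	Laminin G-like 2
836	Laminin G-like 2
850	Laminin G-like 2
862	Laminin G-like 2
880	Laminin G-like 2
948	EGF-like 14
1005	Laminin G-like 3
1055	Laminin G-like 3
1100	Laminin G-like 3
1103	Laminin G-like 3
1107	Laminin G-like 3
1161	EGF-like 15
1229	EGF-like 19
1238	EGF-like 17
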