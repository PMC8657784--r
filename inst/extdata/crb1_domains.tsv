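# CRB1 isoform-A protein domain map, residues 1..1406 (canonical numbering).
# Reconstructed (synthetic boundaries): anchored on the published per-residue
# assignments (167-169 EGF-like 4; 229 EGF-like 6; 316/325 EGF-like 8;
# 482-484 between EGF-like 11 and laminin G-like 1; 521/606/657 laminin
# G-like 1; 745-880 laminin G-like 2; 948 EGF-like 14; 1005-1107 laminin
# G-like 3; 1161 EGF-like 15; 1229 EGF-like 19) with interpolated boundaries
# elsewhere.  Gaps between annotated modules carry kind "inter-domain".
# See crb1_domain_overrides.tsv for published labels that conflict with a
# monotone numbering.
name	kind	start_res	end_res
signal peptide	signal	1	24
EGF-like 1	EGF	25	62
EGF-like 2	EGF	63	100
EGF-like 3	EGF	101	138
EGF-like 4	EGF	139	177
EGF-like 5	EGF	178	216
EGF-like 6	EGF	217	254
EGF-like 7	EGF	255	292
EGF-like 8	EGF	293	330
EGF-like 9	EGF	331	368
EGF-like 10	EGF	369	406
EGF-like 11	EGF	407	444
inter-domain	inter-domain	445	489
Laminin G-like 1	LamG	490	660
EGF-like 12	EGF	661	698
Laminin G-like 2	LamG	699	890
EGF-like 13	EGF	891	928
EGF-like 14	EGF	929	966
Laminin G-like 3	LamG	967	1130
EGF-like 15	EGF	1131	1168
EGF-like 16	EGF	1169	1196
EGF-like 17	EGF	1197	1214
EGF-like 18	EGF	1215	1222
EGF-like 19	EGF	1223	1260
inter-domain	inter-domain	1261	1345
transmembrane	TM	1346	1368
cytoplasmic C-term	cytoplasmic	1369	1406
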