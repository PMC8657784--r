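# CRB1 NM_201253.3 coding-exon table, HGVS c. coordinates (1-based, closed).
# Reconstructed (synthetic boundaries): junctions are constrained by the
# published variant-to-exon assignments (exon 2|3 junction at c.652|653, donor
# after c.4005 closes exon 11, c.55 in exon 1, c.498-619 in exon 2, c.687 in
# exon 3, c.946-974 in exon 4, c.1445-1971 in exon 6, c.2243-2585 in exon 7,
# c.3164/c.3713 in exon 9, c.4214/c.4219 in exon 12); boundaries that no
# published variant pins down are interpolated.
exon	cdna_start	cdna_end
1	1	160
2	161	652
3	653	750
4	751	1029
5	1030	1380
6	1381	2128
7	2129	2800
8	2801	2842
9	2843	3879
10	3880	3940
11	3941	4005
12	4006	4221
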