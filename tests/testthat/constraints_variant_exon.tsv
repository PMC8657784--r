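# Published variant-position -> exon facts that any packaged exon table must
# satisfy (novel-variant table, junction facts from the splice variant and
# the exon-11 donor indel, and the exon assignments quoted in the text).
pos	offset	expected
55	0	exon 1
498	0	exon 2
506	0	exon 2
613	0	exon 2
619	0	exon 2
652	0	exon 2
653	0	exon 3
653	-1	intron 2
687	0	exon 3
946	0	exon 4
974	0	exon 4
1445	0	exon 6
1562	0	exon 6
1817	0	exon 6
1971	0	exon 6
2243	0	exon 7
2423	0	exon 7
2549	0	exon 7
2585	0	exon 7
3164	0	exon 9
3713	0	exon 9
3999	0	exon 11
4005	0	exon 11
4005	1	intron 11
4006	0	exon 12
4073	0	exon 12
4142	0	exon 12
4214	0	exon 12
4219	0	exon 12
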