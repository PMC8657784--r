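# CRB1 retinal isoforms, inclusion intervals in canonical (isoform A) HGVS c.
# coordinates.  Isoform A (Muller glia) spans the full CDS; isoform B
# (photoreceptors) starts inside exon 5 ("exon 5c", its own promoter and
# N-terminus) and ends with the coding part of exon 11 plus a B-specific
# C-terminus; isoform C is secreted (no transmembrane/cytoplasmic part).
# The 5c start coordinate is not published: it is placed at c.1093, the only
# hard constraints being c.1084 < start <= start of exon 6 (c.1381).
name	cell_type	protein_length	incl_start	incl_end
A	Muller	1406	1	4221
B	photoreceptor	1003	1093	4005
C	secreted	754	1	2262
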