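# Published per-residue domain labels that cannot be reconciled with a single
# monotone domain table (the published EGF numbering near the C-terminus is
# internally inconsistent: residue 1229 is labelled EGF-like 19 while the
# downstream residue 1238 is labelled EGF-like 17, and the exon-11 region
# around residue 1333 is labelled EGF-like 18/TM).  Both the base-table label
# and the published label are retained; domainOf() reports the published one.
start_res	end_res	label	note
1238	1238	EGF-like 17	published label for p.Cys1238Phe; base table assigns EGF-like 19
1327	1340	EGF-like 18/TM domain	published label for the exon-11 indel region; base table assigns inter-domain
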