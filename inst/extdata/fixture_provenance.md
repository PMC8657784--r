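# Fixture provenance and normalisation notes

The cohort roster, expected isoform-impact table, novel-variant table and OCT
reference parameters are transcriptions of published per-patient tables for a
50-patient CRB1 cohort.  The following normalisations and annotations were
applied at transcription time (the HGVS parser itself is strict and performs
no cleanup):

## HGVS string normalisation
- `c.2843G> A`, `p. Cys948Tyr` (stray spaces): whitespace removed.
- `c.3999_4005 + 4delinsAAAGGAGAGC`: spaces around `+` removed.
- `c.653-1G > T`: spaces around `>` removed.
- `c.3299>C` (reference base omitted in print): recorded as `c.3299T>C`,
  forced by the protein annotation p.Ile1100Thr (ATT/ATC -> ACT/ACC requires
  T>C at the second codon position, c.3299).
- `p.Pro748Hisfs*67` (one row of the homozygous pair): recorded as
  `p.Pro748Hisfs*6`, the annotation used for the same allele everywhere else.
- `p.cys1229Ser`: capitalised to `p.Cys1229Ser`.

## Fields not printed per patient
- `family_id`: the publication does not print a family column; IDs are
  derived by stripping the sibling suffix from the patient ID
  (M-1640-1/M-1640-4 -> M-1640, etc.).  This yields 44 distinct families
  against the published count of 45; the pipeline reports the difference in
  its discrepancy log rather than forcing agreement.
- `topography`: `macula_restricted` for the macular-dystrophy group
  (lesions restricted to the posterior pole by that group's definition),
  `generalized` otherwise.
- `erg`: full-field ERG severity is described in the text but not printed as
  a per-patient column.  Values here are fixture annotations encoding the
  described severity (EORD ~ indiscernible, RP ~ reduced, MD ~ discernible;
  M-2183's reduced rod/cone responses are described explicitly).  They are
  consumed only by the onset-age tie-break in phenotype classification.
- `onset_age` is kept as printed, including the bounds `<5` and `>5` and the
  missing marker `ND`.

## Genotype of M-2427
The clinical table prints M-2427 as homozygous for c.4073T>A
p.(Ile1358Asn), while the genetic/impact table lists the genotype
p.Thr745Met / p.Ile1358Asn.  The roster follows the genetic table
(allele 1 = c.2234C>T p.Thr745Met): a homozygous exon-12 genotype would
leave isoform B wild type and contradict the published statement that
exactly two early-onset patients express wild-type isoform B.

## Known internal inconsistencies carried as-is
- Patient M-3530 (RP) has printed onset age 3, which contradicts the
  published classification rule (onset before 5 -> early-onset group); the
  roster keeps both values and the pipeline logs the discordance.
- Domain labels for residues 1229 (EGF-like 19) and 1238 (EGF-like 17) are
  mutually inconsistent with a monotone domain order; both published labels
  are preserved (see crb1_domain_overrides.tsv).
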