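---
title: "Isoform-resolved interpretation of CRB1 genotypes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoform-resolved interpretation of CRB1 genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crb1iso)
```

## The interpretation model

*CRB1* encodes an apical polarity protein of the retinal CRB complex.  Two
retinal isoforms matter for genotype interpretation: the canonical
**isoform A** of Müller glial cells (1406 residues, 12 exons, 19 EGF-like
and 3 laminin G-like extracellular modules, a transmembrane segment and a
PDZ-interacting cytoplasmic tail) and the short photoreceptor **isoform B**
(1003 residues), which shares the canonical reading frame from a point
inside exon 5 ("exon 5c") through the coding end of exon 11 and carries its
own termini.  Because the two isoforms share most — but not all — of the
coding sequence, a single allele can be simultaneously deleterious for one
cell type and silent for the other.

The package evaluates a biallelic genotype in three steps.

1. **Per-allele consequence.**  Each allele's HGVS cDNA and protein
   descriptions are parsed and cross-checked by codon arithmetic
   (`residueOf(pos) = ceiling(pos/3)`; exact for single-codon changes, one
   codon of slack for indels whose HGVS form is 3'-shifted).  The class is
   taken from the protein annotation when present, otherwise derived (net
   indel length modulo 3; ±1/±2 offsets are splice-region changes).

2. **Per-isoform product state.**  A variant that does not overlap an
   isoform's inclusion interval leaves that isoform *wild type*.  A
   premature stop (nonsense or frameshift) inside the isoform makes the
   product *absent* when nonsense-mediated decay (NMD) is predicted, and an
   *altered* C-terminal product otherwise.  NMD follows the
   penultimate-exon rule applied per isoform: decay is presumed when the
   stop lies in an exon strictly before the penultimate exon of that
   isoform's own exon sequence — exons 1–10 for isoform A (penultimate =
   11), and exons up to 9 for isoform B, whose seven exons run 5c, 6, …,
   11 (penultimate = 10).  We deliberately apply the rule to each isoform's
   exon list rather than re-using the canonical exon count for both; no
   cohort variant falls in exon 10, so the two readings cannot be
   distinguished by the packaged data, but the per-isoform reading is the
   faithful one.  Splice-region changes are *unknown*, with one documented
   exception: a deletion–insertion that spans a donor site but whose
   exonic part lies inside the isoform still produces a (damaged) protein
   and is treated as *altered* — this is required for the recurrent
   exon-11 delins, which homozygous carriers express as "100% mutated" in
   both cell types.

3. **Dosage.**  Each allele contributes half of a cell type's protein
   pool; an absent (decayed) allele contributes nothing; any unknown
   allele makes the pool unknown.  The resulting labels are categorical
   ("50% mutated/0% WT", "No protein", …), not quantitative expression
   estimates — no attempt is made to model expression gradients across the
   retina.  Müller-cell dosage follows isoform A, photoreceptor dosage
   isoform B.

The frameshift stop position is approximated by the variant's own exon:
locating the true downstream termination codon would require the mRNA
sequence, which the package deliberately does not carry.  This matches
established clinical practice for this gene and is a documented
limitation; the 55-nt refinement of the NMD boundary rule is likewise out
of scope.

## The packaged transcript and domain model

Exon boundaries and domain limits are stored as plain TSV files and
loaded into a validated S4 `TranscriptModel`.  The exon table is a
*constrained reconstruction*: every junction that a published variant
pins down is honoured exactly (the exon 2|3 junction at c.652|653 fixed by
the acceptor variant c.653-1G>T, the exon-11 donor after c.4005 fixed by
the c.3999_4005+4 delins, the exon memberships of all tabulated variants),
and boundaries between those anchors are interpolated.  The same applies
to the domain map, which is anchored on every published residue→domain
assignment.  Users with an authoritative exon or domain table can drop in
replacement files (`loadTranscriptModel()` arguments, or the CLI's
`--transcript-model`); all published-fact constraints are re-checked by
the test suite against whatever model is loaded.

Two published domain labels cannot coexist in a monotone domain table:
residue 1229 is labelled EGF-like 19 while the *downstream* residue 1238
is labelled EGF-like 17 (twice, in two independent tables), and the
exon-11 region near residue 1333 is labelled "EGF-like 18/TM".  Rather
than silently picking a side, the model keeps a monotone base table plus a
published-label override list; `domainOf()` reports the published label,
and both labels remain visible in the model files.

The isoform-B start coordinate ("exon 5c") was never published.  It is
placed at c.1093, the only hard constraints being that it must lie after
c.1084 (a nonsense variant there leaves isoform B wild type) and at or
before the start of exon 6 (missense variants from c.1445 onward affect
isoform B).  The placement is configurable and validity-checked.

## The cohort fixture and its discrepancy log

The packaged roster transcribes the published 50-patient tables; the
transcription notes (whitespace normalisation of HGVS strings, the one
genotype conflict between the clinical and genetic tables, the derivation
of family IDs and ERG severities) live in
`inst/extdata/fixture_provenance.md`.

Phenotype classification implements the published rule with the precedence
**topography > onset threshold > ERG severity**: macula-restricted disease
is MD regardless of onset; otherwise onset before 5 years gives EORD and
later onset RP; an onset exactly at the boundary, or missing, falls back
to ERG severity (indiscernible → EORD).  One roster patient (printed label
RP, printed onset 3 years) contradicts the rule; the classifier does not
special-case it — the discordance is surfaced in the report's discrepancy
log, and the census counts tally the printed labels, as the source tables
themselves do.

Several published summary figures cannot be recomputed from the published
patient-level tables: the distinct-variant total (43 distinct cDNA strings
vs a published 41; 28 distinct missense vs 26 — recurrent codons appear to
have been collapsed, so a codon-collapsed census is reported alongside),
the family count (the roster contains six sibling pairs, implying 44
families against a published 45), the EORD decay-carrier fraction, the
biallelic-missense counts and the mean macular onset age.  The pipeline's
policy is uniform: report the faithful recomputation *and* the published
figure side by side in `cohortReport()$discrepancies`, never force
agreement.

The OCT thickness table is the opposite case: the per-eye raw measurements
behind it were never published, so its means and SDs are *not*
recomputable and serve purely as simulation parameters for the generator
(below).  `octSummarize()` reports a missing SD for single-eye cells, as
the published table does.

## The synthetic generator

`generateCohort()` emulates the statistical structure the analysis
assumes, so that every pipeline stage can be tested end to end without
real data:

- genotypes are two weighted draws from a variant pool (default: the
  cohort's distinct variants at their observed allele frequencies), with a
  homozygosity boost of 0.3 by default — the cohort is ascertained, not
  population-based (18/50 patients are homozygous), so no Hardy–Weinberg
  or explicit consanguinity structure is imposed;
- the generating phenotype follows a deterministic rule — any allele equal
  to the exon-2 in-frame deletion c.498_506del gives MD; otherwise two
  truncating alleles give EORD; two missense alleles give RP; mixed pairs
  track the severe (EORD) group — optionally flipped to another label with
  probability `phenotypeRuleNoise`;
- clinical fields are drawn conditional on the final label: topography
  (macula-restricted iff MD), onset uniform in the published group ranges
  (EORD [0.4, 5), RP [5, 15), MD [16, 42] years — ranges, not
  distributions, were published, so uniform is the least-informative
  choice), ERG severity by group, fundus flags at the cohort prevalences
  (drusen 12/50, PPARPE 14/50, Coats-like 1/50, edema 17/50);
- OCT thicknesses are Normal draws with the published per-cell mean/SD.

Because clinical fields are generated from the final label, a noiseless
cohort is *exactly* recoverable by the classification rule, and the
per-patient dosage truth equals a re-annotation of the generated roster —
these closed-loop identities are what the recovery tests assert.  What the
generator does **not** emulate: real linkage between genotype and onset
within a group, intrafamilial correlation, measurement noise in HGVS
strings, longitudinal change, or ERG waveforms.  Passing recovery tests
therefore validate the pipeline's internal consistency, not its behaviour
on messy real-world rosters.

## Numerical and engineering choices

- **Tie-breaks.** Onset exactly at the 5-year cutoff resolves by ERG
  severity; an unresolvable record returns an explicit "unclassified",
  never a silent default.
- **Degenerate inputs.** Empty cohort files, schema violations, unknown
  isoforms, out-of-CDS positions, all-zero contingency tables and
  unparameterised OCT cells all raise classed errors (`crbLoadError`,
  `crbRangeError`, `crbStatError`, `crbConfigError`, …); parse errors
  carry the offending string, and genotype-level errors are prefixed with
  the patient context.
- **Exact test.** `fisherExact2x2()` delegates to `stats::fisher.test()`;
  the test suite checks it against an independent brute-force
  hypergeometric enumeration for every 2×2 table with total ≤ 30
  (46,375 tables), using the standard 1 + 1e-7 relative guard on the
  "as-extreme" likelihood criterion to absorb floating ties.
- **Determinism.** The analytic path contains no randomness — the JSON
  report is byte-stable across runs — and every stochastic component
  (synthetic cohorts, OCT draws) is driven by an explicit integer seed.
- **Label comparison.** Golden comparisons against the transcribed tables
  normalise typography only (case, hyphen/underscore, the "Lam"/"Laminin"
  abbreviation and the "Intracellular tail"/"cytoplasmic C-term" synonym);
  label *content*, including the internally inconsistent EGF numbering, is
  compared verbatim.
- **Problem sizes.** The closed-loop recovery tests run at 200–1000
  synthetic patients and the OCT convergence check at 10,000 draws —
  large enough that the binomial/standard-error bands are tight, small
  enough that the whole suite stays fast on a single CPU.
- **No reference sequence.** Variants are not validated against the mRNA
  (no ref-base checking, no frameshift stop localisation); genomic
  coordinates, strand handling and liftover are out of scope, and the VCF
  export therefore declares an explicitly non-genomic CDS contig.

## Known limitations

- The exon and domain boundaries between published anchors are
  interpolations; analyses that depend on an unanchored boundary (none of
  the packaged tabulations do) need an authoritative replacement model.
- NMD prediction is the bare penultimate-exon rule: no 55-nt boundary
  refinement, no splice-strength or escape modelling; splice variants
  other than the documented delins remain "unknown".
- Dosage labels are categorical by design and do not model allelic
  expression imbalance or the isoform-B outer-segment gradient.
- Isoform C (the secreted 754-residue form) is carried in the model but
  not used by the dosage calculus; no cohort variant is C-specific.
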