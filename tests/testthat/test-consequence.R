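test_that("consequence classes follow the protein annotation", {
  q <- classifyConsequence(crbModel, "c.498_506del", "p.Ile167_Gly169del")
  expect_identical(q@klass, "in-frame indel")
  expect_identical(q@deletedResidues, 3L)

  q <- classifyConsequence(crbModel, "c.4219T>A", "p.Ter1407Lysext*111")
  expect_identical(q@klass, "stop-loss extension")
  expect_identical(q@extensionLength, 110L)

  q <- classifyConsequence(crbModel, "c.653-1G>T", "p.?")
  expect_identical(q@klass, "splice")

  q <- classifyConsequence(crbModel, "c.613_619del", "p.Ile205Aspfs*13")
  expect_identical(q@klass, "frameshift")
  expect_identical(q@ptcExon, 2L)
})

test_that("classes derive arithmetically when no protein annotation given", {
  expect_identical(classifyConsequence(crbModel, "c.613_619del")@klass,
                   "frameshift")              # 7 nt removed
  expect_identical(classifyConsequence(crbModel, "c.498_506del")@klass,
                   "in-frame indel")          # 9 nt removed
  expect_identical(classifyConsequence(crbModel, "c.653-1G>T")@klass,
                   "splice")
  expect_identical(classifyConsequence(crbModel, "c.2290C>T")@klass,
                   "unknown")                 # substitution needs protein
})

test_that("cDNA/protein inconsistency is rejected", {
  expect_error(classifyConsequence(crbModel, "c.2290C>T", "p.Ala521Val"),
               class = "crbConsistencyError")
})

test_that("decay prediction follows the penultimate-exon rule per isoform", {
  nonsense7 <- classifyConsequence(crbModel, "c.2401A>T", "p.Lys801*")
  expect_identical(predictNmd(crbModel, "A", nonsense7), "yes")
  expect_identical(predictNmd(crbModel, "B", nonsense7), "yes")

  fs12 <- classifyConsequence(crbModel, "c.4214del", "p.Leu1405Argfs*82")
  expect_identical(predictNmd(crbModel, "A", fs12), "no")
  expect_identical(predictNmd(crbModel, "B", fs12), "not_applicable")

  ext <- classifyConsequence(crbModel, "c.4219T>A", "p.Ter1407Lysext*111")
  expect_identical(predictNmd(crbModel, "A", ext), "not_applicable")

  # nonsense in exon 3: decays A, lies outside B entirely
  ns3 <- classifyConsequence(crbModel, "c.687G>A", "p.Trp229*")
  expect_identical(predictNmd(crbModel, "A", ns3), "yes")
  expect_identical(predictNmd(crbModel, "B", ns3), "not_applicable")

  spl <- classifyConsequence(crbModel, "c.653-1G>T", "p.?")
  expect_identical(predictNmd(crbModel, "A", spl), "unknown")
})

test_that("decay is never predicted for a last-exon stop, any isoform", {
  # synthetic frameshifts walked across every exon
  ex <- exons(crbModel)
  for (k in ex$exon) {
    pos <- ex$cdna_start[k]
    q <- new("Consequence", klass = "frameshift", exon = k,
             startRes = residueOf(pos), endRes = residueOf(pos),
             deletedResidues = NA_integer_, extensionLength = NA_integer_,
             ptcExon = k, spansDonor = FALSE, spansAcceptor = FALSE)
    for (iso in c("A", "B")) {
      isoEx <- crb1iso:::.isoformExons(crbModel, iso)
      if (k == isoEx[length(isoEx)])
        expect_false(predictNmd(crbModel, iso, q) == "yes")
    }
  }
})

test_that("per-isoform impact reproduces the published example alleles", {
  impactPair <- function(cdna, protein) {
    cv <- parseCdna(cdna)
    q <- classifyConsequence(crbModel, cv,
                             if (is.na(protein)) NULL else protein)
    list(A = impactOnIsoform(crbModel, cv, q, "A"),
         B = impactOnIsoform(crbModel, cv, q, "B"))
  }
  r <- impactPair("c.687G>A", "p.Trp229*")
  expect_identical(r$A$productState, "absent")
  expect_identical(r$B$productState, "wild_type")

  r <- impactPair("c.4142C>G", "p.Pro1381Arg")
  expect_identical(r$A$productState, "altered")
  expect_identical(r$A$regionLabel, "Cytoplasmic C-term")
  expect_identical(r$B$productState, "wild_type")

  r <- impactPair("c.2843G>A", "p.Cys948Tyr")
  expect_identical(r$A$regionLabel, "EGF-like 14")
  expect_identical(r$B$regionLabel, "EGF-like 14")

  # donor-spanning delins: altered on both isoforms, B label is terminal
  r <- impactPair("c.3999_4005+4delinsAAAGGAGAGC", "p.?")
  expect_identical(r$A$productState, "altered")
  expect_identical(r$A$regionLabel, "?")
  expect_identical(r$B$productState, "altered")
  expect_identical(r$B$regionLabel, "Cytoplasmic C-term")

  # acceptor splice: undetermined for A, untouched B
  r <- impactPair("c.653-1G>T", "p.?")
  expect_identical(r$A$productState, "unknown")
  expect_identical(r$B$productState, "wild_type")

  # in-frame deletion between annotated modules
  r <- impactPair("c.1445_1453del", "p.Ile482_Thr484del")
  expect_identical(normLabel(r$A$regionLabel),
                   normLabel("Deletion between EGF-like 11 and Lam G-like 1"))
})

test_that("no wild-type call for isoform B overlaps its inclusion interval", {
  # cross-check of inIsoform and impact over all cohort alleles
  tab <- distinctVariantTable(crbAnnotated)
  for (i in seq_len(nrow(tab))) {
    cv <- parseCdna(tab$cdna[i])
    if (tab$state_B[i] == "WT")
      expect_false(inIsoform(crbModel, "B", cv@start, cv@end),
                   info = tab$cdna[i])
  }
})
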