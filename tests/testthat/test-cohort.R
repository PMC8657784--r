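test_that("the packaged roster loads with 50 patients and strict schema", {
  expect_identical(nrow(crbCohort), 50L)
  expect_identical(length(unique(crbCohort$family_id)), 44L)
  expect_identical(sum(crbCohort$sex == "M"), 25L)
  expect_identical(as.vector(table(crbCohort$phenotype)[c("EORD", "RP", "MD")]),
                   c(28L, 13L, 9L))

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("patient_id", empty)
  expect_error(loadCohort(empty), class = "crbLoadError")

  bad <- withr::local_tempfile(fileext = ".tsv")
  write.table(crbCohort[, setdiff(names(crbCohort), "allele2_cdna")], bad,
              sep = "\t", quote = FALSE, row.names = FALSE)
  err <- tryCatch(loadCohort(bad), crbError = identity)
  expect_s3_class(err, "crbLoadError")
  expect_match(conditionMessage(err), "allele2_cdna")
})

test_that("phenotype rule matches the printed labels except one known case", {
  rule <- classifyPhenotype(crbCohort)
  expect_false(any(rule == "unclassified"))
  concordant <- rule == crbCohort$phenotype
  expect_identical(sum(concordant), 49L)
  # the single discordance: printed RP with an onset below the cutoff
  expect_identical(crbCohort$patient_id[!concordant], "M-3530")
  # spot checks of the three group definitions
  one <- function(onset, topo, erg = "reduced") {
    classifyPhenotype(data.frame(topography = topo, onset_age = onset,
                                 erg = erg, stringsAsFactors = FALSE))
  }
  expect_identical(one("1.5", "generalized", "indiscernible"), "EORD")
  expect_identical(one("9", "generalized"), "RP")
  expect_identical(one("22", "macula_restricted"), "MD")
  # boundary onset resolved by ERG severity; unresolvable stays explicit
  expect_identical(one("5", "generalized", "indiscernible"), "EORD")
  expect_identical(one("5", "generalized", "reduced"), "RP")
  expect_identical(one("ND", "generalized", "not_done"), "unclassified")
})

test_that("variant census counts distinct variants and classes", {
  cen <- variantCensus(crbAnnotated)
  expect_identical(cen$distinctVariants, 43L)
  expect_identical(cen$byClass$indel, 9L)
  expect_identical(cen$byClass$nonsense, 4L)
  expect_identical(cen$byClass$splice, 1L)
  expect_identical(cen$byClass$`stop-loss`, 1L)
  expect_identical(cen$byClass$missense, 28L)
  # codon-collapsed census merges the four recurrent codons (745, 764,
  # 850, 1103)
  expect_identical(cen$codonCollapsed$distinctVariants, 39L)
  expect_identical(cen$codonCollapsed$byClass$missense, 24L)
  # permutation invariance
  shuffled <- crbAnnotated[rev(seq_len(nrow(crbAnnotated))), ]
  cen2 <- variantCensus(shuffled)
  expect_identical(cen2$distinctVariants, cen$distinctVariants)
  expect_identical(cen2$byClass, cen$byClass)
  # empty cohort gives all zeros
  cen0 <- variantCensus(crbAnnotated[0, ])
  expect_identical(cen0$distinctVariants, 0L)
  expect_identical(cen0$nPatients, 0L)
})

test_that("codon carrier counts distinguish carriers from homozygotes", {
  expect_identical(carriersAtCodon(crbAnnotated, 764L), 10L)
  expect_identical(carriersAtCodon(crbAnnotated, 764L,
                                   homozygousOnly = TRUE), 4L)
  expect_identical(carriersAtCodon(crbAnnotated, 500L), 0L)
  # the in-frame deletion spans residues 167-169: interval matching
  expect_identical(carriersAtCodon(crbAnnotated, 168L), 8L)
})

test_that("biallelic-truncating and isoform-B cross-tabs match the tables", {
  expect_identical(countBiallelicTruncating(crbAnnotated, "EORD"), 7L)
  expect_identical(countBiallelicTruncating(crbAnnotated, "RP"), 0L)
  expect_identical(countBiallelicTruncating(crbAnnotated, "MD"), 0L)
  expect_identical(countWtIsoformB(crbAnnotated, "EORD"), 2L)
  expect_identical(countWtIsoformB(crbAnnotated, "MD"), 2L)
  expect_identical(countWtIsoformB(crbAnnotated, "RP"), 0L)
  expect_identical(exonPredicateCount(crbAnnotated, "RP", c(4L, 12L)), 0L)
  expect_identical(exonPredicateCount(crbAnnotated, "MD", 2L), 8L)
  expect_identical(exonPredicateCount(crbAnnotated, "EORD", integer()), 0L)
})

test_that("clinical tallies count the fundus flags and edema by decade", {
  t <- clinicalTallies(crbCohort)
  expect_identical(t$drusen, 12L)
  expect_identical(t$pparpe, 14L)
  expect_identical(t$coats, 1L)
  expect_identical(sum(t$edemaByDecade$n), t$edema)
  allNo <- crbCohort
  allNo[c("drusen", "pparpe", "coats", "edema")] <- "No"
  t0 <- clinicalTallies(allNo)
  expect_identical(unlist(t0[c("drusen", "pparpe", "coats", "edema")]),
                   c(drusen = 0L, pparpe = 0L, coats = 0L, edema = 0L))
})

test_that("Fisher exact p-values match brute-force enumeration", {
  expect_error(fisherExact2x2(matrix(0, 2, 2)), class = "crbStatError")
  expect_equal(fisherExact2x2(matrix(c(0, 5, 0, 5), 2, 2)), 1)
  expect_equal(fisherExact2x2(matrix(c(1, 0, 0, 1), 2, 2)), 1)
  m <- matrix(c(7, 21, 0, 13), 2, 2)
  expect_equal(fisherExact2x2(m), bruteForceFisher(m), tolerance = 1e-10)
  # random tables
  set.seed(42)
  for (i in 1:200) {
    m <- matrix(sample(0:8, 4, replace = TRUE), 2, 2)
    if (sum(m) == 0) next
    expect_equal(fisherExact2x2(m), bruteForceFisher(m), tolerance = 1e-8,
                 info = paste(m, collapse = ","))
  }
})

test_that("OCT summaries report mean/SD per cell with single-eye SD missing", {
  d <- data.frame(group = "Controls", age = c(25, 25), location = "fovea",
                  thickness = c(300, 300))
  s <- octSummarize(d)
  g <- s[s$decade == "Global", ]
  expect_identical(g$mean, 300)
  expect_identical(g$sd, 0)
  one <- octSummarize(d[1, ])
  expect_true(all(is.na(one$sd)))
  expect_identical(one$n, c(1L, 1L))
  expect_error(octSummarize(d[, -2]), class = "crbStatError")
})
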