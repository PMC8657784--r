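test_that("generation is deterministic given the seed", {
  cfg <- syntheticConfig(nPatients = 40L, seed = 7L,
                         phenotypeRuleNoise = 0.1)
  g1 <- generateCohort(cfg, crbModel)
  g2 <- generateCohort(cfg, crbModel)
  expect_identical(g1, g2)
  g3 <- generateCohort(syntheticConfig(nPatients = 40L, seed = 8L,
                                       phenotypeRuleNoise = 0.1), crbModel)
  expect_false(identical(g1$cohort, g3$cohort))
})

test_that("degenerate configurations are rejected", {
  expect_error(syntheticConfig(nPatients = 0L), class = "crbConfigError")
  expect_error(syntheticConfig(variantPool = data.frame()),
               class = "crbConfigError")
  expect_error(syntheticConfig(phenotypeRuleNoise = 1.5),
               class = "crbConfigError")
})

test_that("a noiseless cohort is fully recovered by the pipeline", {
  cfg <- syntheticConfig(nPatients = 200L, seed = 11L,
                         phenotypeRuleNoise = 0)
  gen <- generateCohort(cfg, crbModel)
  # the generated roster loads under the cohort schema
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write.table(gen$cohort, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  loaded <- loadCohort(tmp)
  expect_identical(nrow(loaded), 200L)
  # classification recovers every generating phenotype
  rule <- classifyPhenotype(loaded)
  expect_identical(rule, gen$truth$rule_phenotype)
  # every patient carrying the macular in-frame deletion is labelled MD
  hasDel <- loaded$allele1_cdna == "c.498_506del" |
    loaded$allele2_cdna == "c.498_506del"
  expect_true(all(loaded$phenotype[hasDel] == "MD"))
  # dosage truth matches a re-annotation of the generated roster
  ann <- annotateCohort(loaded, crbModel)
  expect_identical(ann$muller, gen$truth$muller)
  expect_identical(ann$photoreceptor, gen$truth$photoreceptor)
})

test_that("label noise appears at the configured rate", {
  q <- 0.2
  cfg <- syntheticConfig(nPatients = 500L, seed = 13L,
                         phenotypeRuleNoise = q)
  gen <- generateCohort(cfg, crbModel)
  discord <- mean(gen$truth$label != gen$truth$rule_phenotype)
  # binomial 99% band around q at n = 500
  half <- qnorm(0.995) * sqrt(q * (1 - q) / 500)
  expect_gt(discord, q - half)
  expect_lt(discord, q + half)
})

test_that("OCT draws recover the configured cell parameters", {
  cfg <- syntheticConfig()
  set.seed(5)
  # published cell: Controls / Global fovea, n = 28
  d <- generateOct(cfg, "Controls", "Global", "fovea", 28L)
  s <- octSummarize(d)
  g <- s[s$decade == "Global", ]
  expect_lt(abs(g$mean - 226.79), 3 * 20.71 / sqrt(28))
  # convergence at large n, within 1%
  d <- generateOct(cfg, "EORD", "Global", "fovea", 10000L)
  m <- mean(d$thickness)
  expect_lt(abs(m - 268.94) / 268.94, 0.01)
  # zero-SD configuration collapses to the mean
  cfg0 <- cfg
  cfg0$octParams$fovea_sd[cfg0$octParams$group == "Controls" &
                            cfg0$octParams$decade == "Global"] <- 0
  d0 <- generateOct(cfg0, "Controls", "Global", "fovea", 5L)
  expect_true(all(d0$thickness == 226.79))
  # unparameterised cell is a configuration error
  expect_error(generateOct(cfg, "Controls", "[0;10]", "fovea", 5L),
               class = "crbConfigError")
  expect_error(generateOct(cfg, "Controls", "Global", "bogus", 5L),
               class = "crbConfigError")
})
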