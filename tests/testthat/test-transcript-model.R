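test_that("exon table partitions the CDS contiguously", {
  ex <- exons(crbModel)
  expect_identical(ex$cdna_start[1], 1L)
  expect_identical(ex$cdna_end[nrow(ex)], cdsLength(crbModel))
  expect_true(all(ex$cdna_start[-1] == ex$cdna_end[-nrow(ex)] + 1L))
  expect_true(all(diff(ex$exon) == 1L))
  # CDS length = 3 * (protein length + stop)
  protA <- isoforms(crbModel)$protein_length[isoforms(crbModel)$name == "A"]
  expect_identical(cdsLength(crbModel), 3L * (protA + 1L))
})

test_that("exonOf satisfies every published variant-to-exon constraint", {
  cons <- read.delim(testFile("constraints_variant_exon.tsv"),
                     comment.char = "#", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cons)))
    expect_identical(exonOf(crbModel, cons$pos[i], cons$offset[i]),
                     cons$expected[i],
                     info = sprintf("c.%d offset %d", cons$pos[i],
                                    cons$offset[i]))
  expect_identical(exonOf(crbModel, 1), "exon 1")
  expect_error(exonOf(crbModel, cdsLength(crbModel) + 1L),
               class = "crbRangeError")
  expect_error(exonOf(crbModel, 0), class = "crbRangeError")
})

test_that("residueOf is exact codon arithmetic and monotone", {
  expect_identical(residueOf(2290), 764L)
  expect_identical(residueOf(1562), 521L)
  expect_identical(residueOf(3), 1L)
  k <- 1:1407
  expect_identical(residueOf(3L * k), k)           # third codon base
  r <- residueOf(1:4221)
  expect_true(all(diff(r) >= 0L))                  # monotone non-decreasing
  expect_identical(range(r), c(1L, 1407L))
})

test_that("domainOf satisfies every published residue-to-domain label", {
  cons <- read.delim(testFile("constraints_residue_domain.tsv"),
                     comment.char = "#", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cons)))
    expect_identical(normLabel(domainOf(crbModel, cons$residue[i])),
                     normLabel(cons$expected[i]),
                     info = sprintf("residue %d", cons$residue[i]))
  expect_error(domainOf(crbModel, 0), class = "crbRangeError")
  expect_error(domainOf(crbModel, 1407), class = "crbRangeError")
})

test_that("domain map covers residues 1..1406 without overlap", {
  dm <- domains(crbModel)
  expect_identical(dm$start_res[1], 1L)
  expect_identical(dm$end_res[nrow(dm)], 1406L)
  expect_true(all(dm$start_res[-1] == dm$end_res[-nrow(dm)] + 1L))
})

test_that("isoform inclusion logic matches the published impact cells", {
  expect_false(inIsoform(crbModel, "B", 946))   # exon-4 missense: B is WT
  expect_true(inIsoform(crbModel, "B", 2843))   # exon-9 missense hits B
  expect_false(inIsoform(crbModel, "B", 1084))  # B starts after c.1084
  expect_false(inIsoform(crbModel, "B", 4214))  # exon 12 is A-specific
  # isoform A contains any coding span
  for (pos in c(1L, 946L, 2843L, 4221L))
    expect_true(inIsoform(crbModel, "A", pos))
  expect_error(inIsoform(crbModel, "Z", 100), class = "crbModelError")
  # B spans seven exons: segment 5c through exon 11
  expect_identical(crb1iso:::.isoformExons(crbModel, "B"), 5:11)
})

test_that("a transcript model round-trips through its serialised files", {
  dir <- withr::local_tempdir()
  writeTranscriptModel(crbModel, dir)
  back <- loadTranscriptModel(
    exonFile = file.path(dir, "crb1_exons.tsv"),
    isoformFile = file.path(dir, "crb1_isoforms.tsv"),
    domainFile = file.path(dir, "crb1_domains.tsv"),
    overrideFile = file.path(dir, "crb1_domain_overrides.tsv"))
  expect_identical(exons(back), exons(crbModel))
  expect_identical(domains(back), domains(crbModel))
  expect_identical(isoforms(back), isoforms(crbModel))
})

test_that("a misplaced isoform-B start is rejected", {
  dir <- withr::local_tempdir()
  writeTranscriptModel(crbModel, dir)
  iso <- read.delim(file.path(dir, "crb1_isoforms.tsv"))
  iso$incl_start[iso$name == "B"] <- 1000L   # before the c.1084 floor
  write.table(iso, file.path(dir, "crb1_isoforms.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(loadTranscriptModel(
    exonFile = file.path(dir, "crb1_exons.tsv"),
    isoformFile = file.path(dir, "crb1_isoforms.tsv"),
    domainFile = file.path(dir, "crb1_domains.tsv"),
    overrideFile = file.path(dir, "crb1_domain_overrides.tsv")),
    class = "crbModelError")
})
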