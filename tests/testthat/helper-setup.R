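# Shared objects for the suite: the packaged model and cohort are loaded
# once; label comparison normalises typography only (case, hyphen/underscore,
# "Laminin"/"Lam" and the "Intracellular tail"/"cytoplasmic C-term" synonym),
# never content.

crbModel <- loadTranscriptModel()
crbCohort <- loadCohort()
crbAnnotated <- annotateCohort(crbCohort, crbModel)

normLabel <- function(x) {
  x <- tolower(x)
  x <- gsub("[-_]", " ", x)
  x <- gsub("laminin", "lam", x)
  x <- gsub("intracellular tail", "cytoplasmic c term", x)
  gsub(" +", " ", trimws(x))
}

extdata <- function(name) {
  system.file("extdata", name, package = "crb1iso", mustWork = TRUE)
}

readFixture <- function(name) {
  read.delim(extdata(name), comment.char = "#", stringsAsFactors = FALSE)
}

testFile <- function(name) testthat::test_path(name)

# independent two-sided Fisher oracle: enumerate every table with the
# observed margins and sum the probabilities of those no more likely than
# the observed one (standard floating-tie guard of 1 + 1e-7)
bruteForceFisher <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); n <- sum(m)
  ks <- max(0L, c1 - r2):min(r1, c1)
  prob <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  pObs <- choose(r1, m[1, 1]) * choose(r2, m[2, 1]) / choose(n, c1)
  sum(prob[prob <= pObs * (1 + 1e-7)])
}
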