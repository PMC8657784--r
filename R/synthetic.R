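# Seeded synthetic-cohort generator.  The generator emulates the statistical
# structure the cohort analysis assumes -- recessive genotypes drawn from a
# variant pool, a deterministic genotype->phenotype rule (the exon-2
# in-frame deletion drives maculopathy; two truncating alleles drive
# early-onset disease; two missense alleles drive RP) optionally flipped
# with a small noise probability, per-group onset-age ranges, fundus-flag
# prevalences, and per-cell OCT thickness distributions.

#' Default variant pool for the synthetic generator
#'
#' The distinct variants of the packaged cohort, weighted by their allele
#' frequency in it.
#'
#' @param cohort optional cohort data.frame (defaults to the packaged one).
#' @return data.frame with columns cdna, protein, weight.
#' @export
defaultVariantPool <- function(cohort = loadCohort()) {
  alleles <- data.frame(
    cdna = c(cohort$allele1_cdna, cohort$allele2_cdna),
    protein = c(cohort$allele1_protein, cohort$allele2_protein),
    stringsAsFactors = FALSE)
  tab <- table(alleles$cdna)
  pool <- alleles[!duplicated(alleles$cdna), ]
  pool <- pool[order(pool$cdna), ]
  pool$weight <- as.numeric(tab[pool$cdna]) / sum(tab)
  rownames(pool) <- NULL
  pool
}

#' Build a synthetic-cohort configuration
#'
#' Defaults encode the study conditions: onset ranges per group (EORD
#' [0.4, 5), RP [5, 15), MD [16, 42] years -- the published group ranges,
#' drawn uniformly since only ranges were published), fundus-flag
#' prevalences equal to the cohort rates (drusen 12/50, PPARPE 14/50,
#' Coats-like 1/50, edema 17/50), OCT parameters from the published
#' per-group thickness table, and a homozygosity boost of 0.3 reflecting
#' the ascertained cohort's homozygote fraction (18/50).
#'
#' @param nPatients number of synthetic patients.
#' @param seed integer seed; every draw is derived from it.
#' @param variantPool data.frame (cdna, protein, weight); weights are
#'   normalised.
#' @param phenotypeRuleNoise probability that a patient's label is flipped
#'   away from the genotype rule.
#' @param onsetRanges named list of c(min, max) years per group.
#' @param flagPrevalence named numeric vector of Bernoulli rates.
#' @param homozygosityBoost probability that allele 2 copies allele 1.
#' @param octParams data.frame in the layout of
#'   `oct_reference_params.tsv` (defaults to the packaged parameters).
#' @return a list of class "crb1SyntheticConfig".
#' @export
syntheticConfig <- function(nPatients = 50L, seed = 1L,
                            variantPool = defaultVariantPool(),
                            phenotypeRuleNoise = 0,
                            onsetRanges = list(EORD = c(0.4, 5),
                                               RP = c(5, 15),
                                               MD = c(16, 42)),
                            flagPrevalence = c(drusen = 12 / 50,
                                               pparpe = 14 / 50,
                                               coats = 1 / 50,
                                               edema = 17 / 50),
                            homozygosityBoost = 0.3,
                            octParams = octReferenceParams()) {
  if (is.null(variantPool) || !nrow(variantPool))
    crbError("variant pool must not be empty", "crbConfigError")
  if (nPatients < 1L)
    crbError("nPatients must be at least 1", "crbConfigError")
  if (phenotypeRuleNoise < 0 || phenotypeRuleNoise > 1)
    crbError("phenotypeRuleNoise must be in [0, 1]", "crbConfigError")
  if (is.null(variantPool$weight)) variantPool$weight <- 1
  variantPool$weight <- variantPool$weight / sum(variantPool$weight)
  structure(list(nPatients = as.integer(nPatients), seed = as.integer(seed),
                 variantPool = variantPool,
                 phenotypeRuleNoise = phenotypeRuleNoise,
                 onsetRanges = onsetRanges, flagPrevalence = flagPrevalence,
                 homozygosityBoost = homozygosityBoost,
                 octParams = octParams),
            class = "crb1SyntheticConfig")
}

#' Published OCT reference parameters
#'
#' @return data.frame of per group x decade x location means/SDs (microns)
#'   and eye counts, as packaged.
#' @export
octReferenceParams <- function() {
  read.delim(system.file("extdata", "oct_reference_params.tsv",
                         package = "crb1iso", mustWork = TRUE),
             comment.char = "#", stringsAsFactors = FALSE)
}

# deterministic genotype -> phenotype rule of the generator
.genotypeRule <- function(class1, class2, cdna1, cdna2) {
  if (cdna1 == "c.498_506del" || cdna2 == "c.498_506del") return("MD")
  trunc1 <- class1 %in% c("nonsense", "frameshift", "stop-loss extension",
                          "delins")
  trunc2 <- class2 %in% c("nonsense", "frameshift", "stop-loss extension",
                          "delins")
  if (trunc1 && trunc2) return("EORD")
  if (class1 == "missense" && class2 == "missense") return("RP")
  "EORD"  # mixed missense/truncating pairs track the severe group
}

# coarse allele class used by the rule (parser-backed)
.poolClass <- function(cdna, protein) {
  cv <- parseCdna(cdna)
  if (cv@kind == "delins") return("delins")
  pc <- if (is.na(protein) || !nzchar(protein)) NULL else parseProtein(protein)
  if (is.null(pc)) return(if (cv@startOffset != 0L) "splice" else "unknown")
  switch(pc@kind, missense = "missense", nonsense = "nonsense",
         frameshift = "frameshift", inframe_deletion = "in-frame indel",
         extension = "stop-loss extension", "unknown")
}

#' Generate a synthetic cohort
#'
#' Deterministic given the configured seed.  Genotypes are two weighted
#' draws from the pool (with an optional homozygosity boost); each
#' patient's generating phenotype follows the genotype rule and is flipped
#' to a uniformly-chosen other label with probability
#' `phenotypeRuleNoise`; clinical fields (topography, onset, ERG, flags)
#' are then drawn conditional on the final label, so a noiseless cohort is
#' exactly recoverable by the classification rule.
#'
#' @param cfg a configuration from [syntheticConfig()].
#' @param model a [TranscriptModel-class] used to compute the generating
#'   dosage truth.
#' @return list with `cohort` (a [loadCohort()]-schema data.frame) and
#'   `truth` (patient_id, rule_phenotype, label, muller, photoreceptor).
#' @export
generateCohort <- function(cfg, model = loadTranscriptModel()) {
  if (!inherits(cfg, "crb1SyntheticConfig"))
    crbError("cfg must come from syntheticConfig()", "crbConfigError")
  set.seed(cfg$seed)
  pool <- cfg$variantPool
  pool$class <- mapply(.poolClass, pool$cdna, pool$protein)
  n <- cfg$nPatients
  i1 <- sample.int(nrow(pool), n, replace = TRUE, prob = pool$weight)
  hom <- runif(n) < cfg$homozygosityBoost
  i2 <- ifelse(hom, i1,
               sample.int(nrow(pool), n, replace = TRUE, prob = pool$weight))
  rule <- vapply(seq_len(n), function(k)
    .genotypeRule(pool$class[i1[k]], pool$class[i2[k]],
                  pool$cdna[i1[k]], pool$cdna[i2[k]]), character(1))
  labels <- c("EORD", "RP", "MD")
  flip <- runif(n) < cfg$phenotypeRuleNoise
  label <- vapply(seq_len(n), function(k) {
    if (!flip[k]) rule[k] else sample(setdiff(labels, rule[k]), 1L)
  }, character(1))
  onset <- vapply(seq_len(n), function(k) {
    r <- cfg$onsetRanges[[label[k]]]
    round(runif(1L, r[1], r[2]), 1)
  }, numeric(1))
  drawFlag <- function(p) ifelse(runif(n) < p, "Yes", "No")
  cohort <- data.frame(
    patient_id = sprintf("SYN-%04d", seq_len(n)),
    family_id = sprintf("SYN-%04d", seq_len(n)),
    sex = sample(c("M", "F"), n, replace = TRUE),
    phenotype = label,
    nystagmus = ifelse(label == "EORD" & onset < 1, "Yes", "No"),
    onset_age = format(onset, trim = TRUE),
    age_first_visit = format(round(onset + runif(n, 0, 20), 1), trim = TRUE),
    age_final_visit = "ND", followup_months = "ND",
    topography = ifelse(label == "MD", "macula_restricted", "generalized"),
    erg = c(EORD = "indiscernible", RP = "reduced",
            MD = "discernible")[label],
    allele1_cdna = pool$cdna[i1], allele1_protein = pool$protein[i1],
    allele2_cdna = pool$cdna[i2], allele2_protein = pool$protein[i2],
    initial_bcva_od = "ND", initial_bcva_os = "ND",
    drusen = drawFlag(cfg$flagPrevalence[["drusen"]]),
    pparpe = drawFlag(cfg$flagPrevalence[["pparpe"]]),
    coats = drawFlag(cfg$flagPrevalence[["coats"]]),
    edema = drawFlag(cfg$flagPrevalence[["edema"]]),
    stringsAsFactors = FALSE)
  truth <- data.frame(patient_id = cohort$patient_id, rule_phenotype = rule,
                      label = label, muller = NA_character_,
                      photoreceptor = NA_character_, stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    g <- annotateGenotype(model, cohort$allele1_cdna[k],
                          cohort$allele1_protein[k], cohort$allele2_cdna[k],
                          cohort$allele2_protein[k],
                          context = cohort$patient_id[k])
    truth$muller[k] <- g$muller$label
    truth$photoreceptor[k] <- g$photoreceptor$label
  }
  list(cohort = cohort, truth = truth)
}

#' Draw synthetic per-eye OCT thickness measurements
#'
#' Normal draws with the configured cell mean/SD.  An unparameterised cell
#' (absent or with missing mean) is a configuration error; a cell whose SD
#' was not published (single measured eye) draws with SD 0.
#'
#' @param cfg a [syntheticConfig()] (or anything with `$octParams`).
#' @param group,decade row keys of the parameter table (e.g. "Controls",
#'   "Global").
#' @param location one of fovea, T1500, T3000, N1500.
#' @param nEyes number of eyes to draw.
#' @return data.frame with columns group, decade, location, eye, thickness.
#' @export
generateOct <- function(cfg, group, decade, location, nEyes) {
  params <- if (inherits(cfg, "crb1SyntheticConfig")) cfg$octParams
            else cfg
  row <- params[params$group == group & params$decade == decade, ,
                drop = FALSE]
  col <- c(fovea = "fovea", T1500 = "t1500", T3000 = "t3000",
           N1500 = "n1500")[location]
  if (!nrow(row) || is.na(col))
    crbError(sprintf("no OCT parameters for (%s, %s, %s)", group, decade,
                     location), "crbConfigError")
  mu <- row[[paste0(col, "_mean")]][1L]
  sdv <- row[[paste0(col, "_sd")]][1L]
  if (is.na(mu))
    crbError(sprintf("OCT cell (%s, %s, %s) has no published parameters",
                     group, decade, location), "crbConfigError")
  if (is.na(sdv)) sdv <- 0
  # representative age so the draws land in the requested decade band when
  # re-summarised ("Global" rows aggregate over all ages anyway)
  repAge <- c("[0;10]" = 5, "]10;20]" = 15, "]20;30]" = 25, "]30;40]" = 35,
              "]40;50]" = 45, ">50" = 55, "Global" = 25)[decade]
  data.frame(group = group, decade = decade, age = unname(repAge),
             location = location, eye = seq_len(nEyes),
             thickness = rnorm(nEyes, mu, sdv), stringsAsFactors = FALSE)
}
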