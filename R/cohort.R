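# Cohort pipeline: fixture loading, phenotype classification, per-patient
# annotation and the census/cross-tabulation operations.

.COHORT_COLUMNS <- c("patient_id", "family_id", "sex", "phenotype",
                     "nystagmus", "onset_age", "age_first_visit",
                     "topography", "erg", "allele1_cdna", "allele1_protein",
                     "allele2_cdna", "allele2_protein", "drusen", "pparpe",
                     "coats", "edema")

#' Load a cohort roster
#'
#' Reads the tab-separated cohort schema (see the packaged
#' `crb1_cohort.tsv` for the column set) and checks it.  Missing values are
#' the explicit marker "ND"; onset ages may be numeric, "<5", ">5" or "ND".
#'
#' @param path path to a cohort TSV; `NULL` loads the packaged 50-patient
#'   roster.
#' @return data.frame, one row per patient.
#' @export
loadCohort <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "crb1_cohort.tsv", package = "crb1iso",
                        mustWork = TRUE)
  if (!file.exists(path))
    crbError(sprintf("cohort file '%s' not found", path), "crbLoadError")
  df <- tryCatch(
    read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
               colClasses = "character"),
    error = function(e) crbError(sprintf("cannot read cohort file '%s': %s",
                                         path, conditionMessage(e)),
                                 "crbLoadError"))
  if (!nrow(df))
    crbError(sprintf("cohort file '%s' contains no patients", path),
             "crbLoadError")
  missingCols <- setdiff(.COHORT_COLUMNS, names(df))
  if (length(missingCols))
    crbError(sprintf("cohort file '%s' lacks required column(s): %s", path,
                     paste(missingCols, collapse = ", ")), "crbLoadError")
  if (any(!nzchar(df$allele1_cdna)) || any(!nzchar(df$allele2_cdna)))
    crbError("every patient needs two alleles", "crbLoadError")
  if (any(!df$phenotype %in% c("EORD", "RP", "MD")))
    crbError("phenotype labels must be EORD, RP or MD", "crbLoadError")
  df
}

# onset parsing: list(value = numeric or NA, bound = "exact"/"lt"/"gt"/NA)
.parseOnset <- function(x) {
  if (is.na(x) || x %in% c("", "ND"))
    return(list(value = NA_real_, bound = NA_character_))
  if (startsWith(x, "<"))
    return(list(value = as.numeric(substring(x, 2)), bound = "lt"))
  if (startsWith(x, ">"))
    return(list(value = as.numeric(substring(x, 2)), bound = "gt"))
  list(value = as.numeric(x), bound = "exact")
}

#' Classify phenotype from clinical fields
#'
#' Published grouping rule, applied with the precedence topography > onset
#' threshold > ERG severity: anomalies restricted to the posterior pole give
#' macular dystrophy (MD); otherwise onset before age 5 gives early-onset
#' retinal dystrophy (EORD) and later onset retinitis pigmentosa (RP).
#' Onset exactly at the 5-year boundary, or missing, is resolved by ERG
#' severity (indiscernible responses -> EORD, measurable responses -> RP).
#' Records that remain unresolvable are returned as "unclassified", never a
#' silent default.
#'
#' @param cohort data.frame from [loadCohort()] (or compatible rows).
#' @param onsetCutoff onset-age threshold in years (default 5).
#' @return character vector: "EORD", "RP", "MD" or "unclassified".
#' @export
classifyPhenotype <- function(cohort, onsetCutoff = 5) {
  vapply(seq_len(nrow(cohort)), function(i) {
    r <- cohort[i, ]
    if (identical(r$topography, "macula_restricted")) return("MD")
    if (!identical(r$topography, "generalized")) return("unclassified")
    on <- .parseOnset(r$onset_age)
    byErg <- function() {
      if (identical(r$erg, "indiscernible")) "EORD"
      else if (r$erg %in% c("reduced", "discernible")) "RP"
      else "unclassified"
    }
    if (is.na(on$value)) return(byErg())
    if (on$bound == "lt" && on$value <= onsetCutoff) return("EORD")
    if (on$bound == "gt" && on$value >= onsetCutoff) return("RP")
    if (on$value < onsetCutoff) return("EORD")
    if (on$value > onsetCutoff) return("RP")
    byErg()  # onset exactly at the boundary
  }, character(1))
}

#' Annotate a single variant
#'
#' @param model a [TranscriptModel-class].
#' @param cdna,protein HGVS strings (protein may be NA).
#' @return one-row data.frame with exon, census class, consequence class,
#'   per-isoform NMD calls and impact labels, and the canonical-protein
#'   domain of the affected residue.
#' @export
annotateVariant <- function(model, cdna, protein = NA) {
  cv <- parseCdna(cdna)
  pc <- if (is.null(protein) || is.na(protein) || !nzchar(protein)) NULL
        else parseProtein(protein)
  q <- classifyConsequence(model, cv, pc)
  impA <- impactOnIsoform(model, cv, q, "A")
  impB <- impactOnIsoform(model, cv, q, "B")
  protLenA <- model@isoforms$protein_length[model@isoforms$name == "A"][1L]
  domain <- if (q@klass == "stop-loss extension") "cytoplasmic C-term"
    else if (!is.na(q@startRes) && q@startRes <= protLenA)
      domainOf(model, q@startRes)
    else NA_character_
  data.frame(
    cdna = formatCdna(cv), protein = if (is.null(pc)) NA_character_
      else formatProtein(pc),
    exon = q@exon, consequence = q@klass,
    census_class = .censusClass(cv, pc),
    start_res = q@startRes, end_res = q@endRes,
    truncating = .isTruncating(cv, q),
    nmd_A = predictNmd(model, "A", q), nmd_B = predictNmd(model, "B", q),
    impact_A = impA$regionLabel, impact_B = impB$regionLabel,
    state_A = alleleState(impA), state_B = alleleState(impB),
    domain = domain, stringsAsFactors = FALSE)
}

# census vocabulary: missense / indel / nonsense / splice / stop-loss
.censusClass <- function(cv, pc) {
  if (cv@kind %in% c("deletion", "insertion", "delins", "duplication"))
    return("indel")
  if (cv@startOffset != 0L || cv@endOffset != 0L) return("splice")
  if (is.null(pc)) return("unknown")
  switch(pc@kind, missense = "missense", nonsense = "nonsense",
         extension = "stop-loss", frameshift = "indel",
         inframe_deletion = "indel", "unknown")
}

# truncating allele types: nonsense, frameshifting indel, donor-spanning
# delins, stop-loss (missense, in-frame deletion and splice are excluded)
.isTruncating <- function(cv, q) {
  q@klass %in% c("nonsense", "frameshift", "stop-loss extension") ||
    cv@kind == "delins"
}

#' Annotate every patient of a cohort
#'
#' Parses and classifies both alleles of each patient and computes the
#' per-cell-type dosage labels (Muller cells from isoform A, photoreceptors
#' from isoform B).
#'
#' @param cohort data.frame from [loadCohort()].
#' @param model a [TranscriptModel-class] (default: packaged model).
#' @return the cohort with per-allele annotation columns (`exon1`,
#'   `impact_A1`, `state_B2`, ...) and the `muller` / `photoreceptor` dosage
#'   labels appended.
#' @export
annotateCohort <- function(cohort, model = loadTranscriptModel()) {
  # annotate each distinct allele once
  keys <- unique(c(paste0(cohort$allele1_cdna, "\r", cohort$allele1_protein),
                   paste0(cohort$allele2_cdna, "\r", cohort$allele2_protein)))
  cache <- lapply(keys, function(k) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    annotateVariant(model, parts[1], if (length(parts) > 1) parts[2] else NA)
  })
  names(cache) <- keys
  pull <- function(which) {
    key <- paste0(cohort[[paste0("allele", which, "_cdna")]], "\r",
                  cohort[[paste0("allele", which, "_protein")]])
    rows <- do.call(rbind, cache[key])
    names(rows) <- paste0(names(rows), which)
    rownames(rows) <- NULL
    rows
  }
  a1 <- pull(1L); a2 <- pull(2L)
  muller <- photoreceptor <- character(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    muller[i] <- combineAlleles(a1$state_A1[i], a2$state_A2[i])$label
    photoreceptor[i] <- combineAlleles(a1$state_B1[i], a2$state_B2[i])$label
  }
  cbind(cohort, a1, a2, muller = muller, photoreceptor = photoreceptor,
        stringsAsFactors = FALSE)
}

#' Variant census of an annotated cohort
#'
#' Distinct variants are keyed by their cDNA string; a codon-collapsed
#' census (variants grouped by affected start residue) is reported
#' alongside, since published totals counted recurrent codons once.
#'
#' @param annotated output of [annotateCohort()].
#' @return list with `nPatients`, `nFamilies`, `distinctVariants`, the
#'   per-class census (`byClass`), `codonCollapsed` counts, an exon
#'   histogram over distinct variants, and the per-phenotype patient counts.
#' @export
variantCensus <- function(annotated) {
  longAllele <- rbind(
    data.frame(cdna = annotated$cdna1, class = annotated$census_class1,
               exon = annotated$exon1, res = annotated$start_res1,
               stringsAsFactors = FALSE),
    data.frame(cdna = annotated$cdna2, class = annotated$census_class2,
               exon = annotated$exon2, res = annotated$start_res2,
               stringsAsFactors = FALSE))
  distinct <- longAllele[!duplicated(longAllele$cdna), ]
  byClass <- as.list(table(distinct$class))
  codonKey <- ifelse(is.na(distinct$res), distinct$cdna,
                     paste0(distinct$class, "@", distinct$res))
  collapsed <- distinct[!duplicated(codonKey), ]
  exonHist <- table(factor(distinct$exon, levels = sort(unique(distinct$exon))))
  list(
    nPatients = nrow(annotated),
    nFamilies = length(unique(annotated$family_id)),
    distinctVariants = nrow(distinct),
    byClass = byClass,
    codonCollapsed = list(distinctVariants = nrow(collapsed),
                          byClass = as.list(table(collapsed$class))),
    exonHistogram = as.list(exonHist),
    byPhenotype = as.list(table(annotated$phenotype)))
}

# does either allele of a patient alter a given residue?
.alleleHitsResidue <- function(annotated, which, residue) {
  s <- annotated[[paste0("start_res", which)]]
  e <- annotated[[paste0("end_res", which)]]
  !is.na(s) & s <= residue & residue <= e
}

#' Patients carrying a variant at a given codon
#'
#' @param annotated output of [annotateCohort()].
#' @param residue residue index in canonical numbering.
#' @param homozygousOnly count only patients whose two alleles are the same
#'   cDNA variant hitting the codon.
#' @return integer patient count.
#' @export
carriersAtCodon <- function(annotated, residue, homozygousOnly = FALSE) {
  h1 <- .alleleHitsResidue(annotated, 1L, residue)
  h2 <- .alleleHitsResidue(annotated, 2L, residue)
  if (homozygousOnly)
    sum(h1 & h2 & annotated$cdna1 == annotated$cdna2)
  else
    sum(h1 | h2)
}

#' Patients of a phenotype group with two truncating alleles
#'
#' Truncating types are nonsense, frameshifting indel, donor-spanning
#' delins and stop-loss; missense, in-frame deletions and splice variants
#' are excluded.
#'
#' @param annotated output of [annotateCohort()].
#' @param phenotype "EORD", "RP" or "MD".
#' @return integer patient count.
#' @export
countBiallelicTruncating <- function(annotated, phenotype) {
  sel <- annotated$phenotype == phenotype
  sum(sel & annotated$truncating1 & annotated$truncating2)
}

#' Patients of a phenotype group expressing only wild-type isoform B
#'
#' @param annotated output of [annotateCohort()].
#' @param phenotype "EORD", "RP" or "MD".
#' @return integer count of patients whose photoreceptor dosage label is
#'   "100% WT".
#' @export
countWtIsoformB <- function(annotated, phenotype) {
  sum(annotated$phenotype == phenotype & annotated$photoreceptor == "100% WT")
}

#' Patients of a phenotype group with an allele in given exons
#'
#' @param annotated output of [annotateCohort()].
#' @param phenotype "EORD", "RP" or "MD".
#' @param exonSet integer vector of exon numbers (empty set gives 0).
#' @return integer patient count.
#' @export
exonPredicateCount <- function(annotated, phenotype, exonSet) {
  if (!length(exonSet)) return(0L)
  sel <- annotated$phenotype == phenotype
  sum(sel & (annotated$exon1 %in% exonSet | annotated$exon2 %in% exonSet))
}

#' Clinical flag tallies
#'
#' Counts the fundus-sign flags and reconstructs the macular-edema
#' prevalence by phenotype and decade of age at first visit.
#'
#' @param cohort data.frame from [loadCohort()].
#' @return list with `drusen`, `pparpe`, `coats`, `edema` counts and an
#'   `edemaByDecade` data.frame (phenotype, decade, n).
#' @export
clinicalTallies <- function(cohort) {
  cnt <- function(col) sum(cohort[[col]] == "Yes", na.rm = TRUE)
  ede <- cohort[cohort$edema == "Yes" & !is.na(cohort$edema), ]
  age <- suppressWarnings(as.numeric(ede$age_first_visit))
  decade <- .decadeBand(age)
  byDec <- if (nrow(ede))
    aggregate(list(n = rep(1L, nrow(ede))),
              by = list(phenotype = ede$phenotype, decade = decade), FUN = sum)
  else data.frame(phenotype = character(), decade = character(),
                  n = integer())
  list(drusen = cnt("drusen"), pparpe = cnt("pparpe"), coats = cnt("coats"),
       edema = cnt("edema"), edemaByDecade = byDec)
}

# decade bands matching the published OCT table ([0;10], ]10;20], ..., >50)
.decadeBand <- function(age) {
  bands <- c("[0;10]", "]10;20]", "]20;30]", "]30;40]", "]40;50]", ">50")
  idx <- pmin(ifelse(age <= 10, 1L, ceiling(age / 10)), 6L)
  ifelse(is.na(age), NA_character_, bands[idx])
}
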