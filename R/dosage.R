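# Recessive dosage calculus: two allele states combine into a categorical
# per-cell-type protein pool ("100% mutated", "50% mutated/0% WT", ...).
# Percentages are categorical halves of a two-allele pool, not quantitative
# expression estimates.

#' Combine the states of two alleles into a dosage label
#'
#' Symmetric mapping over the allele-state vocabulary
#' \{WT, MUT, ABSENT, UNKNOWN\}: each allele contributes half of the pool;
#' an ABSENT allele (decayed transcript) contributes nothing; any UNKNOWN
#' allele makes the pool "Unknown".
#'
#' @param a,b allele states ("WT", "MUT", "ABSENT", "UNKNOWN").
#' @return list with `pctMut`, `pctWt` (0/50/100, NA when unknown), `label`
#'   (canonical text) and `flags` (character vector; "no_protein" or
#'   "unknown" where applicable).
#' @examples
#' combineAlleles("MUT", "ABSENT")$label   # "50% mutated/0% WT"
#' combineAlleles("ABSENT", "ABSENT")$label  # "No protein"
#' @export
combineAlleles <- function(a, b) {
  valid <- c("WT", "MUT", "ABSENT", "UNKNOWN")
  if (!(a %in% valid) || !(b %in% valid))
    crbError(sprintf("invalid allele state in (%s, %s)", a, b),
             "crbStateError")
  if (a == "UNKNOWN" || b == "UNKNOWN")
    return(list(pctMut = NA_real_, pctWt = NA_real_, label = "Unknown",
                flags = "unknown"))
  pctMut <- 50 * ((a == "MUT") + (b == "MUT"))
  pctWt <- 50 * ((a == "WT") + (b == "WT"))
  label <- if (pctMut == 0 && pctWt == 0) "No protein"
    else if (pctMut == 100) "100% mutated"
    else if (pctWt == 100) "100% WT"
    else sprintf("%d%% mutated/%d%% WT", pctMut, pctWt)
  flags <- if (label == "No protein") "no_protein" else character()
  list(pctMut = pctMut, pctWt = pctWt, label = label, flags = flags)
}

#' Annotate a biallelic genotype with per-cell-type dosage
#'
#' Runs both alleles through consequence classification and per-isoform
#' impact, then combines them: the Muller-cell pool follows isoform A, the
#' photoreceptor pool isoform B.
#'
#' @param model a [TranscriptModel-class].
#' @param cdna1,protein1,cdna2,protein2 HGVS strings for the two alleles
#'   (protein may be NA/NULL).
#' @param context optional label (e.g. patient ID) prefixed to error
#'   messages.
#' @return list with per-allele impacts (`allele1`, `allele2`, each holding
#'   `A` and `B` impact lists plus the [Consequence-class]) and the combined
#'   `muller` / `photoreceptor` dosage lists.
#' @examples
#' model <- loadTranscriptModel()
#' g <- annotateGenotype(model, "c.687G>A", "p.Trp229*",
#'                       "c.4219T>A", "p.Ter1407Lysext*111")
#' g$muller$label          # "50% mutated/0% WT"
#' g$photoreceptor$label   # "100% WT"
#' @export
annotateGenotype <- function(model, cdna1, protein1, cdna2, protein2,
                             context = NULL) {
  one <- function(cdna, protein) {
    cv <- parseCdna(cdna)
    pc <- if (is.null(protein) || is.na(protein) || !nzchar(protein)) NULL
          else parseProtein(protein)
    q <- classifyConsequence(model, cv, pc)
    list(cdna = cv, consequence = q,
         A = impactOnIsoform(model, cv, q, "A"),
         B = impactOnIsoform(model, cv, q, "B"))
  }
  wrap <- function(expr, which) {
    tryCatch(expr, crbError = function(e) {
      pre <- if (is.null(context)) "" else sprintf("[%s] ", context)
      crbError(sprintf("%sallele %d: %s", pre, which, conditionMessage(e)),
               class(e)[1L])
    })
  }
  a1 <- wrap(one(cdna1, protein1), 1L)
  a2 <- wrap(one(cdna2, protein2), 2L)
  list(allele1 = a1, allele2 = a2,
       muller = combineAlleles(alleleState(a1$A), alleleState(a2$A)),
       photoreceptor = combineAlleles(alleleState(a1$B), alleleState(a2$B)))
}
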