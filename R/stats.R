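# Small statistical helpers for the cohort tabulations.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact conditional (hypergeometric) two-sided p-value, as implemented in
#' [stats::fisher.test()]: the sum of the probabilities of all tables with
#' the observed margins that are no more likely than the observed one.
#'
#' @param tab 2x2 matrix (or coercible) of non-negative integer counts.
#' @return p-value in (0, 1].
#' @examples
#' fisherExact2x2(matrix(c(7, 0, 21, 13), nrow = 2))
#' @export
fisherExact2x2 <- function(tab) {
  m <- as.matrix(tab)
  if (!all(dim(m) == c(2L, 2L)))
    crbError("fisherExact2x2 needs a 2x2 table", "crbStatError")
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    crbError("counts must be non-negative integers", "crbStatError")
  if (sum(m) == 0)
    crbError("all-zero table has no defined p-value", "crbStatError")
  stats::fisher.test(m)$p.value
}

#' Summarise per-eye retinal thickness measurements
#'
#' Arithmetic mean and sample SD per group x decade x location cell, plus a
#' per-group "Global" row per location.  Cells with a single eye report the
#' mean with a missing SD.  Decades follow the bands [0;10], ]10;20], ...,
#' >50 in years.
#'
#' @param measurements data.frame with columns `group`, `age` (years),
#'   `location` (fovea, T1500, T3000, N1500) and `thickness` (microns).
#' @return data.frame with columns group, decade, location, n, mean, sd.
#' @export
octSummarize <- function(measurements) {
  need <- c("group", "age", "location", "thickness")
  miss <- setdiff(need, names(measurements))
  if (length(miss))
    crbError(sprintf("measurements lack column(s): %s",
                     paste(miss, collapse = ", ")), "crbStatError")
  m <- measurements
  m$decade <- .decadeBand(as.numeric(m$age))
  summarise <- function(d) {
    out <- aggregate(d$thickness,
                     by = list(group = d$group, decade = d$decade,
                               location = d$location),
                     FUN = function(x) c(n = length(x), mean = mean(x),
                                         sd = if (length(x) > 1) sd(x)
                                              else NA_real_))
    data.frame(group = out$group, decade = out$decade,
               location = out$location, n = as.integer(out$x[, "n"]),
               mean = out$x[, "mean"], sd = out$x[, "sd"],
               stringsAsFactors = FALSE)
  }
  perDecade <- summarise(m)
  g <- m; g$decade <- "Global"
  res <- rbind(summarise(g), perDecade)
  rownames(res) <- NULL
  res
}
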