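# VCF-style export of variant annotations.  Coordinates are CDS-relative on
# a synthetic contig named after the transcript (the source data carry no
# genomic coordinates), declared explicitly in the header.  Where an allele
# cannot be spelled without the mRNA sequence (deletions/insertions whose
# reference bases were never published) symbolic ALT alleles are used.

#' Export annotated variants as a VCF file
#'
#' One record per distinct variant, on the synthetic contig
#' `<transcriptId>_CDS` with POS equal to the variant's first CDS
#' coordinate.  INFO carries the HGVS strings, exon, consequence class,
#' per-isoform decay calls and impact labels, and the canonical-protein
#' domain.  The file parses with standard VCF readers (it is exercised
#' against VariantAnnotation in the test suite).
#'
#' @param annotations data.frame as produced by [annotateVariant()] rows
#'   (or the allele columns of [annotateCohort()] reshaped to one row per
#'   distinct variant).
#' @param path output path.
#' @param model a [TranscriptModel-class] (contig name and length).
#' @return invisibly, `path`.
#' @export
exportVcf <- function(annotations, path, model = loadTranscriptModel()) {
  contig <- paste0(gsub("[^A-Za-z0-9._]", "_", transcriptId(model)), "_CDS")
  esc <- function(x) {
    x <- ifelse(is.na(x), ".", as.character(x))
    gsub("[ ;,=]", "_", x)
  }
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=crb1iso-%s", as.character(packageVersion("crb1iso"))),
    sprintf("##contig=<ID=%s,length=%d>", contig, cdsLength(model)),
    "##ALT=<ID=DEL,Description=\"Deletion (reference bases not published)\">",
    "##ALT=<ID=INS,Description=\"Insertion placeholder\">",
    "##ALT=<ID=DELINS,Description=\"Deletion-insertion placeholder\">",
    "##ALT=<ID=DUP,Description=\"Duplication placeholder\">",
    "##INFO=<ID=HGVSC,Number=1,Type=String,Description=\"HGVS cDNA\">",
    "##INFO=<ID=HGVSP,Number=1,Type=String,Description=\"HGVS protein\">",
    "##INFO=<ID=EXON,Number=1,Type=String,Description=\"Exon of the variant anchor\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=NMD_A,Number=1,Type=String,Description=\"Predicted decay, Muller isoform A\">",
    "##INFO=<ID=NMD_B,Number=1,Type=String,Description=\"Predicted decay, photoreceptor isoform B\">",
    "##INFO=<ID=ISOA_IMPACT,Number=1,Type=String,Description=\"Impact label on isoform A\">",
    "##INFO=<ID=ISOB_IMPACT,Number=1,Type=String,Description=\"Impact label on isoform B\">",
    "##INFO=<ID=DOMAIN,Number=1,Type=String,Description=\"Canonical-protein domain of the affected residue\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  records <- character(nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    cv <- parseCdna(a$cdna)
    refAlt <- switch(cv@kind,
      substitution = c(cv@ref, cv@alt),
      deletion = c("N", "<DEL>"),
      insertion = c("N", "<INS>"),
      delins = c("N", "<DELINS>"),
      duplication = c("N", "<DUP>"))
    info <- paste(c(
      paste0("HGVSC=", esc(a$cdna)), paste0("HGVSP=", esc(a$protein)),
      paste0("EXON=", esc(a$exon)), paste0("CSQ=", esc(a$consequence)),
      paste0("NMD_A=", esc(a$nmd_A)), paste0("NMD_B=", esc(a$nmd_B)),
      paste0("ISOA_IMPACT=", esc(a$impact_A)),
      paste0("ISOB_IMPACT=", esc(a$impact_B)),
      paste0("DOMAIN=", esc(a$domain))), collapse = ";")
    records[i] <- paste(contig, cv@start, ".", refAlt[1], refAlt[2], ".",
                        ".", info, sep = "\t")
  }
  writeLines(c(header, records), path)
  invisible(path)
}

#' Distinct-variant annotation table of an annotated cohort
#'
#' @param annotated output of [annotateCohort()].
#' @return data.frame with one [annotateVariant()]-style row per distinct
#'   cDNA variant, ordered by CDS position.
#' @export
distinctVariantTable <- function(annotated) {
  cols1 <- c(cdna = "cdna1", protein = "protein1", exon = "exon1",
             consequence = "consequence1", census_class = "census_class1",
             start_res = "start_res1", end_res = "end_res1",
             truncating = "truncating1", nmd_A = "nmd_A1", nmd_B = "nmd_B1",
             impact_A = "impact_A1", impact_B = "impact_B1",
             state_A = "state_A1", state_B = "state_B1", domain = "domain1")
  cols2 <- sub("1$", "2", cols1)
  grab <- function(cols) {
    d <- annotated[, unname(cols)]
    names(d) <- names(cols)
    d
  }
  long <- rbind(grab(cols1), grab(cols2))
  d <- long[!duplicated(long$cdna), ]
  pos <- vapply(d$cdna, function(s) parseCdna(s)@start, integer(1))
  d <- d[order(pos), ]
  rownames(d) <- NULL
  d
}
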