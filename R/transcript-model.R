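#' Load the packaged (or a user-supplied) transcript model
#'
#' Reads the exon, isoform and domain tables and assembles a validated
#' [TranscriptModel-class].  The packaged model describes NM_201253.3:
#' exon junctions are pinned by published variant-to-exon assignments and
#' interpolated elsewhere (see the comments in the packaged TSV files);
#' the isoform-B start ("exon 5c") defaults to c.1093, constrained only to
#' lie after c.1084 and at or before the start of exon 6.
#'
#' @param exonFile,isoformFile,domainFile,overrideFile paths to tab-separated
#'   tables; `NULL` means the packaged CRB1 model.
#' @param transcriptId transcript identifier stored in the model.
#' @return a validated [TranscriptModel-class].
#' @examples
#' model <- loadTranscriptModel()
#' exonOf(model, 2243)
#' domainOf(model, 948)
#' @export
loadTranscriptModel <- function(exonFile = NULL, isoformFile = NULL,
                                domainFile = NULL, overrideFile = NULL,
                                transcriptId = "NM_201253.3") {
  pkgFile <- function(x) system.file("extdata", x, package = "crb1iso",
                                     mustWork = TRUE)
  readTsv <- function(path) {
    read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
               check.names = TRUE)
  }
  ex <- readTsv(if (is.null(exonFile)) pkgFile("crb1_exons.tsv") else exonFile)
  iso <- readTsv(if (is.null(isoformFile)) pkgFile("crb1_isoforms.tsv") else isoformFile)
  dm <- readTsv(if (is.null(domainFile)) pkgFile("crb1_domains.tsv") else domainFile)
  ov <- readTsv(if (is.null(overrideFile)) pkgFile("crb1_domain_overrides.tsv") else overrideFile)
  ex$exon <- as.integer(ex$exon)
  ex$cdna_start <- as.integer(ex$cdna_start)
  ex$cdna_end <- as.integer(ex$cdna_end)
  iso$protein_length <- as.integer(iso$protein_length)
  iso$incl_start <- as.integer(iso$incl_start)
  iso$incl_end <- as.integer(iso$incl_end)
  dm$start_res <- as.integer(dm$start_res)
  dm$end_res <- as.integer(dm$end_res)
  ov$start_res <- as.integer(ov$start_res)
  ov$end_res <- as.integer(ov$end_res)
  model <- new("TranscriptModel", transcriptId = transcriptId, exons = ex,
               isoforms = iso, domains = dm, domainOverrides = ov,
               cdsLength = ex$cdna_end[nrow(ex)])
  # isoform-B placement contract: starts inside exon 5, strictly after the
  # last B-external nonsense position, ends at the coding end of exon 11
  if ("B" %in% iso$name) {
    b <- iso[iso$name == "B", ]
    ex5 <- ex[ex$exon == 5L, ]
    ex11 <- ex[ex$exon == 11L, ]
    if (nrow(ex5) && (b$incl_start <= 1084L || b$incl_start < ex5$cdna_start ||
                      b$incl_start > ex[ex$exon == 6L, "cdna_start"]))
      crbError("isoform B must start inside exon 5, after c.1084",
               "crbModelError")
    if (nrow(ex11) && b$incl_end != ex11$cdna_end)
      crbError("isoform B must end at the last coding position of exon 11",
               "crbModelError")
  }
  validObject(model)
  model
}

#' Write a transcript model back to tab-separated files
#'
#' @param model a [TranscriptModel-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeTranscriptModel <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("crb1_exons.tsv", "crb1_isoforms.tsv",
                            "crb1_domains.tsv", "crb1_domain_overrides.tsv"))
  tabs <- list(model@exons, model@isoforms, model@domains,
               model@domainOverrides)
  for (i in seq_along(paths))
    write.table(tabs[[i]], paths[i], sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(paths)
}

# exon index (integer) of an exonic c. position
.exonIndexOf <- function(model, pos) {
  ex <- model@exons
  if (length(pos) != 1L || is.na(pos) || pos < 1L || pos > model@cdsLength)
    crbError(sprintf("position c.%s is outside the CDS (1..%d)",
                     as.character(pos), model@cdsLength), "crbRangeError")
  ex$exon[ex$cdna_start <= pos & pos <= ex$cdna_end][1L]
}

#' Exon (or intron) containing a cDNA position
#'
#' With `offset = 0` returns the exon whose interval contains `pos`
#' ("exon k").  A negative offset denotes a position in the intron preceding
#' the exon containing `pos` (acceptor side); a positive offset the intron
#' following it (donor side); both return "intron k".
#'
#' @param model a [TranscriptModel-class].
#' @param pos HGVS c. coordinate (1..cdsLength).
#' @param offset intronic offset (0 for exonic positions).
#' @return character scalar, "exon k" or "intron k".
#' @examples
#' model <- loadTranscriptModel()
#' exonOf(model, 2243)        # "exon 7"
#' exonOf(model, 653, -1)     # "intron 2"
#' @export
setGeneric("exonOf", function(model, pos, offset = 0L) standardGeneric("exonOf"))

#' @rdname exonOf
#' @export
setMethod("exonOf", "TranscriptModel", function(model, pos, offset = 0L) {
  k <- .exonIndexOf(model, pos)
  if (offset == 0L) sprintf("exon %d", k)
  else if (offset < 0L) sprintf("intron %d", k - 1L)
  else sprintf("intron %d", k)
})

#' Residue index encoded at a cDNA position
#'
#' Standard codon arithmetic: position `pos` of the CDS belongs to codon
#' `ceiling(pos / 3)`.
#'
#' @param pos HGVS c. coordinate(s); vectorised.
#' @return integer residue indices.
#' @examples
#' residueOf(2290)  # 764
#' residueOf(3)     # 1
#' @export
residueOf <- function(pos) {
  if (any(is.na(pos)) || any(pos < 1L))
    crbError("cDNA position must be a positive integer", "crbRangeError")
  as.integer(ceiling(pos / 3))
}

#' Protein domain at a residue (isoform-A numbering)
#'
#' Returns the domain label covering the residue.  Published per-residue
#' labels recorded in the model's override table take precedence over the
#' monotone base table (the published EGF numbering near the C-terminus is
#' internally inconsistent; both labels are retained in the model files).
#'
#' @param model a [TranscriptModel-class].
#' @param residue residue index, 1..protein_length_A.
#' @param published apply the published-label overrides (default TRUE).
#' @return character domain label.
#' @examples
#' model <- loadTranscriptModel()
#' domainOf(model, 764)   # "Laminin G-like 2"
#' domainOf(model, 19)    # "signal peptide"
#' @export
setGeneric("domainOf",
           function(model, residue, published = TRUE) standardGeneric("domainOf"))

#' @rdname domainOf
#' @export
setMethod("domainOf", "TranscriptModel", function(model, residue,
                                                  published = TRUE) {
  protLen <- model@isoforms$protein_length[model@isoforms$name == "A"][1L]
  if (length(residue) != 1L || is.na(residue) || residue < 1L ||
      residue > protLen)
    crbError(sprintf("residue %s outside 1..%d", as.character(residue),
                     protLen), "crbRangeError")
  if (published && nrow(model@domainOverrides)) {
    ov <- model@domainOverrides
    hit <- ov$start_res <= residue & residue <= ov$end_res
    if (any(hit)) return(ov$label[hit][1L])
  }
  dm <- model@domains
  dm$name[dm$start_res <= residue & residue <= dm$end_res][1L]
})

# full domain record (base table row) at a residue
.domainRecordAt <- function(model, residue) {
  dm <- model@domains
  dm[dm$start_res <= residue & residue <= dm$end_res, , drop = FALSE][1L, ]
}

# names of the annotated modules flanking an inter-domain gap row
.gapNeighbours <- function(model, gapRow) {
  dm <- model@domains
  i <- which(dm$start_res == gapRow$start_res)
  list(before = if (i > 1L) dm$name[i - 1L] else NA_character_,
       after = if (i < nrow(dm)) dm$name[i + 1L] else NA_character_)
}

#' Does a cDNA span fall inside an isoform's inclusion interval?
#'
#' True iff the (exonic) span overlaps the isoform's inclusion interval in
#' canonical c. coordinates.  Intronic offsets are carried but do not move
#' the exonic anchors.
#'
#' @param model a [TranscriptModel-class].
#' @param isoform isoform name ("A", "B", "C").
#' @param start,end exonic anchor positions of the span (c. coordinates).
#' @return logical scalar.
#' @examples
#' model <- loadTranscriptModel()
#' inIsoform(model, "B", 946, 946)    # FALSE: exon 4 precedes the 5c start
#' inIsoform(model, "B", 2843, 2843)  # TRUE
#' @export
setGeneric("inIsoform",
           function(model, isoform, start, end = start) standardGeneric("inIsoform"))

#' @rdname inIsoform
#' @export
setMethod("inIsoform", "TranscriptModel", function(model, isoform, start,
                                                   end = start) {
  iso <- model@isoforms
  row <- iso[iso$name == isoform, , drop = FALSE]
  if (!nrow(row))
    crbError(sprintf("unknown isoform '%s'", isoform), "crbModelError")
  start <= row$incl_end[1L] && end >= row$incl_start[1L]
})

# exon numbers making up an isoform (exons overlapping its inclusion interval)
.isoformExons <- function(model, isoform) {
  iso <- model@isoforms
  row <- iso[iso$name == isoform, , drop = FALSE]
  if (!nrow(row))
    crbError(sprintf("unknown isoform '%s'", isoform), "crbModelError")
  ex <- model@exons
  ex$exon[ex$cdna_start <= row$incl_end[1L] & ex$cdna_end >= row$incl_start[1L]]
}
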