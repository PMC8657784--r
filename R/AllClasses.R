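#' TranscriptModel: coordinate model of the CRB1 transcripts
#'
#' Holds the coding-exon table in HGVS c. coordinates (1-based, closed,
#' relative to the A of the start codon), the isoform inclusion intervals
#' (isoform A = full CDS; isoform B = exon segment 5c through the coding end
#' of exon 11), the protein domain map in isoform-A residue numbering, and
#' the published per-residue label overrides where the published domain
#' numbering is internally inconsistent.
#'
#' @slot transcriptId RefSeq-style transcript identifier.
#' @slot exons data.frame with columns exon, cdna_start, cdna_end.
#' @slot isoforms data.frame with columns name, cell_type, protein_length,
#'   incl_start, incl_end.
#' @slot domains data.frame with columns name, kind, start_res, end_res.
#' @slot domainOverrides data.frame with columns start_res, end_res, label,
#'   note (published labels taking precedence over the base table).
#' @slot cdsLength CDS length in nucleotides (including the stop codon).
#' @export
setClass("TranscriptModel",
  representation(
    transcriptId = "character",
    exons = "data.frame",
    isoforms = "data.frame",
    domains = "data.frame",
    domainOverrides = "data.frame",
    cdsLength = "integer"
  )
)

setValidity("TranscriptModel", function(object) {
  msg <- character()
  ex <- object@exons
  if (!all(c("exon", "cdna_start", "cdna_end") %in% names(ex)))
    return("exon table must have columns exon, cdna_start, cdna_end")
  if (any(ex$cdna_start > ex$cdna_end))
    msg <- c(msg, "exon with cdna_start > cdna_end")
  if (any(diff(ex$exon) != 1L))
    msg <- c(msg, "exon numbers must be strictly increasing by 1")
  if (ex$cdna_start[1L] != 1L)
    msg <- c(msg, "first exon must start at c.1")
  if (nrow(ex) > 1L && any(ex$cdna_start[-1L] != ex$cdna_end[-nrow(ex)] + 1L))
    msg <- c(msg, "exon table must be contiguous in cDNA space")
  if (ex$cdna_end[nrow(ex)] != object@cdsLength)
    msg <- c(msg, "exon table must cover the CDS end")
  iso <- object@isoforms
  if (!"A" %in% iso$name)
    msg <- c(msg, "isoform A (canonical) must be present")
  if ("A" %in% iso$name) {
    a <- iso[iso$name == "A", ]
    if (a$incl_start != 1L || a$incl_end != object@cdsLength)
      msg <- c(msg, "isoform A inclusion must span the full CDS")
    if (object@cdsLength != 3L * (a$protein_length + 1L))
      msg <- c(msg, "cds_length must equal 3 * (protein_length_A + 1)")
  }
  dm <- object@domains
  if (nrow(dm)) {
    if (dm$start_res[1L] != 1L ||
        (nrow(dm) > 1L && any(dm$start_res[-1L] != dm$end_res[-nrow(dm)] + 1L)))
      msg <- c(msg, "domain table must partition the protein without gaps")
    protLenA <- iso$protein_length[iso$name == "A"][1L]
    if (dm$end_res[nrow(dm)] != protLenA)
      msg <- c(msg, "domain table must cover residues 1..protein_length_A")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn TranscriptModel transcript identifier accessor
#' @param object,x a `TranscriptModel`
#' @export
setGeneric("transcriptId", function(object) standardGeneric("transcriptId"))
#' @export
setMethod("transcriptId", "TranscriptModel", function(object) object@transcriptId)

#' @describeIn TranscriptModel exon table accessor
#' @export
setGeneric("exons", function(object) standardGeneric("exons"))
#' @export
setMethod("exons", "TranscriptModel", function(object) object@exons)

#' @describeIn TranscriptModel isoform table accessor
#' @export
setGeneric("isoforms", function(object) standardGeneric("isoforms"))
#' @export
setMethod("isoforms", "TranscriptModel", function(object) object@isoforms)

#' @describeIn TranscriptModel domain table accessor
#' @export
setGeneric("domains", function(object) standardGeneric("domains"))
#' @export
setMethod("domains", "TranscriptModel", function(object) object@domains)

#' @describeIn TranscriptModel CDS length accessor (nt, incl. stop codon)
#' @export
setGeneric("cdsLength", function(object) standardGeneric("cdsLength"))
#' @export
setMethod("cdsLength", "TranscriptModel", function(object) object@cdsLength)

setMethod("show", "TranscriptModel", function(object) {
  cat("TranscriptModel", object@transcriptId, "\n")
  cat("  CDS:", object@cdsLength, "nt in", nrow(object@exons), "exons\n")
  cat("  isoforms:",
      paste(sprintf("%s (%d aa, %s)", object@isoforms$name,
                    object@isoforms$protein_length,
                    object@isoforms$cell_type), collapse = ", "), "\n")
  cat("  domains:", nrow(object@domains), "records,",
      nrow(object@domainOverrides), "published-label override(s)\n")
})

#' CdnaVariant: parsed HGVS cDNA description
#'
#' Structured form of the coding-DNA HGVS dialect used in the cohort tables:
#' substitutions, deletions, insertions, deletion-insertions and
#' duplications, with intronic offsets on either endpoint.
#'
#' @slot raw the input string.
#' @slot kind one of substitution, deletion, insertion, delins, duplication.
#' @slot start,end c. coordinates (1-based, closed interval).
#' @slot startOffset,endOffset intronic offsets (0 when exonic).
#' @slot ref,alt nucleotide strings (possibly empty).
#' @export
setClass("CdnaVariant",
  representation(raw = "character", kind = "character",
                 start = "integer", end = "integer",
                 startOffset = "integer", endOffset = "integer",
                 ref = "character", alt = "character"))

setValidity("CdnaVariant", function(object) {
  msg <- character()
  if (object@start > object@end)
    msg <- c(msg, "start must be <= end")
  if (object@kind == "substitution" &&
      (object@start != object@end || nchar(object@ref) != 1L ||
       nchar(object@alt) != 1L))
    msg <- c(msg, "substitution must have one position and one ref/alt base")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CdnaVariant", function(object) {
  cat("CdnaVariant:", formatCdna(object), sprintf("[%s]\n", object@kind))
})

#' ProteinChange: parsed HGVS protein description
#'
#' @slot raw the input string.
#' @slot kind one of missense, nonsense, inframe_deletion, frameshift,
#'   extension (stop-loss), unknown ("p.?").
#' @slot startRes,endRes residue indices (isoform-A numbering).
#' @slot refAa,altAa three-letter amino-acid codes ("Ter" for stop).
#' @slot fsStopDistance codons from the frameshifted residue to the new stop.
#' @slot extNewStop position of the new stop beyond the natural one
#'   (stop-loss extensions).
#' @export
setClass("ProteinChange",
  representation(raw = "character", kind = "character",
                 startRes = "integer", endRes = "integer",
                 refAa = "character", altAa = "character",
                 fsStopDistance = "integer", extNewStop = "integer"))

setValidity("ProteinChange", function(object) {
  msg <- character()
  if (object@kind == "frameshift" &&
      (is.na(object@fsStopDistance) || object@fsStopDistance < 1L))
    msg <- c(msg, "frameshift requires fs stop distance >= 1")
  if (object@kind == "extension" &&
      (is.na(object@extNewStop) || object@extNewStop < 2L))
    msg <- c(msg, "extension requires new stop position >= 2")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ProteinChange", function(object) {
  cat("ProteinChange:", formatProtein(object), sprintf("[%s]\n", object@kind))
})

#' Consequence: protein-level consequence of one allele
#'
#' @slot klass one of missense, nonsense, frameshift, in-frame indel,
#'   stop-loss extension, splice, unknown.
#' @slot exon exon number of the variant's exonic anchor.
#' @slot startRes,endRes affected residue interval (NA for splice/unknown).
#' @slot deletedResidues residues removed by an in-frame deletion.
#' @slot extensionLength residues appended before the new stop (stop-loss).
#' @slot ptcExon exon carrying the premature stop (nonsense/frameshift;
#'   approximated by the variant's own exon), NA otherwise.
#' @slot spansDonor,spansAcceptor whether the description crosses a splice
#'   donor/acceptor site.
#' @export
setClass("Consequence",
  representation(klass = "character", exon = "integer",
                 startRes = "integer", endRes = "integer",
                 deletedResidues = "integer", extensionLength = "integer",
                 ptcExon = "integer", spansDonor = "logical",
                 spansAcceptor = "logical"))

setMethod("show", "Consequence", function(object) {
  cat("Consequence:", object@klass, "| exon", object@exon)
  if (!is.na(object@startRes))
    cat(" | residues", object@startRes, "-", object@endRes)
  if (!is.na(object@ptcExon)) cat(" | PTC exon", object@ptcExon)
  cat("\n")
})
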