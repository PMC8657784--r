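# Variant-level engine: consequence class, per-isoform NMD under the
# penultimate-exon rule, and per-isoform impact labels.

#' Classify the protein-level consequence of a cDNA variant
#'
#' When a protein annotation is supplied the class follows it ("p.?" from a
#' splice-site-spanning change maps to splice); without one, the class is
#' derived arithmetically (net length change modulo 3 for indels, offsets of
#' 1-2 nt for splice).  Residue spans from the protein annotation are checked
#' against codon arithmetic on the cDNA span (exact for single-codon
#' changes; one codon of slack for indels, whose HGVS description is
#' 3'-shifted across codon boundaries).
#'
#' @param model a [TranscriptModel-class].
#' @param cdna a [CdnaVariant-class] (or HGVS string).
#' @param protein a [ProteinChange-class], HGVS string, or NULL.
#' @return a [Consequence-class].
#' @examples
#' model <- loadTranscriptModel()
#' classifyConsequence(model, "c.498_506del", "p.Ile167_Gly169del")
#' @export
setGeneric("classifyConsequence",
  function(model, cdna, protein = NULL) standardGeneric("classifyConsequence"))

#' @rdname classifyConsequence
#' @export
setMethod("classifyConsequence", "TranscriptModel",
  function(model, cdna, protein = NULL) {
  cv <- if (is(cdna, "CdnaVariant")) cdna else parseCdna(cdna)
  pc <- if (is.null(protein)) NULL
        else if (is(protein, "ProteinChange")) protein
        else parseProtein(protein)
  intronicOnly <- cv@startOffset != 0L && cv@endOffset != 0L &&
    cv@start == cv@end
  spansDonor <- cv@endOffset > 0L
  spansAcceptor <- cv@startOffset < 0L

  if (!is.null(pc)) {
    klass <- switch(pc@kind,
      unknown = if (cv@startOffset != 0L || cv@endOffset != 0L) "splice"
                else "unknown",
      missense = "missense",
      nonsense = "nonsense",
      frameshift = "frameshift",
      inframe_deletion = "in-frame indel",
      extension = "stop-loss extension")
  } else {
    klass <- if (cv@kind == "substitution") {
      if (cv@startOffset != 0L) "splice" else "unknown"
    } else {
      removed <- switch(cv@kind,
        deletion = , delins = cv@end - cv@start + 1L +
          max(cv@endOffset, 0L) - min(cv@startOffset, 0L),
        insertion = 0L, duplication = 0L)
      added <- switch(cv@kind,
        deletion = 0L, delins = nchar(cv@alt), insertion = nchar(cv@alt),
        duplication = cv@end - cv@start + 1L)
      if ((added - removed) %% 3L == 0L) "in-frame indel" else "frameshift"
    }
  }

  exon <- .exonIndexOf(model, cv@start)

  # affected residue interval
  startRes <- endRes <- NA_integer_
  if (!is.null(pc) && !is.na(pc@startRes)) {
    startRes <- pc@startRes; endRes <- pc@endRes
  } else if (klass %in% c("missense", "nonsense", "frameshift",
                          "in-frame indel", "stop-loss extension") ||
             (klass %in% c("splice", "unknown") && cv@kind == "delins")) {
    startRes <- residueOf(cv@start); endRes <- residueOf(cv@end)
  }

  # cDNA/protein consistency: codon arithmetic must agree with the protein
  # annotation (indel descriptions are 3'-shifted, allow one codon)
  if (!is.null(pc) && !is.na(pc@startRes) && cv@startOffset == 0L) {
    expect <- residueOf(cv@start)
    tol <- if (pc@kind %in% c("missense", "nonsense", "extension")) 0L else 1L
    if (abs(expect - pc@startRes) > tol)
      crbError(sprintf(
        "cDNA span of %s implies residue %d but protein annotation %s names %d",
        cv@raw, expect, pc@raw, pc@startRes), "crbConsistencyError")
  }

  deletedResidues <- NA_integer_
  if (klass == "in-frame indel" && cv@kind == "deletion")
    deletedResidues <- (cv@end - cv@start + 1L) %/% 3L
  extensionLength <- NA_integer_
  if (klass == "stop-loss extension" && !is.null(pc))
    extensionLength <- pc@extNewStop - 1L
  ptcExon <- if (klass %in% c("nonsense", "frameshift")) exon else NA_integer_

  new("Consequence", klass = klass, exon = exon,
      startRes = as.integer(startRes), endRes = as.integer(endRes),
      deletedResidues = deletedResidues, extensionLength = extensionLength,
      ptcExon = ptcExon, spansDonor = spansDonor,
      spansAcceptor = spansAcceptor)
})

#' Predict nonsense-mediated decay for one isoform
#'
#' Implements the penultimate-exon rule: decay is presumed when a premature
#' stop (nonsense or frameshift) lies in an exon strictly before the
#' penultimate exon of that isoform's exon sequence.  For isoform A (exons
#' 1-12) that means exons 1-10; for isoform B (exon segment 5c through exon
#' 11) exons up to 9, exon 10 being B's penultimate exon.  Missense,
#' in-frame and stop-loss changes are not NMD substrates; splice changes
#' are "unknown".
#'
#' @param model a [TranscriptModel-class].
#' @param isoform isoform name.
#' @param consequence a [Consequence-class].
#' @return one of "yes", "no", "not_applicable", "unknown".
#' @export
setGeneric("predictNmd",
  function(model, isoform, consequence) standardGeneric("predictNmd"))

#' @rdname predictNmd
#' @export
setMethod("predictNmd", "TranscriptModel",
  function(model, isoform, consequence) {
  q <- consequence
  if (q@klass %in% c("missense", "in-frame indel", "stop-loss extension"))
    return("not_applicable")
  if (q@klass %in% c("splice", "unknown")) return("unknown")
  isoExons <- .isoformExons(model, isoform)
  if (!(q@ptcExon %in% isoExons)) return("not_applicable")
  penultimate <- isoExons[length(isoExons) - 1L]
  if (q@ptcExon < penultimate) "yes" else "no"
})

#' Impact of one allele on one isoform
#'
#' The product state is `wild_type` when the variant does not overlap the
#' isoform's inclusion interval; `absent` when a premature stop triggers
#' predicted decay of that isoform's transcript; `unknown` for splice or
#' undetermined protein changes (with one exception: a deletion-insertion
#' spanning a donor site whose exonic part lies inside the isoform is
#' treated as an altered product); otherwise `altered`, with a region label
#' from the domain map ("Cytoplasmic C-term" for changes in the isoform's
#' terminal exon; "Deletion between X and Y" for in-frame deletions falling
#' between annotated modules).
#'
#' @param model a [TranscriptModel-class].
#' @param cdna a [CdnaVariant-class].
#' @param consequence the matching [Consequence-class].
#' @param isoform isoform name.
#' @return list with elements `isoform`, `productState` (wild_type /
#'   altered / absent / unknown) and `regionLabel`.
#' @export
setGeneric("impactOnIsoform",
  function(model, cdna, consequence, isoform) standardGeneric("impactOnIsoform"))

#' @rdname impactOnIsoform
#' @export
setMethod("impactOnIsoform", "TranscriptModel",
  function(model, cdna, consequence, isoform) {
  cv <- cdna; q <- consequence
  res <- function(state, label) list(isoform = isoform, productState = state,
                                     regionLabel = label)
  if (!inIsoform(model, isoform, cv@start, cv@end))
    return(res("wild_type", "WT"))
  isoExons <- .isoformExons(model, isoform)
  lastExon <- isoExons[length(isoExons)]
  if (q@klass == "splice") {
    if (cv@kind == "delins" && q@spansDonor) {
      # exonic part inside the isoform: an altered protein is still made
      label <- if (q@exon == lastExon) "Cytoplasmic C-term" else "?"
      return(res("altered", label))
    }
    return(res("unknown", "?"))
  }
  if (q@klass == "unknown") return(res("unknown", "?"))
  if (q@klass %in% c("nonsense", "frameshift")) {
    if (predictNmd(model, isoform, q) == "yes") return(res("absent", "NMD"))
    return(res("altered", .regionLabel(model, q)))
  }
  res("altered", .regionLabel(model, q))
})

# domain-level region label for an altered product
.regionLabel <- function(model, q) {
  if (!is.na(q@exon) && q@exon == nrow(model@exons))
    return("Cytoplasmic C-term")
  if (q@klass == "stop-loss extension") return("Cytoplasmic C-term")
  if (is.na(q@startRes)) return("?")
  if (q@klass == "in-frame indel") {
    recs <- unique(vapply(q@startRes:q@endRes, function(r)
      .domainRecordAt(model, r)$name, character(1)))
    rec1 <- .domainRecordAt(model, q@startRes)
    if (identical(recs, "inter-domain")) {
      nb <- .gapNeighbours(model, rec1)
      return(sprintf("Deletion between %s and %s", nb$before, nb$after))
    }
    return(domainOf(model, q@startRes))
  }
  domainOf(model, q@startRes)
}

#' Allele state code of an isoform impact
#'
#' Collapses a product state to the four-letter vocabulary used by the
#' dosage calculus: wild_type -> WT, altered -> MUT, absent -> ABSENT,
#' unknown -> UNKNOWN.
#'
#' @param impact a list as returned by [impactOnIsoform()].
#' @return character scalar.
#' @export
alleleState <- function(impact) {
  switch(impact$productState,
         wild_type = "WT", altered = "MUT", absent = "ABSENT",
         unknown = "UNKNOWN",
         crbError(sprintf("unknown product state '%s'", impact$productState),
                  "crbStateError"))
}
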