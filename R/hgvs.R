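# HGVS parsing for the cDNA and protein dialects used in the cohort tables.
# Deliberately narrow: only the syntax that occurs in the cohort is accepted
# (substitution, deletion, insertion, delins, duplication at the cDNA level;
# missense, nonsense, in-frame deletion, frameshift, stop-loss extension and
# "p.?" at the protein level).  Anything else fails loudly with the
# offending token; no silent cleanup (table typography is normalised at
# fixture-transcription time, not here).

.AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
          "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
          "Tyr", "Val")

.parseError <- function(raw, token) {
  crbError(sprintf("unsupported HGVS syntax in '%s' (near '%s')", raw, token),
           "crbParseError")
}

#' Parse an HGVS cDNA variant description
#'
#' @param text a string beginning "c.".
#' @return a [CdnaVariant-class].
#' @examples
#' parseCdna("c.2290C>T")
#' parseCdna("c.3999_4005+4delinsAAAGGAGAGC")
#' @export
parseCdna <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(text))
    crbError("empty cDNA variant string", "crbParseError")
  if (!startsWith(text, "c.")) .parseError(text, substr(text, 1, 2))
  body <- substring(text, 3L)
  mk <- function(kind, s, so, e, eo, ref = "", alt = "") {
    new("CdnaVariant", raw = text, kind = kind,
        start = as.integer(s), end = as.integer(e),
        startOffset = as.integer(so), endOffset = as.integer(eo),
        ref = ref, alt = alt)
  }
  off <- function(x) if (is.na(x) || x == "") 0L else as.integer(x)
  # substitution: POS[offset]REF>ALT
  m <- regmatches(body,
    regexec("^(\\d+)([+-]\\d+)?([ACGT])>([ACGT])$", body))[[1]]
  if (length(m))
    return(mk("substitution", m[2], off(m[3]), m[2], off(m[3]),
              ref = m[4], alt = m[5]))
  # range ops: POS[off][_POS[off]] (del[SEQ] | dup | insSEQ | delinsSEQ)
  m <- regmatches(body,
    regexec("^(\\d+)([+-]\\d+)?(?:_(\\d+)([+-]\\d+)?)?(delins|del|dup|ins)([ACGT]*)$",
            body))[[1]]
  if (!length(m)) .parseError(text, body)
  s <- m[2]; so <- off(m[3])
  e <- if (m[4] == "") m[2] else m[4]
  eo <- if (m[4] == "") so else off(m[5])
  op <- m[6]; seq <- m[7]
  if (as.integer(s) > as.integer(e)) .parseError(text, paste0(s, "_", e))
  v <- switch(op,
    del = mk("deletion", s, so, e, eo, ref = seq),
    dup = mk("duplication", s, so, e, eo, ref = seq),
    ins = {
      if (m[4] == "" || !nzchar(seq)) .parseError(text, "ins")
      if (as.integer(e) != as.integer(s) + 1L || so != 0L || eo != 0L)
        .parseError(text, "ins")
      mk("insertion", s, so, e, eo, alt = seq)
    },
    delins = {
      if (!nzchar(seq)) .parseError(text, "delins")
      mk("delins", s, so, e, eo, alt = seq)
    })
  validObject(v)
  v
}

#' Serialise a [CdnaVariant-class] back to HGVS
#'
#' Round-trip identity `formatCdna(parseCdna(s)) == s` holds for every
#' variant string in the packaged cohort.
#'
#' @param v a [CdnaVariant-class].
#' @return character scalar.
#' @export
formatCdna <- function(v) {
  stopifnot(is(v, "CdnaVariant"))
  offTxt <- function(o) if (o == 0L) "" else sprintf("%+d", o)
  p1 <- paste0(v@start, offTxt(v@startOffset))
  p2 <- paste0(v@end, offTxt(v@endOffset))
  span <- if (v@start == v@end && v@startOffset == v@endOffset) p1
          else paste0(p1, "_", p2)
  body <- switch(v@kind,
    substitution = paste0(p1, v@ref, ">", v@alt),
    deletion = paste0(span, "del", v@ref),
    duplication = paste0(span, "dup", v@ref),
    insertion = paste0(span, "ins", v@alt),
    delins = paste0(span, "delins", v@alt))
  paste0("c.", body)
}

#' Parse an HGVS protein change description
#'
#' Accepts the parenthesised predicted form ("p.(Arg764Cys)"), "Ter" or "*"
#' for the stop codon, frameshifts with a stop distance ("p.Ile205Aspfs*13"),
#' stop-loss extensions ("p.Ter1407Lysext*111"), in-frame deletions and
#' "p.?" (unknown).
#'
#' @param text a string beginning "p.".
#' @return a [ProteinChange-class].
#' @examples
#' parseProtein("p.Ile205Aspfs*13")
#' parseProtein("p.Ter1407Lysext*111")
#' @export
parseProtein <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(text))
    crbError("empty protein change string", "crbParseError")
  if (!startsWith(text, "p.")) .parseError(text, substr(text, 1, 2))
  body <- substring(text, 3L)
  body <- sub("^\\((.*)\\)$", "\\1", body)
  mk <- function(kind, s = NA, e = NA, ref = NA_character_,
                 alt = NA_character_, fs = NA, ext = NA) {
    p <- new("ProteinChange", raw = text, kind = kind,
             startRes = as.integer(s), endRes = as.integer(e),
             refAa = ref, altAa = alt, fsStopDistance = as.integer(fs),
             extNewStop = as.integer(ext))
    validObject(p)
    p
  }
  if (body == "?") return(mk("unknown"))
  aa <- paste0("(", paste(.AA3, collapse = "|"), ")")
  # stop-loss extension: Ter<pos><Aa>ext*<n>
  m <- regmatches(body, regexec(paste0("^(?:Ter|\\*)(\\d+)", aa,
                                       "ext\\*(\\d+)$"), body))[[1]]
  if (length(m))
    return(mk("extension", m[2], m[2], ref = "Ter", alt = m[3], ext = m[4]))
  # frameshift: <Aa><pos>[<Aa>]fs(*|Ter)<n>
  m <- regmatches(body, regexec(paste0("^", aa, "(\\d+)", aa,
                                       "?fs(?:\\*|Ter)(\\d+)$"), body))[[1]]
  if (length(m))
    return(mk("frameshift", m[3], m[3], ref = m[2],
              alt = if (nzchar(m[4])) m[4] else NA_character_, fs = m[5]))
  # in-frame deletion, range or single residue
  m <- regmatches(body, regexec(paste0("^", aa, "(\\d+)_", aa,
                                       "(\\d+)del$"), body))[[1]]
  if (length(m)) {
    if (as.integer(m[3]) > as.integer(m[5])) .parseError(text, "del")
    return(mk("inframe_deletion", m[3], m[5], ref = m[2], alt = m[4]))
  }
  m <- regmatches(body, regexec(paste0("^", aa, "(\\d+)del$"), body))[[1]]
  if (length(m))
    return(mk("inframe_deletion", m[3], m[3], ref = m[2], alt = m[2]))
  # missense / nonsense
  m <- regmatches(body, regexec(paste0("^", aa, "(\\d+)(", paste(
    c(.AA3, "Ter"), collapse = "|"), "|\\*)$"), body))[[1]]
  if (length(m)) {
    alt <- if (m[4] %in% c("Ter", "*")) "Ter" else m[4]
    kind <- if (alt == "Ter") "nonsense" else "missense"
    return(mk(kind, m[3], m[3], ref = m[2], alt = alt))
  }
  .parseError(text, body)
}

#' Serialise a [ProteinChange-class] back to HGVS
#'
#' @param p a [ProteinChange-class].
#' @return character scalar ("*" style for stops, matching the cohort
#'   tables).
#' @export
formatProtein <- function(p) {
  stopifnot(is(p, "ProteinChange"))
  body <- switch(p@kind,
    unknown = "?",
    missense = paste0(p@refAa, p@startRes, p@altAa),
    nonsense = paste0(p@refAa, p@startRes, "*"),
    frameshift = paste0(p@refAa, p@startRes,
                        if (!is.na(p@altAa)) p@altAa else "", "fs*",
                        p@fsStopDistance),
    inframe_deletion = if (p@startRes == p@endRes)
        paste0(p@refAa, p@startRes, "del")
      else paste0(p@refAa, p@startRes, "_", p@altAa, p@endRes, "del"),
    extension = paste0("Ter", p@startRes, p@altAa, "ext*", p@extNewStop))
  paste0("p.", body)
}
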