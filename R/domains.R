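# AP2/ERF and B3 domain consensus cores.
#
# A fixed 60-residue AP2/ERF scaffold carries the diagnostic positions the
# classifier reads: residue 14 (V in DREB-type, A in ERF-type), residue 19
# (E in canonical DREBs) and the conserved WLG tripeptide at 26-28. The
# synthetic generator plants these cores verbatim, and the regex fallback
# detector recognises the scaffold with the diagnostic positions wildcarded.

.AP2_SCAFFOLD <- paste0("YRGVRQRTWG", "KWVVEIRDEN", "RGSRLWLGTF",
                        "DTAEEAARAY", "DEAARAMYGP", "DARTNFPDSG")
.B3_CORE <- "FEKVLTPSDVGKLNRLVIPKQHAEKHFPLQSGNVSGKGVLLNFED"

#' AP2/ERF domain consensus cores
#'
#' @param type \code{"DREB"} (V14) or \code{"ERF"} (A14, D19).
#' @return 60-residue consensus string.
#' @export
ap2_consensus <- function(type = c("DREB", "ERF")) {
  type <- match.arg(type)
  s <- .chars(.AP2_SCAFFOLD)
  if (type == "ERF") {
    s[14] <- "A"
    s[19] <- "D"
    s[42] <- "Q"
  }
  paste(s, collapse = "")
}

.make_ap2_domain <- function(v14 = "V", e19 = "E", wlg = TRUE) {
  s <- .chars(.AP2_SCAFFOLD)
  s[14] <- v14
  s[19] <- e19
  if (!wlg) s[26:28] <- c("K", "A", "G")
  paste(s, collapse = "")
}

#' Locate planted AP2/B3 consensus cores in proteins (regex fallback)
#'
#' A lightweight stand-in for an HMM search on synthetic data: matches the
#' fixed AP2/ERF scaffold with the diagnostic positions (14, 19, 26-28)
#' wildcarded, and the fixed B3 core. Returns hits in the
#' [read_domtblout()] layout.
#'
#' @param proteins named character vector of protein sequences.
#' @return domain-hit data.frame.
#' @export
find_consensus_domains <- function(proteins) {
  s <- .chars(.AP2_SCAFFOLD)
  s[c(14L, 19L, 26L, 27L, 28L, 42L)] <- "."
  ap2_re <- paste(s, collapse = "")
  out <- list()
  for (id in names(proteins)) {
    p <- proteins[[id]]
    for (re in c(ap2_re, .B3_CORE)) {
      m <- gregexpr(re, p)[[1]]
      if (m[1] == -1L) next
      lens <- attr(m, "match.length")
      out[[length(out) + 1L]] <- data.frame(
        protein_id = id,
        domain_name = if (identical(re, ap2_re)) "AP2" else "B3",
        start = as.integer(m), end = as.integer(m) + lens - 1L,
        score = NA_real_, evalue = NA_real_, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(protein_id = character(), domain_name = character(),
                      start = integer(), end = integer(), score = numeric(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
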