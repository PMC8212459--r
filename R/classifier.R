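#' Degenerate consensus motif patterns
#'
#' The diagnostic motifs used to separate DREB subgroups: the conserved WLG
#' tripeptide of the AP2/ERF domain, the DREB1-type NLS
#' (\code{[PK]K[RK][PR][AT]GR[TK]KFRETRHP}; position 8 may be relaxed to any
#' residue, as its two published renderings disagree there), the PKK-like
#' DREB2 NLS (\code{RKxPAKGSKKGCMxGKGGPENxx}), the DSAW and LWSY flanking
#' motifs, and CMIV-1 (\code{[KR]GKGGPxN}).
#'
#' @param name motif name.
#' @param nls_pos8_any relax position 8 of the DREB1 NLS to any residue.
#' @return a \code{motif_pattern}: list of per-position allowed-residue sets.
#' @export
motif_pattern <- function(name = c("WLG", "DREB1-NLS", "DREB2-NLS",
                                   "DSAW", "LWSY", "CMIV-1"),
                          nls_pos8_any = FALSE) {
  name <- match.arg(name)
  lit <- function(s) as.list(.chars(s))
  x <- list(.AA_LETTERS)
  pat <- switch(name,
    "WLG" = lit("WLG"),
    "DSAW" = lit("DSAW"),
    "LWSY" = lit("LWSY"),
    "CMIV-1" = c(list(c("K", "R")), lit("GKGGP"), x, lit("N")),
    "DREB1-NLS" = c(list(c("P", "K")), lit("K"), list(c("R", "K")),
                    list(c("P", "R")), list(c("A", "T")), lit("GR"),
                    if (nls_pos8_any) x else list(c("T", "K")),
                    lit("KFRETRHP")),
    "DREB2-NLS" = c(lit("RK"), x, lit("PAKGSKKGCM"), x, lit("GKGGPEN"),
                    x, x))
  structure(pat, class = "motif_pattern", motif = name)
}

#' Scan a protein for a degenerate consensus motif
#'
#' Returns all non-overlapping leftmost matches; each pattern position must
#' be satisfied exactly (set membership, no mismatches).
#'
#' @param protein ungapped protein sequence (single string).
#' @param pattern a \code{motif_pattern} (or a name accepted by
#'   [motif_pattern()]).
#' @return data.frame with columns \code{start}, \code{end} (1-based,
#'   inclusive); zero rows when the motif is absent.
#' @export
scan_motif <- function(protein, pattern) {
  if (is.character(pattern)) pattern <- motif_pattern(pattern)
  if (grepl("-", protein, fixed = TRUE))
    stop("protein must be ungapped")
  s <- .chars(protein)
  L <- length(pattern)
  starts <- integer()
  i <- 1L
  while (i + L - 1L <= length(s)) {
    hit <- TRUE
    for (j in seq_len(L)) {
      if (!(s[i + j - 1L] %in% pattern[[j]])) { hit <- FALSE; break }
    }
    if (hit) {
      starts <- c(starts, i)
      i <- i + L
    } else i <- i + 1L
  }
  data.frame(start = starts, end = starts + L - 1L)
}

#' Read the V14 and E19 diagnostic residues of an AP2/ERF domain
#'
#' Positions are domain-relative, counting the first residue of the domain
#' hit as position 1. In canonical DREB proteins position 14 is valine and
#' position 19 glutamic acid; DREB1-type proteins may carry a non-E residue
#' at 19 without losing DREB identity.
#'
#' @param protein ungapped protein sequence.
#' @param domain_start,domain_end 1-based inclusive domain extent.
#' @return named character vector \code{c(v14 = ..., e19 = ...)}.
#' @export
check_v14_e19 <- function(protein, domain_start, domain_end) {
  len <- domain_end - domain_start + 1L
  if (len < 19L)
    stop("domain of length ", len, " is shorter than 19 residues")
  if (domain_end > nchar(protein))
    stop("domain extent exceeds protein length")
  c(v14 = substr(protein, domain_start + 13L, domain_start + 13L),
    e19 = substr(protein, domain_start + 18L, domain_start + 18L))
}

#' Classify one protein at the superfamily level
#'
#' Applies the AP2/ERF decision tree in order: two or more AP2 domains give
#' \code{AP2}; at least one AP2 plus a B3 domain gives \code{RAV}; a single
#' AP2 domain lacking the conserved WLG motif within its span is
#' \code{atypical} (excluded from further subgrouping); a single
#' WLG-containing AP2 domain is \code{DREB-candidate} when the domain's 14th
#' residue is V, \code{ERF} when it is A, and otherwise decided by higher
#' global similarity to the DREB versus ERF domain consensus.
#'
#' @param protein ungapped protein sequence.
#' @param hits domain-hit data.frame rows for this protein
#'   ([read_domtblout()] layout).
#' @return a \code{classified_gene} list: \code{protein_id},
#'   \code{superfamily}, \code{subgroup}, \code{n_ap2_domains},
#'   \code{has_b3}, \code{domain_start}/\code{domain_end} (first AP2 hit),
#'   and diagnostic \code{flags}.
#' @export
classify_superfamily <- function(protein, hits) {
  ap2 <- hits[hits$domain_name == "AP2", , drop = FALSE]
  b3 <- hits[hits$domain_name == "B3", , drop = FALSE]
  if (nrow(ap2) == 0L)
    stop("not an AP2/ERF-superfamily protein (no AP2 domain hit)")
  ap2 <- ap2[order(ap2$start), , drop = FALSE]
  cl <- list(protein_id = if (nrow(hits)) hits$protein_id[1] else NA_character_,
             superfamily = NA_character_, subgroup = "unassigned",
             n_ap2_domains = nrow(ap2), has_b3 = nrow(b3) > 0L,
             domain_start = ap2$start[1], domain_end = ap2$end[1],
             flags = list(wlg = NA, v14 = NA_character_, e19 = NA_character_,
                          dreb1_nls = NA, dreb2_nls = NA, dsaw = NA,
                          lwsy = NA, cmiv1 = NA))
  if (nrow(ap2) >= 2L) {
    cl$superfamily <- "AP2"
    class(cl) <- "classified_gene"
    return(cl)
  }
  if (nrow(b3) >= 1L) {
    cl$superfamily <- "RAV"
    class(cl) <- "classified_gene"
    return(cl)
  }
  dom <- substr(protein, ap2$start[1], ap2$end[1])
  wlg <- nrow(scan_motif(dom, "WLG")) > 0L
  cl$flags$wlg <- wlg
  if (!wlg) {
    cl$superfamily <- "atypical"
    class(cl) <- "classified_gene"
    return(cl)
  }
  v <- tryCatch(check_v14_e19(protein, ap2$start[1], ap2$end[1]),
                error = function(e) c(v14 = NA_character_, e19 = NA_character_))
  cl$flags$v14 <- unname(v["v14"])
  cl$flags$e19 <- unname(v["e19"])
  cl$superfamily <- if (identical(unname(v["v14"]), "V")) "DREB-candidate"
    else if (identical(unname(v["v14"]), "A")) "ERF"
    else if (.protein_identity(dom, ap2_consensus("DREB")) >=
             .protein_identity(dom, ap2_consensus("ERF"))) "DREB-candidate"
    else "ERF"
  class(cl) <- "classified_gene"
  cl
}

#' @export
print.classified_gene <- function(x, ...) {
  cat("AP2/ERF classification:", x$protein_id, "\n",
      " superfamily:", x$superfamily, " subgroup:", x$subgroup, "\n",
      " AP2 domains:", x$n_ap2_domains, " B3:", x$has_b3, "\n")
  fl <- x$flags
  cat("  flags: wlg =", fl$wlg, "| v14 =", fl$v14, "| e19 =", fl$e19,
      "| dreb1_nls =", fl$dreb1_nls, "| cmiv1 =", fl$cmiv1,
      "| dsaw =", fl$dsaw, "| lwsy =", fl$lwsy, "\n")
  invisible(x)
}

#' Assign a DREB candidate to subgroup A-1 (DREB1) or A-2 (DREB2)
#'
#' A-1 when the DREB1-type NLS ends within \code{nls_window} residues
#' upstream of the AP2 domain; A-2 when a CMIV-1 motif occurs upstream of
#' the domain. Both kinds of evidence together raise an ambiguity error;
#' neither leaves the candidate as \code{other-A}. The DSAW (within
#' \code{dsaw_window} residues downstream of the domain), LWSY (final
#' \code{lwsy_window} residues) and PKK-like DREB2-NLS flags are recorded
#' regardless of the subgroup outcome.
#'
#' @param classified a \code{classified_gene} with superfamily
#'   \code{DREB-candidate}.
#' @param protein the ungapped protein sequence.
#' @param nls_window,dsaw_window,lwsy_window window sizes in residues.
#' @return the updated \code{classified_gene}.
#' @export
subgroup_dreb <- function(classified, protein, nls_window = 30L,
                          dsaw_window = 10L, lwsy_window = 15L) {
  if (!identical(classified$superfamily, "DREB-candidate"))
    stop("subgroup_dreb() requires a DREB-candidate classification")
  ds <- classified$domain_start
  de <- classified$domain_end
  up <- substr(protein, 1L, ds - 1L)

  nls1 <- scan_motif(up, "DREB1-NLS")
  a1 <- nrow(nls1) > 0L && any(nls1$end >= ds - 1L - nls_window)
  cmiv <- scan_motif(up, "CMIV-1")
  a2 <- nrow(cmiv) > 0L
  classified$flags$dreb1_nls <- a1
  classified$flags$cmiv1 <- a2
  classified$flags$dreb2_nls <- nrow(scan_motif(up, "DREB2-NLS")) > 0L

  down <- substr(protein, de + 1L, min(nchar(protein), de + dsaw_window +
                                         3L))
  dsaw <- scan_motif(down, "DSAW")
  classified$flags$dsaw <- nrow(dsaw) > 0L && any(dsaw$start <= dsaw_window)
  tail_seq <- substr(protein, max(1L, nchar(protein) - lwsy_window + 1L),
                     nchar(protein))
  classified$flags$lwsy <- nrow(scan_motif(tail_seq, "LWSY")) > 0L

  if (a1 && a2)
    stop("ambiguous DREB subgroup evidence for ", classified$protein_id,
         ": DREB1-NLS at [", paste(nls1$start, nls1$end, sep = "-",
                                   collapse = ","),
         "] and CMIV-1 at [", paste(cmiv$start, cmiv$end, sep = "-",
                                    collapse = ","), "]")
  classified$subgroup <- if (a1) "A-1" else if (a2) "A-2" else "other-A"
  classified
}

#' Classify a set of proteins end to end
#'
#' Runs [classify_superfamily()] on every protein with at least one AP2
#' domain hit, then [subgroup_dreb()] on the DREB candidates, and returns a
#' flat table.
#'
#' @param proteins named character vector of protein sequences.
#' @param hits domain-hit data.frame over all proteins.
#' @param ... passed to [subgroup_dreb()].
#' @return data.frame, one row per protein with >= 1 AP2 hit.
#' @export
classify_proteins <- function(proteins, hits, ...) {
  ids <- intersect(names(proteins), unique(hits$protein_id[
    hits$domain_name == "AP2"]))
  rows <- lapply(ids, function(id) {
    cl <- classify_superfamily(proteins[[id]],
                               hits[hits$protein_id == id, , drop = FALSE])
    cl$protein_id <- id
    if (identical(cl$superfamily, "DREB-candidate"))
      cl <- subgroup_dreb(cl, proteins[[id]], ...)
    data.frame(protein_id = id, superfamily = cl$superfamily,
               subgroup = cl$subgroup, n_ap2_domains = cl$n_ap2_domains,
               has_b3 = cl$has_b3,
               wlg = cl$flags$wlg, v14 = cl$flags$v14, e19 = cl$flags$e19,
               dreb1_nls = cl$flags$dreb1_nls,
               dreb2_nls = cl$flags$dreb2_nls, dsaw = cl$flags$dsaw,
               lwsy = cl$flags$lwsy, cmiv1 = cl$flags$cmiv1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Partition family genes into allelic loci
#'
#' In an autopolyploid genome, alleles of one locus sit on homologous
#' chromosomes (same chromosome number, different haplotype letter, e.g.
#' Chr2A/2B/2C/2D) and encode near-identical proteins. Genes are co-allelic
#' when both conditions hold (global protein identity >= \code{threshold});
#' the partition is the transitive closure. A qualifying pair on the same
#' haplotype is kept as separate loci with a warning.
#'
#' @param genes gene-model data.frame ([read_gff3()] layout).
#' @param proteins named character vector covering every
#'   \code{genes$protein_id}.
#' @param threshold identity threshold (fraction), default 0.95.
#' @return integer vector of locus ids, parallel to \code{genes} rows.
#' @export
group_alleles <- function(genes, proteins, threshold = 0.95) {
  n <- nrow(genes)
  if (any(!genes$protein_id %in% names(proteins)))
    stop("missing protein sequence for some genes")
  chr <- lapply(genes$chromosome, .parse_chromosome)
  pairs <- list()
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ci <- chr[[i]]; cj <- chr[[j]]
    if (is.na(ci$number) || is.na(cj$number) || ci$number != cj$number) next
    same_hap <- identical(ci$haplotype, cj$haplotype)
    pid <- .protein_identity(proteins[[genes$protein_id[i]]],
                             proteins[[genes$protein_id[j]]])
    if (pid < threshold) next
    if (same_hap) {
      warning("genes ", genes$gene_id[i], " and ", genes$gene_id[j],
              " meet the allele identity threshold but share haplotype ",
              genes$chromosome[i], "; kept as separate loci")
      next
    }
    pairs[[length(pairs) + 1L]] <- c(i, j)
  }
  .components(n, pairs)
}

#' Name family loci and alleles by chromosomal order
#'
#' Distinct loci are lettered A, B, C, ... in order of (chromosome
#' lexicographic, start ascending) of each locus's first-occurring allele;
#' alleles within a locus get suffixes -1..-k in the same coordinate order,
#' and single-allele loci carry no suffix. Names are invariant to the input
#' row order.
#'
#' @param genes gene-model data.frame.
#' @param loci integer locus ids from [group_alleles()] (or any partition).
#' @param prefix family name prefix, e.g. \code{"SsDREB1"}.
#' @return named character vector mapping \code{gene_id} to assigned name.
#' @export
assign_names <- function(genes, loci, prefix) {
  stopifnot(length(loci) == nrow(genes))
  key <- order(genes$chromosome, genes$start)
  first_rank <- vapply(split(seq_len(nrow(genes)), loci), function(idx)
    min(match(idx, key)), 1)
  locus_order <- rank(first_rank, ties.method = "first")
  if (length(first_rank) > 26L)
    stop("more than 26 loci; out of letters")
  out <- character(nrow(genes))
  for (lid in names(first_rank)) {
    idx <- which(loci == as.integer(lid))
    letter <- LETTERS[locus_order[lid]]
    idx <- idx[order(genes$chromosome[idx], genes$start[idx])]
    nm <- if (length(idx) == 1L) paste0(prefix, letter)
      else paste0(prefix, letter, "-", seq_along(idx))
    out[idx] <- nm
  }
  stats::setNames(out, genes$gene_id)
}
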