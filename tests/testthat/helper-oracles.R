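# Independent oracles and small fixture builders used across the tests.

# --- brute-force NG86 oracle -------------------------------------------------
# Deliberately separate implementation: translation through seqinr, explicit
# enumeration of every substitution ordering. Conventions match the method
# definition: neighbour changes creating stops count as nonsynonymous sites;
# pathways through stops are excluded (all orderings used, stop steps
# nonsynonymous, only when every ordering is blocked).

.oracle_translate <- function(codon)
  seqinr::translate(seqinr::s2c(tolower(codon)))

.oracle_codons <- function(x)
  substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))

.oracle_sites <- function(codon) {
  aa <- .oracle_translate(codon)
  syn <- 0
  for (pos in 1:3) {
    for (nt in c("A", "C", "G", "T")) {
      if (substr(codon, pos, pos) == nt) next
      alt <- codon
      substr(alt, pos, pos) <- nt
      alt_aa <- .oracle_translate(alt)
      if (alt_aa != "*" && alt_aa == aa) syn <- syn + 1 / 3
    }
  }
  c(syn, 3 - syn)
}

.oracle_orderings <- function(v) {
  if (length(v) <= 1) return(list(v))
  res <- list()
  for (k in seq_along(v))
    for (tail in .oracle_orderings(v[-k])) res[[length(res) + 1]] <- c(v[k], tail)
  res
}

.oracle_pair_subs <- function(a, b) {
  diffs <- which(seqinr::s2c(a) != seqinr::s2c(b))
  if (!length(diffs)) return(c(0, 0))
  score <- function(order, skip_stop) {
    cur <- a
    sd <- nd <- 0
    for (pos in order) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      if (.oracle_translate(nxt) == "*") {
        if (skip_stop) return(NULL)
        nd <- nd + 1
      } else if (.oracle_translate(cur) == .oracle_translate(nxt)) {
        sd <- sd + 1
      } else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  orders <- .oracle_orderings(diffs)
  res <- Filter(Negate(is.null), lapply(orders, score, skip_stop = TRUE))
  if (!length(res)) res <- lapply(orders, score, skip_stop = FALSE)
  Reduce(`+`, res) / length(res)
}

oracle_ng86 <- function(cds_a, cds_b) {
  ca <- .oracle_codons(cds_a)
  cb <- .oracle_codons(cds_b)
  keep <- vapply(seq_along(ca), function(i)
    grepl("^[ACGT]{3}$", ca[i]) && grepl("^[ACGT]{3}$", cb[i]) &&
      .oracle_translate(ca[i]) != "*" && .oracle_translate(cb[i]) != "*",
    TRUE)
  ca <- ca[keep]; cb <- cb[keep]
  sa <- rowSums(vapply(ca, .oracle_sites, c(0, 0)))
  sb <- rowSums(vapply(cb, .oracle_sites, c(0, 0)))
  subs <- rowSums(vapply(seq_along(ca), function(i)
    .oracle_pair_subs(ca[i], cb[i]), c(0, 0)))
  list(S = (sa[1] + sb[1]) / 2, N = (sa[2] + sb[2]) / 2,
       Sd = subs[1], Nd = subs[2])
}

# random stop-free CDS of n codons
random_sense_cds <- function(n) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste(sample(sense, n, replace = TRUE), collapse = "")
}

# random additive distance matrix and its generating (unrooted) topology
random_additive <- function(n) {
  tr <- ape::rtree(n)
  list(tree = ape::unroot(tr), d = ape::cophenetic.phylo(tr))
}

random_protein_seq <- function(n) {
  aa <- c("A","R","N","D","C","E","Q","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# two-clade toy alignment: 20 split-informative columns + per-leaf private
# columns, so the central bipartition carries maximal signal
two_clade_alignment <- function() {
  width <- 42L
  base_a <- strsplit(paste(rep("A", width), collapse = ""), "")[[1]]
  base_c <- base_a; base_c[1:20] <- "C"
  mk <- function(base, private) {
    s <- base
    s[private] <- "W"
    paste(s, collapse = "")
  }
  c(a1 = mk(base_a, 21:22), a2 = mk(base_a, 23:24), a3 = mk(base_a, 25:26),
    b1 = mk(base_c, 27:28), b2 = mk(base_c, 29:30), b3 = mk(base_c, 31:32))
}
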