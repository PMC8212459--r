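# --- NG86 codon counting ----------------------------------------------------

# per-codon results are memoized (at most 61 codons / 61x61 pairs)
.memo <- new.env(parent = emptyenv())

.memoize <- function(key, value) {
  if (!is.null(.memo[[key]])) return(.memo[[key]])
  .memo[[key]] <- value
  value
}

# fractional synonymous/nonsynonymous site counts of one codon: at each of
# the three positions, the fraction of the three single-nucleotide changes
# that preserve the amino acid. Changes creating a stop codon count as
# nonsynonymous, which keeps s + n = 3 exactly per codon.
.codon_sites <- function(codon) {
  nts <- c("A", "C", "G", "T")
  aa <- .translate_codon(codon)
  s <- 0
  cs <- .chars(codon)
  for (pos in 1:3) {
    for (nt in setdiff(nts, cs[pos])) {
      alt <- cs
      alt[pos] <- nt
      alt <- paste(alt, collapse = "")
      if (!.is_stop(alt) && .translate_codon(alt) == aa) s <- s + 1 / 3
    }
  }
  c(syn = s, nonsyn = 3 - s)
}

.perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in .perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# pathway-averaged (sd, nd) between two codons: all minimal substitution
# orderings, equal weights, pathways through stop codons excluded; when all
# pathways are blocked, all orderings are used with stop steps counted as
# nonsynonymous.
.codon_path_counts <- function(a, b) {
  ca <- .chars(a)
  cb <- .chars(b)
  d <- which(ca != cb)
  if (!length(d)) return(c(sd = 0, nd = 0))
  walk <- function(order, allow_stop) {
    cur <- ca
    sd <- nd <- 0
    for (pos in order) {
      nxt <- cur
      nxt[pos] <- cb[pos]
      from <- paste(cur, collapse = "")
      to <- paste(nxt, collapse = "")
      if (.is_stop(to) && !allow_stop) return(NULL)
      if (!.is_stop(to) && .translate_codon(from) == .translate_codon(to))
        sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  paths <- Filter(Negate(is.null), lapply(.perms(d), walk, allow_stop = FALSE))
  if (!length(paths)) paths <- lapply(.perms(d), walk, allow_stop = TRUE)
  Reduce(`+`, paths) / length(paths)
}

.codon_sites_m <- function(codon)
  .memoize(paste0("s", codon), .codon_sites(codon))

.codon_path_counts_m <- function(a, b)
  .memoize(paste0("p", a, b), .codon_path_counts(a, b))

# single-nucleotide, non-stop neighbours of a sense codon, split by effect
.codon_neighbors <- function(codon) {
  .memoize(paste0("n", codon), {
    nts <- c("A", "C", "G", "T")
    cs <- .chars(codon)
    aa <- .translate_codon(codon)
    syn <- character(); non <- character()
    for (pos in 1:3) for (nt in setdiff(nts, cs[pos])) {
      alt <- cs; alt[pos] <- nt
      altc <- paste(alt, collapse = "")
      if (.is_stop(altc)) next
      if (.translate_codon(altc) == aa) syn <- c(syn, altc)
      else non <- c(non, altc)
    }
    list(syn = syn, non = non)
  })
}

# analyzable-codon mask: both codons pure ACGT and neither a stop
.codon_mask <- function(codons_a, codons_b) {
  ok <- function(x) grepl("^[ACGT]{3}$", x) & !vapply(x, function(c)
    isTRUE(.is_stop(c)), TRUE)
  ok(codons_a) & ok(codons_b)
}

#' Nei-Gojobori (1986) Ka/Ks for a pair of coding sequences
#'
#' Synonymous/nonsynonymous site fractions come from single-nucleotide
#' neighbour enumeration per codon, averaged over the two sequences;
#' multi-hit codons are averaged over all minimal substitution pathways with
#' equal weights (pathways through stop codons excluded). Proportions are
#' Jukes-Cantor corrected: \code{Ka = -3/4 log(1 - 4 pn / 3)}, likewise Ks.
#' Codons containing a gap, an ambiguous base or a stop in either sequence
#' are excluded pairwise.
#'
#' @param cds_a,cds_b in-frame CDS strings of equal length (gaps allowed in
#'   codon-aligned multiples of 3); alternatively \code{cds_a} may be a
#'   2-sequence \code{codon_alignment} from [codon_align()].
#' @return object of class \code{kaks}: fractional site counts \code{N},
#'   \code{S}, pathway-averaged substitution counts \code{Nd}, \code{Sd},
#'   proportions \code{pn}, \code{ps}, corrected rates \code{ka}, \code{ks},
#'   \code{ratio} (Ka/Ks; \code{NA} when Ks is 0 or saturated),
#'   \code{saturated}, \code{n_codons} (analyzable), and \code{p_value}
#'   (filled by [fisher_selection_test()]).
#' @export
ng86 <- function(cds_a, cds_b = NULL) {
  if (is.null(cds_b)) {
    if (length(cds_a) != 2L)
      stop("supply two sequences or a 2-sequence codon alignment")
    cds_b <- cds_a[[2]]
    cds_a <- cds_a[[1]]
  }
  if (nchar(cds_a) != nchar(cds_b))
    stop("aligned CDS lengths differ")
  codons_a <- .split_codons(toupper(cds_a))
  codons_b <- .split_codons(toupper(cds_b))
  keep <- .codon_mask(codons_a, codons_b)
  if (!any(keep)) stop("no analyzable codons")
  codons_a <- codons_a[keep]
  codons_b <- codons_b[keep]

  sites_a <- vapply(codons_a, .codon_sites_m, c(syn = 0, nonsyn = 0))
  sites_b <- vapply(codons_b, .codon_sites_m, c(syn = 0, nonsyn = 0))
  S <- (sum(sites_a["syn", ]) + sum(sites_b["syn", ])) / 2
  N <- (sum(sites_a["nonsyn", ]) + sum(sites_b["nonsyn", ])) / 2

  subs <- mapply(.codon_path_counts_m, codons_a, codons_b)
  Sd <- sum(subs["sd", ])
  Nd <- sum(subs["nd", ])

  pn <- Nd / N
  ps <- Sd / S
  saturated <- pn >= 0.75 || ps >= 0.75
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  ka <- if (saturated) NA_real_ else jc(pn)
  ks <- if (saturated) NA_real_ else jc(ps)
  ratio <- if (!saturated && !is.na(ks) && ks > 0) ka / ks else NA_real_
  structure(list(N = N, S = S, Nd = Nd, Sd = Sd, pn = pn, ps = ps,
                 ka = ka, ks = ks, ratio = ratio, saturated = saturated,
                 n_codons = sum(keep), p_value = NA_real_),
            class = "kaks")
}

#' @export
print.kaks <- function(x, ...) {
  cat(sprintf(
    "NG86 Ka/Ks over %d codons\n  N = %.3f, S = %.3f, Nd = %.3f, Sd = %.3f\n",
    x$n_codons, x$N, x$S, x$Nd, x$Sd))
  if (x$saturated) {
    cat("  saturated (pn or ps >= 3/4); rates undefined\n")
  } else {
    cat(sprintf("  Ka = %.4f, Ks = %.4f, Ka/Ks = %s\n", x$ka, x$ks,
                if (is.na(x$ratio)) "undefined" else sprintf("%.3f", x$ratio)))
  }
  if (!is.na(x$p_value))
    cat(sprintf("  Fisher exact p = %.4g\n", x$p_value))
  invisible(x)
}

#' Fisher exact test for selection on an NG86 result
#'
#' Two-sided Fisher exact test on the 2x2 table of rounded substitution and
#' non-substituted site counts \code{[Nd, N - Nd; Sd, S - Sd]}
#' (round-half-away-from-zero; the fractional NG86 counts make this an
#' approximation).
#'
#' @param result a \code{kaks} object.
#' @return the \code{kaks} object with \code{p_value} filled.
#' @export
fisher_selection_test <- function(result) {
  stopifnot(inherits(result, "kaks"))
  if (result$saturated) stop("result is saturated; test undefined")
  rnd <- function(x) sign(x) * floor(abs(x) + 0.5)
  tab <- matrix(rnd(c(result$Nd, result$N - result$Nd,
                      result$Sd, result$S - result$Sd)),
                nrow = 2, byrow = TRUE)
  if (any(tab < 0)) stop("negative rounded cell in Fisher table")
  result$p_value <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  result
}

#' Convert synonymous divergence to time
#'
#' \code{T = Ks / (2 r) * 1e-6} million years, with a default substitution
#' clock of \code{r = 6.1e-9} synonymous substitutions per site per year (a
#' grass-lineage rate).
#'
#' @param ks synonymous substitutions per synonymous site (vectorised).
#' @param rate clock rate, substitutions/site/year.
#' @return data.frame of class \code{divergence_estimate} with columns
#'   \code{ks}, \code{rate}, \code{t_mya}.
#' @export
divergence_time <- function(ks, rate = 6.1e-9) {
  if (any(is.na(ks)) || any(ks < 0)) stop("ks must be non-negative")
  if (rate <= 0) stop("rate must be positive")
  structure(data.frame(ks = ks, rate = rate, t_mya = ks / (2 * rate) * 1e-6),
            class = c("divergence_estimate", "data.frame"))
}

# --- protein-guided codon alignment ----------------------------------------

#' Thread a protein alignment onto coding sequences
#'
#' Each ungapped protein must translate its CDS exactly under the standard
#' genetic code (a single terminal stop codon is stripped); each protein gap
#' column becomes one codon gap.
#'
#' @param protein_alignment named character vector of equal-width gapped
#'   protein sequences.
#' @param cds named character vector of ungapped coding sequences covering
#'   every alignment id.
#' @return named character vector of gapped CDS strings (class
#'   \code{codon_alignment}), width 3x the protein alignment width.
#' @export
codon_align <- function(protein_alignment, cds) {
  widths <- nchar(protein_alignment)
  if (length(unique(widths)) != 1L)
    stop("protein alignment rows differ in width")
  missing <- setdiff(names(protein_alignment), names(cds))
  if (length(missing)) stop("no CDS for: ", paste(missing, collapse = ", "))
  out <- vapply(names(protein_alignment), function(id) {
    prot_aln <- protein_alignment[[id]]
    prot <- gsub("-", "", prot_aln, fixed = TRUE)
    d <- toupper(cds[[id]])
    L <- nchar(prot)
    if (nchar(d) == 3L * (L + 1L)) {
      last <- substr(d, nchar(d) - 2L, nchar(d))
      if (isTRUE(.is_stop(last))) d <- substr(d, 1L, nchar(d) - 3L)
    }
    if (nchar(d) != 3L * L)
      stop("CDS length ", nchar(d), " of '", id, "' does not match 3 x ",
           L, " protein residues")
    tr <- .chars(.translate_cds(d))
    pr <- .chars(prot)
    bad <- which(tr != pr & pr != "X")
    if (length(bad))
      stop("translation mismatch for '", id, "' at protein position ",
           bad[1], ": ", pr[bad[1]], " vs codon ", tr[bad[1]])
    codons <- .split_codons(d)
    k <- 0L
    paste(vapply(.chars(prot_aln), function(ch) {
      if (ch == "-") return("---")
      k <<- k + 1L
      codons[[k]]
    }, ""), collapse = "")
  }, "")
  structure(out, class = "codon_alignment")
}

# --- distances, NJ, bootstrap ----------------------------------------------

#' Poisson-corrected protein distances with pairwise deletion
#'
#' For each sequence pair, alignment sites where either member carries a gap
#' or an X are removed (pairwise deletion); \code{p} is the fraction of
#' differing remaining sites and \code{d = -log(1 - p)}. A pair with
#' \code{p = 1} gets an undefined (\code{NA}) distance.
#'
#' @param alignment named character vector of equal-width gapped protein
#'   sequences (>= 2).
#' @return symmetric labelled distance matrix with zero diagonal.
#' @export
poisson_distance <- function(alignment) {
  if (length(alignment) < 2L) stop("need at least two sequences")
  if (length(unique(nchar(alignment))) != 1L)
    stop("alignment rows differ in width")
  labs <- names(alignment)
  if (is.null(labs) || any(!nzchar(labs))) stop("sequences must be named")
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  bad <- m == "-" | m == "X" | m == "?" | m == "."
  n <- length(alignment)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    use <- !bad[i, ] & !bad[j, ]
    if (!any(use))
      stop("no comparable sites between '", labs[i], "' and '", labs[j], "'")
    p <- mean(m[i, use] != m[j, use])
    d[i, j] <- d[j, i] <- if (p >= 1) NA_real_ else -log(1 - p)
  }
  d
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Standard Q-criterion agglomeration; ties are broken by the smallest
#' (i, j) index pair in the current matrix order, the final three nodes are
#' resolved exactly by the three-point formula, and negative branch lengths
#' are clamped to zero unless disabled.
#'
#' @param d symmetric labelled distance matrix (n >= 3, no NA).
#' @param clamp_negative clamp negative branch lengths to 0 (default TRUE).
#' @return an unrooted \pkg{ape} \code{phylo} tree.
#' @export
nj_tree <- function(d, clamp_negative = TRUE) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least three taxa")
  if (anyNA(d)) stop("distance matrix contains undefined entries")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  labs <- rownames(d)
  if (is.null(labs)) stop("distance matrix must be labelled")
  cl <- function(x) if (clamp_negative) max(x, 0) else x
  br <- function(x) sprintf("%.15g", x)
  node <- labs
  D <- d
  while (length(node) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    vi <- cl(D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    vj <- cl(D[i, j] - D[i, j] / 2 - (r[i] - r[j]) / (2 * (m - 2)))
    merged <- paste0("(", node[i], ":", br(vi), ",", node[j], ":", br(vj), ")")
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    dk <- dk[-c(i, j)]
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, dk), c(dk, 0))
    node <- c(node[-c(i, j)], merged)
  }
  va <- cl((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  vb <- cl((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  vc <- cl((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- paste0("(", node[1], ":", br(va), ",", node[2], ":", br(vb), ",",
                node[3], ":", br(vc), ");")
  ape::read.tree(text = nwk)
}

#' Bootstrap support for the neighbor-joining tree
#'
#' Alignment columns are resampled with replacement \code{n_reps} times;
#' each replicate tree is built by [poisson_distance()] then [nj_tree()].
#' Support for each bipartition of the full-data tree is the percentage of
#' replicate trees containing it (not a majority-rule consensus). Replicates
#' with undefined distances are skipped and tallied in the
#' \code{bootstrap_skipped} attribute.
#'
#' @param alignment named character vector of gapped protein sequences.
#' @param n_reps number of bootstrap replicates (0 = no supports).
#' @param seed RNG seed (required when \code{n_reps > 0}).
#' @param clamp_negative passed to [nj_tree()].
#' @return the full-data \code{phylo} tree, with integer percentage supports
#'   in \code{node.label} when \code{n_reps > 0}.
#' @export
bootstrap_support <- function(alignment, n_reps = 1000L, seed = NULL,
                              clamp_negative = TRUE) {
  full <- nj_tree(poisson_distance(alignment), clamp_negative)
  if (n_reps == 0L) return(full)
  if (is.null(seed)) stop("seed is required for the bootstrap")
  chars <- do.call(rbind, strsplit(alignment, ""))
  rownames(chars) <- names(alignment)
  ncol_aln <- ncol(chars)
  if (ncol_aln < 1L) stop("alignment has no columns")
  .with_seed(seed, {
    boot <- list()
    skipped <- 0L
    for (rep in seq_len(n_reps)) {
      cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
      sub <- apply(chars[, cols, drop = FALSE], 1, paste, collapse = "")
      t <- tryCatch({
        dd <- poisson_distance(sub)
        if (anyNA(dd)) NULL else nj_tree(dd, clamp_negative)
      }, error = function(e) NULL)
      if (is.null(t)) skipped <- skipped + 1L else boot[[length(boot) + 1L]] <- t
    }
    if (!length(boot)) stop("all bootstrap replicates were skipped")
    counts <- ape::prop.clades(full, boot, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    full$node.label <- as.character(round(100 * counts / length(boot)))
    attr(full, "bootstrap_skipped") <- skipped
    attr(full, "bootstrap_reps") <- n_reps
    full
  })
}
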