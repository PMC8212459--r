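#' Genes expressed at very low levels or undetectable in every sample
#'
#' @param fpkm genes x samples FPKM matrix (non-negative).
#' @param threshold detection threshold (default FPKM 1).
#' @return character vector of gene ids.
#' @export
detect_low_expression <- function(fpkm, threshold = 1) {
  .check_fpkm(fpkm)
  rownames(fpkm)[apply(fpkm < threshold, 1, all)]
}

.check_fpkm <- function(fpkm) {
  if (!is.matrix(fpkm) || is.null(rownames(fpkm)) || is.null(colnames(fpkm)))
    stop("fpkm must be a matrix with gene and sample names")
  if (any(fpkm < 0)) stop("FPKM values must be non-negative")
}

#' Group-preferential expression calls
#'
#' A gene is preferential for group a when \code{mean(a) / (mean(b) +
#' pseudocount) >= min_fold} and \code{mean(a)} reaches the detection
#' threshold; symmetric for group b.
#'
#' @param fpkm genes x samples FPKM matrix.
#' @param samples_a,samples_b sample ids of the two groups.
#' @param group_a,group_b group labels used in the calls.
#' @param min_fold fold-change cutoff (default 2).
#' @param min_level detection threshold on the preferred-group mean.
#' @param pseudocount added to denominators (default 0.01).
#' @return data.frame with \code{gene}, \code{call}
#'   (\code{"preferential(<group>)"} or \code{"none"}), \code{fold}.
#' @export
group_preference <- function(fpkm, samples_a, samples_b, group_a = "a",
                             group_b = "b", min_fold = 2, min_level = 1,
                             pseudocount = 0.01) {
  .check_fpkm(fpkm)
  missing <- setdiff(c(samples_a, samples_b), colnames(fpkm))
  if (length(missing))
    stop("unknown group sample(s): ", paste(missing, collapse = ", "))
  ma <- rowMeans(fpkm[, samples_a, drop = FALSE])
  mb <- rowMeans(fpkm[, samples_b, drop = FALSE])
  fold_a <- ma / (mb + pseudocount)
  fold_b <- mb / (ma + pseudocount)
  call <- ifelse(fold_a >= min_fold & ma >= min_level,
                 paste0("preferential(", group_a, ")"),
                 ifelse(fold_b >= min_fold & mb >= min_level,
                        paste0("preferential(", group_b, ")"), "none"))
  data.frame(gene = rownames(fpkm), call = call,
             fold = pmax(fold_a, fold_b), stringsAsFactors = FALSE)
}

#' Expression trend along an ordered gradient
#'
#' Spearman rank correlation of FPKM against position: \code{|rho| >=
#' rho_cutoff} gives \code{increasing}/\code{decreasing}; otherwise a gene
#' whose maximum lies at an interior position and exceeds every other
#' position by \code{peak_fold} is \code{peaked(<position>)}; else
#' \code{none}.
#'
#' @param fpkm genes x samples FPKM matrix.
#' @param samples ordered sample ids along the gradient (>= 3).
#' @param positions numeric positions (default \code{seq_along(samples)}).
#' @param rho_cutoff Spearman cutoff (default 0.8).
#' @param peak_fold interior-peak margin (default 2).
#' @return data.frame with \code{gene}, \code{call}, \code{rho}.
#' @export
gradient_trend <- function(fpkm, samples, positions = seq_along(samples),
                           rho_cutoff = 0.8, peak_fold = 2) {
  .check_fpkm(fpkm)
  if (length(samples) < 3L) stop("need at least 3 ordered positions")
  x <- fpkm[, samples, drop = FALSE]
  res <- lapply(seq_len(nrow(x)), function(i) {
    v <- x[i, ]
    rho <- if (stats::sd(v) == 0) 0 else
      suppressWarnings(stats::cor(v, positions, method = "spearman"))
    if (is.na(rho)) rho <- 0
    call <- if (rho >= rho_cutoff) "increasing"
      else if (rho <= -rho_cutoff) "decreasing"
      else {
        k <- which.max(v)
        if (k > 1L && k < length(v) && all(v[k] >= peak_fold * v[-k]))
          paste0("peaked(", positions[k], ")") else "none"
      }
    data.frame(gene = rownames(x)[i], call = call, rho = rho,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Light- versus dark-phase contrast over diurnal cycles
#'
#' A gene is \code{light-elevated} when \code{mean(light) / (mean(dark) +
#' pseudocount) >= min_fold} independently in every cycle series.
#'
#' @param fpkm genes x samples FPKM matrix.
#' @param light,dark sample ids of the two phases.
#' @param series named vector/factor assigning each of those samples to a
#'   cycle series; default a single series.
#' @param min_fold fold cutoff (default 2).
#' @param pseudocount added to the dark-phase mean.
#' @return data.frame with \code{gene}, \code{call}, \code{min_fold_seen}.
#' @export
diurnal_contrast <- function(fpkm, light, dark, series = NULL, min_fold = 2,
                             pseudocount = 0.01) {
  .check_fpkm(fpkm)
  if (!length(light) || !length(dark)) stop("empty phase sample set")
  if (is.null(series))
    series <- stats::setNames(rep("cycle1", length(c(light, dark))),
                              c(light, dark))
  folds <- sapply(unique(series), function(s) {
    l <- intersect(light, names(series)[series == s])
    d <- intersect(dark, names(series)[series == s])
    if (!length(l) || !length(d)) stop("empty phase set in series ", s)
    rowMeans(fpkm[, l, drop = FALSE]) /
      (rowMeans(fpkm[, d, drop = FALSE]) + pseudocount)
  })
  folds <- matrix(folds, nrow = nrow(fpkm))
  worst <- apply(folds, 1, min)
  data.frame(gene = rownames(fpkm),
             call = ifelse(worst >= min_fold, "light-elevated", "none"),
             min_fold_seen = worst, stringsAsFactors = FALSE)
}

#' Stress induction/repression calls from paired treated-control samples
#'
#' Per pair, \code{fold = (treated + pseudocount) / (control +
#' pseudocount)}; a gene is \code{induced} when \code{fold >= min_fold} and
#' the treated value reaches \code{min_fpkm}, \code{repressed}
#' symmetrically. With several pairs the per-pair calls are combined under
#' the \code{all} or \code{any} policy.
#'
#' @param fpkm genes x samples FPKM matrix.
#' @param treated,control equal-length vectors of paired sample ids.
#' @param min_fold fold cutoff (default 2).
#' @param min_fpkm detection floor on the higher member (default 1).
#' @param pseudocount ratio pseudocount (default 0.01).
#' @param policy \code{"all"} (every pair must agree) or \code{"any"}.
#' @return data.frame with \code{gene}, \code{call}, \code{fold} (geometric
#'   mean over pairs).
#' @export
stress_response <- function(fpkm, treated, control, min_fold = 2,
                            min_fpkm = 1, pseudocount = 0.01,
                            policy = c("all", "any")) {
  .check_fpkm(fpkm)
  policy <- match.arg(policy)
  if (length(treated) != length(control))
    stop("unpaired sample: treated and control differ in length")
  comb <- if (policy == "all") function(x) all(x) else function(x) any(x)
  t_m <- fpkm[, treated, drop = FALSE]
  c_m <- fpkm[, control, drop = FALSE]
  fold <- (t_m + pseudocount) / (c_m + pseudocount)
  ind <- fold >= min_fold & t_m >= min_fpkm
  rep_ <- (1 / fold) >= min_fold & c_m >= min_fpkm
  call <- vapply(seq_len(nrow(fpkm)), function(i) {
    if (comb(ind[i, ])) "induced"
    else if (comb(rep_[i, ])) "repressed"
    else "none"
  }, "")
  data.frame(gene = rownames(fpkm), call = call,
             fold = exp(rowMeans(log(fold))), stringsAsFactors = FALSE)
}

#' Concordance between RNA-seq FPKM and qRT-PCR relative expression
#'
#' @param fpkm,qpcr paired numeric vectors (length >= 3).
#' @return squared Pearson correlation (R^2).
#' @export
qpcr_concordance <- function(fpkm, qpcr) {
  if (length(fpkm) != length(qpcr) || length(fpkm) < 3L)
    stop("need paired vectors of length >= 3")
  if (stats::sd(fpkm) == 0 || stats::sd(qpcr) == 0)
    stop("zero variance in one of the vectors")
  stats::cor(fpkm, qpcr)^2
}

#' Score recovery of planted expression patterns
#'
#' Evaluates each gene of a [make_expression_fixture()] object under the
#' analysis its planted pattern belongs to and reports whether the planted
#' call is recovered.
#'
#' @param fixture output of [make_expression_fixture()].
#' @param low_threshold,min_fold analysis parameters.
#' @return data.frame with \code{gene}, \code{planted}, \code{recovered}.
#' @export
classify_expression_fixture <- function(fixture, low_threshold = 1,
                                        min_fold = 2) {
  fpkm <- fixture$fpkm
  design <- fixture$design
  s <- function(...) design$sample[...]
  low <- detect_low_expression(fpkm, low_threshold)
  pref <- group_preference(fpkm, s(design$group == "leaf"),
                           s(design$group == "stalk"), "leaf", "stalk",
                           min_fold = min_fold)
  grad <- gradient_trend(fpkm, s(design$analysis == "gradient"))
  di_samp <- design[design$analysis == "diurnal", ]
  diur <- diurnal_contrast(fpkm, di_samp$sample[di_samp$group == "light"],
                           di_samp$sample[di_samp$group == "dark"],
                           series = stats::setNames(di_samp$series,
                                                    di_samp$sample),
                           min_fold = min_fold)
  cold <- stress_response(fpkm, "cold_treated", "cold_control",
                          min_fold = min_fold)
  drought <- stress_response(fpkm, "drought_treated", "drought_control",
                             min_fold = min_fold)
  one <- function(df, gene) df$call[df$gene == gene]
  rec <- vapply(seq_len(nrow(fixture$truth)), function(i) {
    g <- fixture$truth$gene[i]
    switch(fixture$truth$pattern[i],
      "undetectable" = g %in% low,
      "constitutive" = !(g %in% low) && one(pref, g) == "none",
      "leaf-preferential" = one(pref, g) == "preferential(leaf)",
      "increasing" = one(grad, g) == "increasing",
      "decreasing" = one(grad, g) == "decreasing",
      "light-elevated" = one(diur, g) == "light-elevated",
      "drought-induced" = one(drought, g) == "induced",
      "cold-induced" = one(cold, g) == "induced")
  }, TRUE)
  data.frame(gene = fixture$truth$gene, planted = fixture$truth$pattern,
             recovered = rec, stringsAsFactors = FALSE)
}
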