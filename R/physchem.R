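#' Physicochemical profile of a protein (ProtParam-style)
#'
#' Computes length, molecular weight (sum of average residue masses plus one
#' water), theoretical pI (bisection on the net charge using the Bjellqvist
#' pKa set), GRAVY (mean Kyte-Doolittle hydropathy), aliphatic index
#' (\code{100 * (fA + 2.9 fV + 3.9 (fI + fL))} with mole fractions) and
#' instability index (\code{10/L * sum DIWV(dipeptides)}, Guruprasad
#' weights).
#'
#' Unknown residues \code{X} are tolerated for MW/GRAVY/AI (skipped, with
#' length renormalisation) but raise an error for pI and the instability
#' index.
#'
#' @param protein ungapped protein sequence.
#' @param pi_tol bisection tolerance for pI, in pH units.
#' @return object of class \code{physchem_profile}: list with
#'   \code{length_aa}, \code{mw}, \code{pi}, \code{gravy},
#'   \code{aliphatic_index}, \code{instability_index}.
#' @export
physchem <- function(protein, pi_tol = 1e-4) {
  if (!nzchar(protein)) stop("empty sequence")
  if (grepl("-", protein, fixed = TRUE)) stop("protein must be ungapped")
  s <- .chars(protein)
  bad <- setdiff(s, c(.AA20, "X"))
  if (length(bad)) stop("illegal residue '", bad[1], "'")
  known <- s[s != "X"]
  if (!length(known)) stop("sequence contains only unknown residues")
  has_x <- length(known) < length(s)

  mw <- sum(.RESIDUE_MASS[known]) + .WATER_MASS
  gravy <- mean(.KD_HYDROPATHY[known])
  f <- table(factor(known, levels = names(.RESIDUE_MASS))) / length(known)
  ai <- 100 * (f[["A"]] + 2.9 * f[["V"]] + 3.9 * (f[["I"]] + f[["L"]]))

  pi <- if (has_x) NA_real_ else .isoelectric_point(s, tol = pi_tol)
  ii <- if (has_x || length(s) < 2L) NA_real_ else {
    dip <- .DIWV[cbind(s[-length(s)], s[-1L])]
    10 / length(s) * sum(dip)
  }
  if (has_x)
    warning("sequence contains X; pI and instability index not computed")
  structure(list(length_aa = length(s), mw = mw, pi = pi, gravy = gravy,
                 aliphatic_index = unname(ai), instability_index = ii),
            class = "physchem_profile")
}

#' @export
print.physchem_profile <- function(x, ...) {
  cat(sprintf(
    "Protein profile: %d aa | MW %.2f Da | pI %.2f | GRAVY %.3f | AI %.2f | II %.2f\n",
    x$length_aa, x$mw, x$pi, x$gravy, x$aliphatic_index,
    x$instability_index))
  invisible(x)
}

# net charge at a given pH with Bjellqvist/ProtParam pKa values
.net_charge <- function(counts, nterm_res, pH) {
  pos <- 1 / (1 + 10^(pH - .PKA_NTERM_DEFAULT))
  nt <- .PKA_NTERM[nterm_res]
  if (!is.na(nt)) pos <- 1 / (1 + 10^(pH - nt))
  for (r in names(.PKA_SIDE_POS))
    pos <- pos + counts[[r]] / (1 + 10^(pH - .PKA_SIDE_POS[[r]]))
  neg <- 1 / (1 + 10^(.PKA_CTERM - pH))
  for (r in names(.PKA_SIDE_NEG))
    neg <- neg + counts[[r]] / (1 + 10^(.PKA_SIDE_NEG[[r]] - pH))
  pos - neg
}

.isoelectric_point <- function(s, tol = 1e-4) {
  counts <- as.list(table(factor(s, levels = .AA20)))
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (.net_charge(counts, s[1], mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
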