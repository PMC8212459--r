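#' Reference coordinates of the tandem-duplicated SsDREB1 alleles
#'
#' The published chromosomal coordinates of the 12 \emph{S. spontaneum}
#' DREB1 allele genes that form four tandem-duplication clusters on
#' chromosomes 2B, 2C and 2D (two clusters on 2D). Used as input for
#' windowed tandem-cluster detection.
#'
#' @return data.frame with \code{cluster}, \code{gene}, \code{chromosome},
#'   \code{start}, \code{end}.
#' @export
ssdreb_tandem_geometry <- function() {
  data.frame(
    cluster = c(1L, 1L, 2L, 2L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 4L),
    gene = c("SsDREB1C-2", "SsDREB1I",
             "SsDREB1B-3", "SsDREB1G", "SsDREB1F-2", "SsDREB1H",
             "SsDREB1A-4",
             "SsDREB1B-2", "SsDREB1C-1", "SsDREB1D",
             "SsDREB1A-3", "SsDREB1E"),
    chromosome = c("Chr2D", "Chr2D",
                   "Chr2D", "Chr2D", "Chr2D", "Chr2D", "Chr2D",
                   "Chr2B", "Chr2B", "Chr2B",
                   "Chr2C", "Chr2C"),
    start = c(22208944L, 22226936L,
              22092288L, 22107221L, 22113187L, 22117638L, 22126308L,
              26564597L, 26597272L, 26612975L,
              30543015L, 30554216L),
    end = c(22209639L, 22227607L,
            22093103L, 22108036L, 22113903L, 22118345L, 22127015L,
            26565409L, 26598093L, 26613670L,
            30543701L, 30554923L),
    stringsAsFactors = FALSE)
}

#' Reference synonymous divergence of SsDREB1-SbDREB1 ortholog pairs
#'
#' Published pairwise Ks values between tandem-duplicated \emph{S.
#' spontaneum} DREB1 genes and their sorghum orthologs, together with the
#' published divergence times (million years) derived from them under the
#' 6.1e-9 substitutions/site/year clock.
#'
#' @return data.frame with \code{pair}, \code{ks}, \code{t_mya_published}.
#' @export
ssdreb_divergence_pairs <- function() {
  data.frame(
    pair = c("SbDREB1A-SsDREB1C-2", "SbDREB1A-SsDREB1D",
             "SbDREB1A-SsDREB1I", "SbDREB1D-SsDREB1E",
             "SbDREB1D-SsDREB1H", "SbDREB1A-SsDREB1C-1",
             "SbDREB1B-SsDREB1B-2", "SbDREB1B-SsDREB1B-1",
             "SbDREB1B-SsDREB1G", "SbDREB1E-SsDREB1A-4",
             "SbDREB1E-SsDREB1A-2"),
    ks = c(0.079, 0.079, 0.096, 0.133, 0.140, 0.170, 0.180, 0.183, 0.191,
           0.213, 0.230),
    t_mya_published = c(6.487, 6.496, 7.841, 10.917, 11.496, 13.902,
                        14.747, 15.038, 15.686, 17.444, 18.874),
    stringsAsFactors = FALSE)
}
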