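#' Detect tandem-duplication clusters by chromosomal windowing
#'
#' Two same-chromosome family members are joined when they are homologous
#' and their gap (end of the upstream gene to start of the downstream gene)
#' is at most \code{window} bp; clusters are the connected components of
#' that graph, singletons are dropped, members are ordered by start and
#' cluster ids are assigned in (chromosome, start) order. A chromosomal
#' region within 200 kb containing two or more family genes is the classical
#' definition, hence the default window.
#'
#' Homology comes from \code{edges} (gene pairs with \code{identity >=
#' min_identity}); with \code{edges = NULL} every same-chromosome pair is
#' treated as homologous (pure-distance clustering).
#'
#' @param genes gene-model data.frame ([read_gff3()] layout).
#' @param edges optional data.frame \code{(gene_a, gene_b, identity)};
#'   symmetric.
#' @param window maximum gap in bp (default 200000).
#' @param min_identity identity threshold on edges (default 0.4).
#' @return data.frame with columns \code{cluster_id}, \code{chromosome},
#'   \code{gene_id}, \code{start}, \code{end}; zero rows when no cluster.
#' @export
tandem_clusters <- function(genes, edges = NULL, window = 200000,
                            min_identity = 0.4) {
  if (any(is.na(genes$chromosome) | !nzchar(genes$chromosome)))
    stop("gene with unknown chromosome: ",
         genes$gene_id[which(is.na(genes$chromosome) |
                               !nzchar(genes$chromosome))[1]])
  n <- nrow(genes)
  hom <- .homology_lookup(edges, min_identity)
  pairs <- list()
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (genes$chromosome[i] != genes$chromosome[j]) next
    if (!hom(genes$gene_id[i], genes$gene_id[j])) next
    gap <- max(genes$start[i], genes$start[j]) -
      min(genes$end[i], genes$end[j])
    if (gap <= window) pairs[[length(pairs) + 1L]] <- c(i, j)
  }
  comp <- .components(n, pairs)
  keep <- comp %in% which(tabulate(comp) >= 2L)
  out <- data.frame(comp = comp[keep], chromosome = genes$chromosome[keep],
                    gene_id = genes$gene_id[keep], start = genes$start[keep],
                    end = genes$end[keep], stringsAsFactors = FALSE)
  if (!nrow(out))
    return(data.frame(cluster_id = integer(), chromosome = character(),
                      gene_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  first <- do.call(rbind, lapply(split(out, out$comp), function(g)
    data.frame(comp = g$comp[1], chromosome = g$chromosome[1],
               start = min(g$start))))
  first <- first[order(first$chromosome, first$start), ]
  first$cluster_id <- seq_len(nrow(first))
  out$cluster_id <- first$cluster_id[match(out$comp, first$comp)]
  out <- out[order(out$cluster_id, out$start), ]
  rownames(out) <- NULL
  out[, c("cluster_id", "chromosome", "gene_id", "start", "end")]
}

.homology_lookup <- function(edges, min_identity) {
  if (is.null(edges)) return(function(a, b) TRUE)
  keep <- edges$identity >= min_identity
  keys <- c(paste(edges$gene_a[keep], edges$gene_b[keep]),
            paste(edges$gene_b[keep], edges$gene_a[keep]))
  function(a, b) paste(a, b) %in% keys
}

#' Classify the duplication mode of each family gene
#'
#' Members of a tandem cluster are \code{tandem}; genes with at least one
#' homology edge to a different chromosome or beyond the window on the same
#' chromosome are \code{segmental/WGD-candidate}; the rest are \code{none}.
#'
#' @param genes gene-model data.frame.
#' @param clusters output of [tandem_clusters()] on the same genes.
#' @param edges homology edges \code{(gene_a, gene_b, identity)}; required
#'   for segmental calls (no call is made without edges).
#' @param window same window as used for clustering.
#' @param min_identity identity threshold on edges.
#' @return named character vector gene_id -> mode.
#' @export
classify_duplication <- function(genes, clusters, edges = NULL,
                                 window = 200000, min_identity = 0.4) {
  mode <- stats::setNames(rep("none", nrow(genes)), genes$gene_id)
  mode[genes$gene_id %in% clusters$gene_id] <- "tandem"
  if (!is.null(edges) && nrow(edges)) {
    edges <- edges[edges$identity >= min_identity, , drop = FALSE]
    g <- genes
    rownames(g) <- g$gene_id
    for (k in seq_len(nrow(edges))) {
      a <- edges$gene_a[k]; b <- edges$gene_b[k]
      if (!a %in% g$gene_id || !b %in% g$gene_id) next
      far <- g[a, "chromosome"] != g[b, "chromosome"] ||
        (max(g[a, "start"], g[b, "start"]) -
           min(g[a, "end"], g[b, "end"])) > window
      if (far) {
        if (mode[a] == "none") mode[a] <- "segmental/WGD-candidate"
        if (mode[b] == "none") mode[b] <- "segmental/WGD-candidate"
      }
    }
  }
  mode
}

#' Per-chromosome family gene counts
#'
#' @param genes gene-model data.frame.
#' @return data.frame with per-chromosome counts and haplotype-collapsed
#'   counts (e.g. Chr2A-Chr2D pooled as chromosome number 2).
#' @export
chromosome_summary <- function(genes) {
  if (!nrow(genes))
    return(data.frame(chromosome = character(), n_genes = integer(),
                      chromosome_number = integer(), n_haplotype_pooled =
                        integer(), stringsAsFactors = FALSE))
  tab <- as.data.frame(table(chromosome = genes$chromosome),
                       stringsAsFactors = FALSE)
  names(tab)[2] <- "n_genes"
  num <- vapply(tab$chromosome, function(c) .parse_chromosome(c)$number, 1L)
  pooled <- tapply(tab$n_genes, num, sum)
  tab$chromosome_number <- num
  tab$n_haplotype_pooled <- as.integer(pooled[as.character(num)])
  tab[order(tab$chromosome), ]
}
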