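#' Run the full gene-family analysis pipeline
#'
#' Orchestrates the stages in dependency order: \code{simulate} (write a
#' synthetic genome + expression fixture), \code{classify} (superfamily /
#' DREB subgroup + physicochemical table), \code{duplication} (tandem
#' clusters, duplication modes, chromosome summary), \code{kaks} (NG86 +
#' divergence times over CDS pairs), \code{tree} (bootstrapped NJ from
#' Poisson distances) and \code{expression} (pattern calls). Each enabled
#' stage writes its outputs under \code{config$out_dir} and contributes to
#' the returned report; inputs for every enabled stage are checked before
#' any stage runs. Given identical inputs, config and seed, reruns are
#' byte-identical.
#'
#' @param config a named list (or path to a YAML/JSON file) with fields:
#'   \code{out_dir}; \code{seed}; \code{stages} (character subset of
#'   \code{c("simulate","classify","duplication","kaks","tree",
#'   "expression")}); per-stage inputs \code{proteins}, \code{domains},
#'   \code{gff}, \code{edges}, \code{cds}, \code{pairs} (2-column table of
#'   CDS ids), \code{alignment}, \code{fpkm}; parameters \code{window},
#'   \code{rate}, \code{bootstrap_reps}, \code{min_fold},
#'   \code{low_threshold}, and \code{fixture_spec}/\code{expression_spec}
#'   for the simulate stage. When \code{simulate} is enabled its outputs
#'   feed the downstream stages.
#' @return a named list report (also written to \code{out_dir/report.json}).
#' @export
run_pipeline <- function(config) {
  if (is.character(config))
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
      else jsonlite::read_json(config, simplifyVector = TRUE)
  stages <- config$stages %||% character()
  report <- list(stages = stages)
  if (!length(stages)) return(report)
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  if (is.null(seed) && any(stages %in% c("simulate", "tree")))
    stop("config$seed is required for stochastic stages")

  # fail fast on missing inputs for enabled stages
  need <- function(field, stage)
    if (stage %in% stages && !"simulate" %in% stages &&
        is.null(config[[field]]))
      stop("missing input '", field, "' for enabled stage '", stage, "'")
  need("proteins", "classify"); need("domains", "classify")
  need("gff", "duplication")
  need("cds", "kaks"); need("pairs", "kaks")
  need("alignment", "tree")
  need("fpkm", "expression")
  for (f in c("proteins", "domains", "gff", "edges", "cds", "alignment",
              "fpkm", "pairs"))
    if (is.character(config[[f]]) && length(config[[f]]) == 1L &&
        !file.exists(config[[f]]))
      stop("input file for '", f, "' not found: ", config[[f]])

  log_msg <- function(...) message("[drebfam] ", ...)
  proteins <- NULL; hits <- NULL; genes <- NULL; edges <- NULL
  cds <- NULL; fx_expr <- NULL

  if ("simulate" %in% stages) {
    log_msg("simulate: seed = ", seed)
    fspec <- config$fixture_spec %||% list()
    fspec$seed <- fspec$seed %||% seed
    fx <- make_genome_fixture(fspec)
    espec <- config$expression_spec %||% list()
    fx_expr <- make_expression_fixture(
      n_genes = espec$n_genes %||% 16L, seed = espec$seed %||% seed,
      sigma = espec$sigma %||% 0.2)
    write_fasta(fx$proteins, file.path(out_dir, "proteins.faa"))
    write_fasta(fx$cds, file.path(out_dir, "cds.fna"))
    write_gff3(fx$genes, file.path(out_dir, "genes.gff3"))
    write_domtblout(fx$hits, file.path(out_dir, "domains.domtblout"))
    utils::write.table(fx$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    proteins <- fx$proteins; hits <- fx$hits; genes <- fx$genes
    edges <- fx$edges
    cds <- fx$cds
    fx_truth <- fx$truth
    report$simulate <- list(n_genes = nrow(fx$genes),
                            n_clusters = max(fx$truth$cluster))
  }

  if ("classify" %in% stages) {
    if (is.null(proteins)) {
      proteins <- read_fasta(config$proteins, "protein")
      hits <- read_domtblout(config$domains)
    }
    log_msg("classify: ", length(proteins), " proteins")
    cls <- classify_proteins(proteins, hits)
    phys <- do.call(rbind, lapply(cls$protein_id, function(id) {
      p <- suppressWarnings(physchem(proteins[[id]]))
      data.frame(protein_id = id, length_aa = p$length_aa, mw = p$mw,
                 pi = p$pi, gravy = p$gravy,
                 aliphatic_index = p$aliphatic_index,
                 instability_index = p$instability_index)
    }))
    cls <- merge(cls, phys, by = "protein_id", sort = TRUE)
    utils::write.table(cls, file.path(out_dir, "classified.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$classify <- list(
      n = nrow(cls),
      superfamily_counts = as.list(table(cls$superfamily)),
      subgroup_counts = as.list(table(cls$subgroup[
        cls$superfamily == "DREB-candidate"])))
  }

  if ("duplication" %in% stages) {
    if (is.null(genes)) genes <- read_gff3(config$gff)
    if (is.null(edges) && !is.null(config$edges))
      edges <- utils::read.delim(config$edges, stringsAsFactors = FALSE)
    window <- config$window %||% 200000
    log_msg("duplication: ", nrow(genes), " genes, window = ", window)
    clus <- tandem_clusters(genes, edges, window = window)
    modes <- classify_duplication(genes, clus, edges, window = window)
    utils::write.table(clus, file.path(out_dir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$duplication <- list(
      n_clusters = if (nrow(clus)) max(clus$cluster_id) else 0L,
      cluster_table = clus,
      modes = as.list(table(modes)),
      chromosome_summary = chromosome_summary(genes))
  }

  if ("kaks" %in% stages) {
    if (is.null(cds)) cds <- read_fasta(config$cds, "dna")
    pairs <- if (!is.null(config$pairs)) {
      if (is.character(config$pairs))
        utils::read.delim(config$pairs, stringsAsFactors = FALSE)
      else config$pairs
    } else if (exists("fx_truth", inherits = FALSE)) {
      # default on simulated data: within-cluster gene pairs
      do.call(rbind, lapply(split(fx_truth[fx_truth$cluster > 0L, ],
                                  fx_truth$cluster[fx_truth$cluster > 0L]),
                            function(g) if (nrow(g) >= 2L)
                              data.frame(seq_a = g$cds_id[1],
                                         seq_b = g$cds_id[2])))
    } else NULL
    if (is.null(pairs)) stop("kaks stage needs a pairs table")
    rate <- config$rate %||% 6.1e-9
    log_msg("kaks: ", nrow(pairs), " pairs, rate = ", rate)
    rows <- lapply(seq_len(nrow(pairs)), function(i) {
      a <- pairs[i, 1]; b <- pairs[i, 2]
      r <- fisher_selection_test(ng86(cds[[a]], cds[[b]]))
      t <- if (!is.na(r$ks)) divergence_time(r$ks, rate)$t_mya else NA_real_
      data.frame(seq_a = a, seq_b = b, N = r$N, S = r$S, Nd = r$Nd,
                 Sd = r$Sd, ka = r$ka, ks = r$ks, ratio = r$ratio,
                 p_value = r$p_value, t_mya = t, stringsAsFactors = FALSE)
    })
    kk <- do.call(rbind, rows)
    utils::write.table(kk, file.path(out_dir, "kaks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$kaks <- kk
  }

  if ("tree" %in% stages) {
    aln <- if (!is.null(config$alignment))
      read_fasta(config$alignment, "protein", aligned = TRUE)
    else stop("tree stage needs an alignment")
    reps <- config$bootstrap_reps %||% 1000L
    log_msg("tree: ", length(aln), " sequences, ", reps, " replicates")
    tr <- bootstrap_support(aln, n_reps = reps, seed = seed)
    write_newick(tr, file.path(out_dir, "tree.nwk"))
    report$tree <- list(newick = write_newick(tr),
                        skipped = attr(tr, "bootstrap_skipped") %||% 0L)
  }

  if ("expression" %in% stages) {
    if (!is.null(fx_expr)) {
      rec <- classify_expression_fixture(fx_expr,
                                         config$low_threshold %||% 1,
                                         config$min_fold %||% 2)
      utils::write.table(rec, file.path(out_dir, "expression_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$expression <- list(n = nrow(rec),
                                recovered = mean(rec$recovered))
    } else {
      fpkm <- as.matrix(utils::read.delim(config$fpkm, row.names = 1,
                                          check.names = FALSE))
      low <- detect_low_expression(fpkm, config$low_threshold %||% 1)
      report$expression <- list(n = nrow(fpkm), low_expressed = low)
    }
    log_msg("expression: done")
  }

  write_report(report, file.path(out_dir, "report.json"))
  report
}
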