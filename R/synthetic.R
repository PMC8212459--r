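# Synthetic fixtures with known ground truth for every pipeline stage.
# The generators are pure functions of (spec, seed).

.MOTIF_INSTANCE <- c(
  "DREB1-NLS" = "PKRPAGRTKFRETRHP",
  "DREB2-NLS" = "RKSPAKGSKKGCMAGKGGPENST",
  "CMIV-1"    = "KGKGGPAN",
  "DSAW"      = "DSAW",
  "LWSY"      = "LWSY")

.rand_aa <- function(n) paste(sample(.AA20, n, replace = TRUE), collapse = "")

#' Generate a protein with a planted domain architecture and motifs
#'
#' Domain copies are realised as the fixed consensus cores (so
#' [find_consensus_domains()] recovers them) and each requested motif is
#' planted once at a non-overlapping position consistent with the
#' classifier's window rules: CMIV-1 and the NLS motifs upstream of the
#' domain (the DREB1 NLS immediately upstream), DSAW immediately downstream,
#' LWSY in the C-terminal tail. Deterministic per seed.
#'
#' @param architecture one of \code{"double-AP2"}, \code{"AP2+B3"},
#'   \code{"single-AP2-with-WLG"}, \code{"single-AP2-no-WLG"}.
#' @param motifs subset of
#'   \code{c("DREB1-NLS","DREB2-NLS","DSAW","LWSY","CMIV-1")}.
#' @param seed RNG seed.
#' @param v14,e19 residues planted at AP2-domain positions 14 and 19.
#' @param id sequence id.
#' @return list with \code{id}, \code{sequence}, and truth tables
#'   \code{domains} and \code{motifs} (1-based coordinates).
#' @export
make_protein <- function(architecture = c("single-AP2-with-WLG", "double-AP2",
                                          "AP2+B3", "single-AP2-no-WLG"),
                         motifs = character(), seed = 1L, v14 = "V",
                         e19 = "E", id = "protein_1") {
  architecture <- match.arg(architecture)
  bad <- setdiff(motifs, names(.MOTIF_INSTANCE))
  if (length(bad)) stop("unknown motif(s): ", paste(bad, collapse = ", "))
  if (architecture == "single-AP2-no-WLG" && "DSAW" %in% motifs)
    stop("contradictory request: DSAW adjacency requires a WLG-bearing domain")
  .with_seed(seed, {
    wlg <- architecture != "single-AP2-no-WLG"
    dom <- .make_ap2_domain(v14 = v14, e19 = e19, wlg = wlg)
    segs <- character()
    doms <- list()
    mots <- list()
    pos <- 0L
    add <- function(s, label = NULL, kind = NULL) {
      segs[[length(segs) + 1L]] <<- s
      if (!is.null(label)) {
        rec <- data.frame(name = label, start = pos + 1L,
                          end = pos + nchar(s), stringsAsFactors = FALSE)
        if (kind == "domain") doms[[length(doms) + 1L]] <<- rec
        else mots[[length(mots) + 1L]] <<- rec
      }
      pos <<- pos + nchar(s)
    }
    add(.rand_aa(sample(20:35, 1)))
    if ("CMIV-1" %in% motifs) {
      add(.MOTIF_INSTANCE[["CMIV-1"]], "CMIV-1", "motif")
      add(.rand_aa(3))
    }
    if ("DREB2-NLS" %in% motifs) {
      add(.MOTIF_INSTANCE[["DREB2-NLS"]], "DREB2-NLS", "motif")
      add(.rand_aa(3))
    }
    if ("DREB1-NLS" %in% motifs) {
      add(.MOTIF_INSTANCE[["DREB1-NLS"]], "DREB1-NLS", "motif")
      add(.rand_aa(3))
    }
    add(dom, "AP2", "domain")
    if (architecture == "double-AP2") {
      add(.rand_aa(sample(20:30, 1)))
      add(dom, "AP2", "domain")
    }
    if (architecture == "AP2+B3") {
      add(.rand_aa(sample(15:25, 1)))
      add(.B3_CORE, "B3", "domain")
    }
    if ("DSAW" %in% motifs) {
      add(.rand_aa(2))
      add(.MOTIF_INSTANCE[["DSAW"]], "DSAW", "motif")
    }
    add(.rand_aa(sample(25:40, 1)))
    if ("LWSY" %in% motifs) {
      add(.MOTIF_INSTANCE[["LWSY"]], "LWSY", "motif")
      add(.rand_aa(3))
    }
    list(id = id,
         sequence = paste(segs, collapse = ""),
         domains = if (length(doms)) do.call(rbind, doms) else
           data.frame(name = character(), start = integer(), end = integer()),
         motifs = if (length(mots)) do.call(rbind, mots) else
           data.frame(name = character(), start = integer(), end = integer()))
  })
}

# random reverse translation: uniform synonymous codon per residue
.reverse_translate <- function(protein) {
  gc <- .genetic_code()
  by_aa <- split(names(gc), unname(gc))
  paste(vapply(.chars(protein), function(aa) {
    opts <- by_aa[[aa]]
    if (is.null(opts)) stop("cannot reverse-translate residue '", aa, "'")
    opts[sample.int(length(opts), 1L)]
  }, ""), collapse = "")
}

.FAMILY_RECIPES <- list(
  AP2      = list(architecture = "double-AP2", motifs = character(), v14 = "V"),
  RAV      = list(architecture = "AP2+B3", motifs = character(), v14 = "V"),
  atypical = list(architecture = "single-AP2-no-WLG", motifs = character(),
                  v14 = "V"),
  DREB1    = list(architecture = "single-AP2-with-WLG",
                  motifs = c("DREB1-NLS", "DSAW", "LWSY"), v14 = "V"),
  DREB2    = list(architecture = "single-AP2-with-WLG",
                  motifs = c("CMIV-1", "DREB2-NLS"), v14 = "V"),
  ERF      = list(architecture = "single-AP2-with-WLG", motifs = character(),
                  v14 = "A"))

#' Generate a multi-chromosome genome fixture with planted ground truth
#'
#' Emulates a family-classification + duplication-mapping input set:
#' proteins of each requested (sub)family, their coding sequences, a GFF3
#' gene table with planted tandem clusters, a domain-hit table, homology
#' edges and a truth table. Tandem-cluster members are placed with
#' adjacent-member gaps below \code{max_gap} and carry identical proteins;
#' all other genes are placed more than 200 kb from any family member.
#'
#' @param spec list with fields \code{seed} (integer),
#'   \code{n_chromosomes} (default 4), \code{genes_per_family} (named counts
#'   over \code{AP2}, \code{RAV}, \code{atypical}, \code{DREB1},
#'   \code{DREB2}, \code{ERF}), \code{tandem_clusters} (list of
#'   \code{list(chromosome =, n_members =, max_gap =)}),
#'   \code{chromosome_length} (bp, default 3e7).
#' @return list with \code{proteins}, \code{cds} (named vectors),
#'   \code{genes} (gene-model data.frame), \code{hits}, \code{edges}
#'   (gene_a, gene_b, identity), \code{truth}.
#' @export
make_genome_fixture <- function(spec) {
  seed <- spec$seed %||% 1L
  n_chr <- spec$n_chromosomes %||% 4L
  counts <- spec$genes_per_family %||% c(DREB1 = 4L, DREB2 = 2L, ERF = 4L)
  clusters <- spec$tandem_clusters %||% list()
  chr_len <- spec$chromosome_length %||% 3e7
  if (any(counts < 0)) stop("family counts must be >= 0")
  .with_seed(seed, {
    chroms <- paste0("Chr", rep(seq_len(ceiling(n_chr / 4)), each = 4),
                     c("A", "B", "C", "D"))[seq_len(n_chr)]
    proteins <- character(); cds <- character()
    genes <- list(); hits <- list(); truth <- list(); edges <- list()
    next_pos <- stats::setNames(rep(250000, n_chr), chroms)
    gid <- 0L
    add_gene <- function(chrom, start, prot, fam, cluster,
                         cds_seq = NULL) {
      gid <<- gid + 1L
      gene_id <- sprintf("g%03d", gid)
      pid <- paste0(gene_id, "_P"); cid <- paste0(gene_id, "_C")
      end <- start + 3L * nchar(prot$sequence) - 1L
      if (end > chr_len)
        stop("chromosome ", chrom, " too short to satisfy spacing")
      proteins[pid] <<- prot$sequence
      cds[cid] <<- cds_seq %||% .reverse_translate(prot$sequence)
      genes[[length(genes) + 1L]] <<- data.frame(
        gene_id = gene_id, chromosome = chrom, start = start, end = end,
        strand = sample(c("+", "-"), 1), protein_id = pid, cds_id = cid,
        stringsAsFactors = FALSE)
      h <- prot$domains
      if (nrow(h))
        hits[[length(hits) + 1L]] <<- data.frame(
          protein_id = pid, domain_name = h$name, start = h$start,
          end = h$end, score = 100, evalue = 1e-30, stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <<- data.frame(
        gene_id = gene_id, protein_id = pid, cds_id = cid, family = fam,
        cluster = cluster, chromosome = chrom, start = start, end = end,
        stringsAsFactors = FALSE)
      gene_id
    }
    # scattered (non-cluster) genes, > 200 kb apart
    k <- 0L
    for (fam in names(counts)) {
      recipe <- .FAMILY_RECIPES[[fam]]
      if (is.null(recipe)) stop("unknown family '", fam, "'")
      for (i in seq_len(counts[[fam]])) {
        k <- k + 1L
        chrom <- chroms[(k - 1L) %% n_chr + 1L]
        prot <- make_protein(recipe$architecture, recipe$motifs,
                             seed = sample.int(1e8, 1), v14 = recipe$v14,
                             id = paste0(fam, "_", i))
        add_gene(chrom, next_pos[[chrom]], prot, fam, 0L)
        next_pos[chrom] <- next_pos[[chrom]] + 250000 + sample.int(150000, 1)
      }
    }
    # planted tandem clusters: cloned DREB1-type proteins, gaps < max_gap
    for (ci in seq_along(clusters)) {
      cspec <- clusters[[ci]]
      if (cspec$n_members < 2L) stop("tandem cluster needs >= 2 members")
      if (cspec$max_gap <= 0) stop("max_gap must be positive")
      chrom <- cspec$chromosome
      if (!chrom %in% chroms) stop("unknown chromosome '", chrom, "'")
      prot <- make_protein("single-AP2-with-WLG",
                           c("DREB1-NLS", "DSAW", "LWSY"),
                           seed = sample.int(1e8, 1),
                           id = paste0("cluster", ci))
      start <- next_pos[[chrom]] + 250000
      cluster_cds <- .reverse_translate(prot$sequence)
      ids <- character(cspec$n_members)
      for (mi in seq_len(cspec$n_members)) {
        ids[mi] <- add_gene(chrom, start, prot, "DREB1", ci, cluster_cds)
        gap <- 1000 + sample.int(max(1, cspec$max_gap - 1500), 1)
        start <- start + 3L * nchar(prot$sequence) + gap
      }
      next_pos[chrom] <- start + 250000
      for (a in seq_len(length(ids) - 1L)) for (b in (a + 1L):length(ids))
        edges[[length(edges) + 1L]] <- data.frame(
          gene_a = ids[a], gene_b = ids[b], identity = 1.0,
          stringsAsFactors = FALSE)
    }
    empty_edges <- data.frame(gene_a = character(), gene_b = character(),
                              identity = numeric(), stringsAsFactors = FALSE)
    list(proteins = proteins, cds = cds,
         genes = do.call(rbind, genes),
         hits = do.call(rbind, hits),
         edges = if (length(edges)) do.call(rbind, edges) else empty_edges,
         truth = do.call(rbind, truth))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a codon-sequence pair with controlled Ka and Ks
#'
#' Starting from a random stop-free CDS, Poisson-distributed numbers of
#' synonymous and nonsynonymous single-nucleotide codon changes (expected
#' counts \code{target_ks * S} and \code{target_ka * N}, with \code{S},
#' \code{N} the NG86 site counts of the ancestor) are applied to the second
#' copy, drawing uniformly among the eligible single-nucleotide transitions
#' of the current sequence. Stop codons are never created. Synonymous moves
#' are additionally constrained to keep the mutated codon's pathway-averaged
#' nonsynonymous difference from the ancestral codon at zero, so a pure-Ks
#' pair always yields \code{Nd = 0}.
#'
#' @param n_codons number of codons.
#' @param target_ks,target_ka target NG86 rates (each < 0.7; saturation
#'   guard).
#' @param seed RNG seed.
#' @return list \code{(cds_a, cds_b)} of equal-length CDS strings.
#' @export
mutate_cds_pair <- function(n_codons, target_ks, target_ka, seed = 1L) {
  if (target_ks < 0 || target_ka < 0) stop("targets must be >= 0")
  if (target_ks >= 0.7 || target_ka >= 0.7)
    stop("targets must stay below 0.7 to avoid saturation")
  .with_seed(seed, {
    anc <- sample(.sense_codons(), n_codons, replace = TRUE)
    sites <- vapply(anc, .codon_sites_m, c(syn = 0, nonsyn = 0))
    S <- sum(sites["syn", ]); N <- sum(sites["nonsyn", ])
    n_syn <- stats::rpois(1, target_ks * S)
    n_non <- stats::rpois(1, target_ka * N)
    cur <- anc
    # eligible transitions per codon instance; drawn uniformly over all
    # eligible single-nucleotide transitions of the current sequence
    options_for <- function(ci, synonymous) {
      nb <- .codon_neighbors(cur[ci])
      if (!synonymous) return(nb$non)
      nb$syn[vapply(nb$syn, function(alt)
        .codon_path_counts_m(anc[ci], alt)[["nd"]] == 0, TRUE)]
    }
    apply_events <- function(n_events, synonymous) {
      if (n_events == 0L) return(invisible())
      opts <- lapply(seq_along(cur), options_for, synonymous = synonymous)
      for (e in seq_len(n_events)) {
        counts <- lengths(opts)
        if (sum(counts) == 0L)
          stop("unsatisfiable target: no eligible ",
               if (synonymous) "synonymous" else "nonsynonymous",
               " transitions remain on this sequence")
        ci <- sample.int(length(cur), 1L, prob = counts)
        cur[ci] <<- opts[[ci]][sample.int(counts[ci], 1L)]
        opts[[ci]] <- options_for(ci, synonymous)
      }
    }
    apply_events(n_syn, TRUE)
    apply_events(n_non, FALSE)
    list(cds_a = paste(anc, collapse = ""),
         cds_b = paste(cur, collapse = ""))
  })
}

# --- expression fixtures -----------------------------------------------------

.EXPRESSION_DESIGN <- local({
  d <- rbind(
    data.frame(sample = paste0("leaf_", 1:3), analysis = "tissue",
               group = "leaf", position = NA_integer_, series = NA,
               pair = NA),
    data.frame(sample = paste0("stalk_", 1:3), analysis = "tissue",
               group = "stalk", position = NA_integer_, series = NA,
               pair = NA),
    data.frame(sample = paste0("zone_", 1:4), analysis = "gradient",
               group = "gradient", position = 1:4, series = NA, pair = NA),
    data.frame(sample = c(paste0("c1_L", 1:3), paste0("c1_D", 1:3),
                          paste0("c2_L", 1:3), paste0("c2_D", 1:3)),
               analysis = "diurnal",
               group = rep(c("light", "dark", "light", "dark"), each = 3),
               position = NA_integer_,
               series = rep(c("cycle1", "cycle2"), each = 6), pair = NA),
    data.frame(sample = c("cold_treated", "cold_control",
                          "drought_treated", "drought_control"),
               analysis = "stress",
               group = c("cold", "cold", "drought", "drought"),
               position = NA_integer_, series = NA,
               pair = c("treated", "control", "treated", "control")))
  d$analysis <- as.character(d$analysis)
  d
})

.EXPRESSION_PATTERNS <- c("undetectable", "constitutive", "leaf-preferential",
                          "increasing", "decreasing", "light-elevated",
                          "drought-induced", "cold-induced")

.pattern_baseline <- function(pattern, design, cold_fold = 200,
                              drought_fold = 20) {
  v <- rep(10, nrow(design))
  names(v) <- design$sample
  zones <- design$sample[design$analysis == "gradient"]
  switch(pattern,
    "undetectable" = v[] <- 0.2,
    "constitutive" = v[] <- 10,
    "leaf-preferential" = {
      v[design$group == "leaf"] <- 40
      v[design$group == "stalk"] <- 4
    },
    "increasing" = v[zones] <- c(2, 6, 18, 54),
    "decreasing" = v[zones] <- c(54, 18, 6, 2),
    "light-elevated" = {
      v[design$group == "light"] <- 30
      v[design$group == "dark"] <- 5
    },
    "drought-induced" = {
      v["drought_treated"] <- drought_fold
      v["drought_control"] <- 1
    },
    "cold-induced" = {
      v["cold_treated"] <- cold_fold
      v["cold_control"] <- 1
    },
    stop("unknown pattern '", pattern, "'"))
  v
}

#' Generate an FPKM matrix with planted expression patterns
#'
#' The sample design covers four analysis blocks: a leaf/stalk tissue panel
#' (3 + 3 samples), a four-zone leaf developmental gradient, two diurnal
#' light/dark cycles (3 + 3 samples each) and paired stress contrasts (cold
#' and drought, treated vs control). Each gene receives one pattern template
#' (recycled over \code{patterns}); multiplicative log-normal noise of
#' parameter \code{sigma} is applied to every entry.
#'
#' @param patterns character vector from
#'   \code{c("undetectable","constitutive","leaf-preferential","increasing",
#'   "decreasing","light-elevated","drought-induced","cold-induced")}.
#' @param n_genes number of genes (patterns recycled).
#' @param seed RNG seed.
#' @param sigma log-normal noise sd (>= 0), default 0.2.
#' @param cold_fold,drought_fold planted induction folds.
#' @return list with \code{fpkm} (genes x samples matrix), \code{design}
#'   (sample metadata), \code{truth} (gene, pattern).
#' @export
make_expression_fixture <- function(patterns = .EXPRESSION_PATTERNS,
                                    n_genes = length(patterns), seed = 1L,
                                    sigma = 0.2, cold_fold = 200,
                                    drought_fold = 20) {
  if (sigma < 0) stop("sigma must be >= 0")
  bad <- setdiff(patterns, .EXPRESSION_PATTERNS)
  if (length(bad)) stop("unknown pattern(s): ", paste(bad, collapse = ", "))
  design <- .EXPRESSION_DESIGN
  .with_seed(seed, {
    planted <- rep_len(patterns, n_genes)
    genes <- sprintf("gene_%03d", seq_len(n_genes))
    base <- t(vapply(planted, .pattern_baseline,
                     numeric(nrow(design)), design = design,
                     cold_fold = cold_fold, drought_fold = drought_fold))
    noise <- matrix(stats::rlnorm(length(base), 0, sigma), nrow(base))
    fpkm <- base * noise
    dimnames(fpkm) <- list(genes, design$sample)
    list(fpkm = fpkm, design = design,
         truth = data.frame(gene = genes, pattern = planted,
                            stringsAsFactors = FALSE))
  })
}
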