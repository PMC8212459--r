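test_that("make_protein plants the requested domains and motifs verbatim", {
  pr <- make_protein("single-AP2-with-WLG", c("DREB1-NLS", "DSAW", "LWSY"),
                     seed = 1)
  expect_identical(pr$sequence,
                   make_protein("single-AP2-with-WLG",
                                c("DREB1-NLS", "DSAW", "LWSY"),
                                seed = 1)$sequence)
  dom <- pr$domains[pr$domains$name == "AP2", ]
  expect_equal(nrow(dom), 1L)
  expect_identical(substr(pr$sequence, dom$start + 25, dom$start + 27), "WLG")
  expect_identical(substr(pr$sequence, dom$start + 13, dom$start + 13), "V")
  for (m in seq_len(nrow(pr$motifs))) {
    planted <- substr(pr$sequence, pr$motifs$start[m], pr$motifs$end[m])
    expect_equal(nrow(scan_motif(planted, pr$motifs$name[m])), 1L)
  }
  # different seeds give different backgrounds
  expect_false(pr$sequence ==
                 make_protein("single-AP2-with-WLG",
                              c("DREB1-NLS", "DSAW", "LWSY"),
                              seed = 2)$sequence)
})

test_that("planted architectures classify as designed (by construction)", {
  p_a1 <- make_protein("single-AP2-with-WLG", c("DREB1-NLS", "DSAW", "LWSY"),
                       seed = 1, id = "a1")
  p_rav <- make_protein("AP2+B3", seed = 2, id = "rav")
  p_ap2 <- make_protein("double-AP2", seed = 3, id = "ap2")
  p_aty <- make_protein("single-AP2-no-WLG", seed = 4, id = "aty")
  p_a2 <- make_protein("single-AP2-with-WLG", c("CMIV-1", "DREB2-NLS"),
                       seed = 5, id = "a2")
  p_erf <- make_protein("single-AP2-with-WLG", seed = 6, v14 = "A", id = "erf")
  prots <- setNames(vapply(list(p_a1, p_rav, p_ap2, p_aty, p_a2, p_erf),
                           `[[`, "", "sequence"),
                    c("a1", "rav", "ap2", "aty", "a2", "erf"))
  cls <- classify_proteins(prots, find_consensus_domains(prots))
  got <- setNames(cls$superfamily, cls$protein_id)
  expect_identical(got[["ap2"]], "AP2")
  expect_identical(got[["rav"]], "RAV")
  expect_identical(got[["aty"]], "atypical")
  expect_identical(got[["erf"]], "ERF")
  sub <- setNames(cls$subgroup, cls$protein_id)
  expect_identical(sub[["a1"]], "A-1")
  expect_identical(sub[["a2"]], "A-2")
  expect_error(make_protein("single-AP2-no-WLG", "DSAW", seed = 1),
               "contradictory")
})

test_that("mutate_cds_pair honours zero targets and pure-synonymous moves", {
  mp0 <- mutate_cds_pair(300, 0, 0, seed = 5)
  expect_identical(mp0$cds_a, mp0$cds_b)
  for (s in 1:5) {
    mp <- mutate_cds_pair(300, 0.2, 0, seed = s)
    r <- ng86(mp$cds_a, mp$cds_b)
    expect_identical(r$Nd, 0)
    expect_gt(r$Sd, 0)
  }
  expect_identical(mutate_cds_pair(120, 0.1, 0.05, seed = 9),
                   mutate_cds_pair(120, 0.1, 0.05, seed = 9))
  expect_error(mutate_cds_pair(100, 0.8, 0.1, seed = 1), "saturation")
})

test_that("genome fixture plants recoverable tandem clusters and truth", {
  spec <- list(seed = 42, n_chromosomes = 4,
               genes_per_family = c(DREB1 = 3, ERF = 3),
               tandem_clusters = list(
                 list(chromosome = "Chr1A", n_members = 3, max_gap = 50000)))
  fx <- make_genome_fixture(spec)
  expect_identical(fx$genes$gene_id, fx$truth$gene_id)
  clus <- tandem_clusters(fx$genes, fx$edges)
  expect_equal(sort(clus$gene_id),
               sort(fx$truth$gene_id[fx$truth$cluster == 1]))
  gaps <- diff(clus$start) - (clus$end[-nrow(clus)] - clus$start[-nrow(clus)])
  expect_true(all(clus$start[-1] - clus$end[-nrow(clus)] < 50000))

  fx0 <- make_genome_fixture(list(seed = 1, genes_per_family =
                                    c(DREB1 = 4)))
  expect_equal(nrow(tandem_clusters(fx0$genes, fx0$edges)), 0L)
  # spacing: non-cluster genes sit > 200 kb apart on each chromosome
  by_chr <- split(fx0$genes, fx0$genes$chromosome)
  for (g in by_chr) if (nrow(g) > 1) {
    g <- g[order(g$start), ]
    expect_true(all(g$start[-1] - g$end[-nrow(g)] > 200000))
  }
  expect_error(make_genome_fixture(list(
    seed = 1, genes_per_family = c(DREB1 = 50), n_chromosomes = 1,
    chromosome_length = 1e6)), "too short")
})

test_that("expression fixture realises each pattern exactly at zero noise", {
  fx <- make_expression_fixture(n_genes = 8, seed = 3, sigma = 0)
  m <- fx$fpkm
  const <- fx$truth$gene[fx$truth$pattern == "constitutive"]
  expect_true(all(m[const, ] == 10))
  und <- fx$truth$gene[fx$truth$pattern == "undetectable"]
  expect_true(all(m[und, ] < 1))
  cold <- fx$truth$gene[fx$truth$pattern == "cold-induced"]
  expect_gte(m[cold, "cold_treated"] / m[cold, "cold_control"], 200)
  inc <- fx$truth$gene[fx$truth$pattern == "increasing"]
  zones <- fx$design$sample[fx$design$analysis == "gradient"]
  expect_true(all(diff(m[inc, zones]) > 0))
  expect_error(make_expression_fixture(n_genes = 4, seed = 1, sigma = -1),
               "sigma")
  expect_identical(make_expression_fixture(n_genes = 6, seed = 2)$fpkm,
                   make_expression_fixture(n_genes = 6, seed = 2)$fpkm)
})
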