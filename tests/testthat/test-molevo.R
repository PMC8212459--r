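test_that("codon_align threads protein gaps onto CDS codons", {
  aln <- c(s1 = "MK-V", s2 = "MKLV")
  cds <- c(s1 = "ATGAAAGTT", s2 = "ATGAAACTTGTT")
  ca <- codon_align(aln, cds)
  expect_identical(unname(ca["s1"]), "ATGAAA---GTT")
  expect_identical(unname(ca["s2"]), "ATGAAACTTGTT")
  expect_equal(nchar(ca[["s1"]]), 12L)
  # terminal stop codons are stripped before the length check
  expect_identical(unname(codon_align(c(s = "MK"),
                                      c(s = "ATGAAATAA"))["s"]), "ATGAAA")
  expect_error(codon_align(c(s1 = "M"), c(s1 = "GGG")),
               "translation mismatch.*position 1")
  expect_error(codon_align(c(s1 = "MK"), c(s1 = "ATGAAAG")), "match 3 x")
})

test_that("translate-then-align round-trips random coding fixtures", {
  set.seed(17)
  for (rep in 1:10) {
    cds <- random_sense_cds(sample(10:40, 1))
    prot <- paste(vapply(.oracle_codons(cds), .oracle_translate, ""),
                  collapse = "")
    ca <- codon_align(setNames(prot, "x"), setNames(cds, "x"))
    expect_identical(unname(ca[["x"]]), cds)
  }
})

test_that("ng86 reproduces hand-enumerated counts on homogeneous codons", {
  r0 <- ng86("ATGAAA", "ATGAAA")
  expect_equal(r0$ka, 0)
  expect_equal(r0$ks, 0)
  # 10x GGG vs 9x GGG + 1x AGG: a single nonsynonymous first-position change.
  # Sites: GGG has 1 synonymous site, AGG has 5/3 (CGG at pos 1, AGA at pos
  # 3), so S = (10 + 9 + 5/3)/2 = 59/6 and N = 121/6.
  a <- paste(rep("GGG", 10), collapse = "")
  b <- paste(c("AGG", rep("GGG", 9)), collapse = "")
  r <- ng86(a, b)
  expect_equal(r$S, 59 / 6, tolerance = 1e-12)
  expect_equal(r$N, 121 / 6, tolerance = 1e-12)
  expect_equal(r$Nd, 1)
  expect_equal(r$Sd, 0)
  expect_equal(r$ka, -0.75 * log(1 - 4 * (6 / 121) / 3), tolerance = 1e-12)
  expect_equal(r$ks, 0)
  expect_true(is.na(r$ratio))
  # site counts always partition 3 x analyzable codons
  expect_equal(r$N + r$S, 3 * r$n_codons)
})

test_that("ng86 equals the exhaustive-pathway oracle on random short pairs", {
  set.seed(23)
  for (rep in 1:60) {
    n <- sample(1:6, 1)
    a <- random_sense_cds(n)
    b <- random_sense_cds(n)
    r <- ng86(a, b)
    o <- oracle_ng86(a, b)
    expect_equal(r$N, o$N, tolerance = 1e-9)
    expect_equal(r$S, o$S, tolerance = 1e-9)
    expect_equal(r$Nd, o$Nd, tolerance = 1e-9)
    expect_equal(r$Sd, o$Sd, tolerance = 1e-9)
    expect_equal(r$N + r$S, 3 * r$n_codons, tolerance = 1e-9)
  }
})

test_that("substitution counts stay within site counts at realistic divergence", {
  for (s in 1:10) {
    mp <- mutate_cds_pair(150, 0.15, 0.05, seed = 100 + s)
    r <- ng86(mp$cds_a, mp$cds_b)
    expect_lte(r$Nd, r$N + 1e-9)
    expect_lte(r$Sd, r$S + 1e-9)
    expect_false(r$saturated)
  }
})

test_that("gapped, ambiguous and stop codons are excluded pairwise", {
  r <- ng86("ATG---AAANNNGGG", "ATGAAAAAAAAAGGG")
  expect_equal(r$n_codons, 3L)
  # saturation flagged, not thrown
  rs <- ng86("AAAAAAAAA", "GGGGGGGGG")
  expect_true(rs$saturated)
  expect_true(is.na(rs$ka))
  expect_error(ng86("---", "AAA"), "no analyzable")
})

test_that("Fisher selection test matches hypergeometric enumeration", {
  r <- ng86(paste(rep("GGG", 10), collapse = ""),
            paste(rep("GGG", 10), collapse = ""))
  expect_equal(fisher_selection_test(r)$p_value, 1)
  # direct table check against the hypergeometric tail sum
  tab <- matrix(c(10, 90, 0, 100), 2, byrow = TRUE)
  p_r <- stats::fisher.test(tab)$p.value
  dens <- stats::dhyper(0:100, 100, 100, 10)
  p_brute <- sum(dens[dens <= stats::dhyper(10, 100, 100, 10) * (1 + 1e-7)])
  expect_equal(p_r, p_brute, tolerance = 1e-9)
  # symmetric margins give p = 1
  mp <- mutate_cds_pair(200, 0.05, 0.05, seed = 2)
  rr <- fisher_selection_test(ng86(mp$cds_a, mp$cds_b))
  expect_true(rr$p_value >= 0 && rr$p_value <= 1)
})

test_that("divergence time applies T = Ks / (2r) exactly and scales linearly", {
  expect_equal(divergence_time(0)$t_mya, 0)
  expect_equal(divergence_time(0.122)$t_mya, 10.0, tolerance = 1e-12)
  expect_equal(divergence_time(0.180)$t_mya, 14.747, tolerance = 0.006 * 14.747)
  ks <- c(0.05, 0.1, 0.4)
  expect_equal(divergence_time(2 * ks)$t_mya, 2 * divergence_time(ks)$t_mya)
  expect_equal(divergence_time(ks, rate = 2 * 6.1e-9)$t_mya,
               divergence_time(ks)$t_mya / 2)
  expect_error(divergence_time(-0.1), "non-negative")
  expect_error(divergence_time(0.1, rate = 0), "positive")
})

test_that("Poisson distances use pairwise deletion per sequence pair", {
  a <- c(s1 = "AAAAAAAAAA", s2 = "AAAAAAAAAC")
  expect_equal(poisson_distance(a)["s1", "s2"], -log(0.9), tolerance = 1e-12)
  expect_equal(poisson_distance(c(x = "MKV", y = "MKV"))["x", "y"], 0)
  # 3-sequence toy, hand computation per pair
  aln <- c(p = "AC-GT", q = "ACAGA", r = "XCAGT")
  d <- poisson_distance(aln)
  expect_equal(d["p", "q"], -log(1 - 1 / 4), tolerance = 1e-12)  # 4 shared
  expect_equal(d["p", "r"], 0, tolerance = 1e-12)                # 3 shared
  expect_equal(d["q", "r"], -log(1 - 1 / 4), tolerance = 1e-12)  # 4 shared
  expect_true(isSymmetric(d))
  expect_error(poisson_distance(c(a = "X-", b = "AX")), "no comparable")
  # p = 1 marked undefined
  expect_true(is.na(poisson_distance(c(a = "AAAA", b = "CCCC"))[1, 2]))
})

test_that("NJ recovers additive trees exactly (topology and lengths)", {
  # 4-taxon additive matrix from ((A:1,B:2):1,(C:3,D:1))
  d <- matrix(c(0, 3, 5, 3,
                3, 0, 6, 4,
                5, 6, 0, 4,
                3, 4, 4, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(d)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-12)
  truth <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):0);")
  expect_equal(as.numeric(phangorn::RF.dist(tr, ape::unroot(truth))), 0)
  # n = 3 star via the three-point formula
  d3 <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- nj_tree(d3)
  expect_equal(sort(t3$edge.length), c(1, 1, 2))
  expect_error(nj_tree(d3[1:2, 1:2]), "three taxa")

  set.seed(41)
  for (rep in 1:10) {
    ra <- random_additive(sample(4:8, 1))
    tr <- nj_tree(ra$d)
    expect_equal(as.numeric(phangorn::RF.dist(tr, ra$tree)), 0)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(ra$d), colnames(ra$d)],
                 ra$d, tolerance = 1e-9)
    # cross-check against an independent NJ implementation
    expect_equal(as.numeric(phangorn::RF.dist(tr, ape::nj(ra$d))), 0)
  }
})

test_that("bootstrap supports are deterministic and strong on clean splits", {
  aln <- two_clade_alignment()
  tr <- bootstrap_support(aln, n_reps = 200, seed = 99)
  supp <- as.numeric(tr$node.label)
  # the a1a2a3 | b1b2b3 bipartition is present in every replicate
  expect_gte(max(supp, na.rm = TRUE), 95)
  tr2 <- bootstrap_support(aln, n_reps = 200, seed = 99)
  expect_identical(tr$node.label, tr2$node.label)
  expect_identical(write_newick(tr), write_newick(tr2))
  # no supports without replicates
  tr0 <- bootstrap_support(aln, n_reps = 0)
  expect_null(tr0$node.label)
  expect_error(bootstrap_support(aln, n_reps = 10), "seed")
})
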