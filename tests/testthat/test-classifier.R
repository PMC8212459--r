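test_that("motif scanner applies exact per-position set membership", {
  expect_equal(scan_motif("KGKGGPAN", "CMIV-1"),
               data.frame(start = 1L, end = 8L))
  expect_equal(nrow(scan_motif("QGKGGPAN", "CMIV-1")), 0L)
  expect_equal(scan_motif("XXRGKGGPWNXX", "CMIV-1"),
               data.frame(start = 3L, end = 10L))
  # non-overlapping leftmost matches
  expect_equal(scan_motif("DSAWDSAWDSAW", "DSAW")$start, c(1L, 5L, 9L))
  # planted NLS found at the planted offset
  pr <- make_protein("single-AP2-with-WLG", "DREB1-NLS", seed = 8)
  hit <- scan_motif(pr$sequence, "DREB1-NLS")
  planted <- pr$motifs[pr$motifs$name == "DREB1-NLS", ]
  expect_equal(hit$start, planted$start)
  expect_error(scan_motif("MK-V", "DSAW"), "ungapped")
})

test_that("superfamily decision tree follows domain architecture in order", {
  dom <- ap2_consensus("DREB")
  two_ap2 <- paste0("MKKV", dom, "GGSSGG", dom, "KL")
  h2 <- find_consensus_domains(c(p = two_ap2))
  expect_identical(classify_superfamily(two_ap2, h2)$superfamily, "AP2")

  hits_rav <- data.frame(protein_id = "r", domain_name = c("AP2", "B3"),
                         start = c(5L, 80L), end = c(64L, 124L),
                         score = NA, evalue = NA)
  rav_seq <- paste0("MKKV", dom, paste(rep("G", 60), collapse = ""))
  expect_identical(classify_superfamily(rav_seq, hits_rav)$superfamily, "RAV")

  one <- paste0("MKKV", dom, "GGSSGG")
  h1 <- data.frame(protein_id = "p", domain_name = "AP2", start = 5L,
                   end = 64L, score = NA, evalue = NA)
  expect_identical(classify_superfamily(one, h1)$superfamily,
                   "DREB-candidate")
  erf <- paste0("MKKV", ap2_consensus("ERF"), "GGSSGG")
  expect_identical(classify_superfamily(erf, h1)$superfamily, "ERF")

  nowlg <- make_protein("single-AP2-no-WLG", seed = 2)
  hn <- find_consensus_domains(c(p = nowlg$sequence))
  expect_identical(classify_superfamily(nowlg$sequence, hn)$superfamily,
                   "atypical")
  expect_error(classify_superfamily("MKV", h1[0, ]), "not an AP2/ERF")
})

test_that("V14/E19 are read at domain-relative positions 14 and 19", {
  p <- paste0("GG", "XXXXXXXXXXXXXVXXXXE", "AAAA")
  expect_equal(check_v14_e19(p, 3L, 21L), c(v14 = "V", e19 = "E"))
  # DREB1-style: V14 with a non-E residue at 19 stays readable
  dom <- ap2_consensus("DREB")
  substr(dom, 19, 19) <- "Q"
  p2 <- paste0("MK", dom)
  expect_equal(check_v14_e19(p2, 3L, 62L), c(v14 = "V", e19 = "Q"))
  expect_error(check_v14_e19("AAAAAAAAAA", 1L, 10L), "shorter than 19")
})

test_that("DREB subgroup assignment uses upstream NLS/CMIV-1 evidence", {
  a1 <- make_protein("single-AP2-with-WLG", c("DREB1-NLS", "DSAW", "LWSY"),
                     seed = 11, id = "a1")
  h <- find_consensus_domains(c(a1 = a1$sequence))
  cl <- subgroup_dreb(classify_superfamily(a1$sequence, h), a1$sequence)
  expect_identical(cl$subgroup, "A-1")
  expect_true(cl$flags$dreb1_nls && cl$flags$dsaw && cl$flags$lwsy)

  # CMIV-1 without the PKK-like NLS: still A-2, dreb2_nls stays FALSE
  a2 <- make_protein("single-AP2-with-WLG", "CMIV-1", seed = 12, id = "a2")
  h2 <- find_consensus_domains(c(a2 = a2$sequence))
  cl2 <- subgroup_dreb(classify_superfamily(a2$sequence, h2), a2$sequence)
  expect_identical(cl2$subgroup, "A-2")
  expect_false(cl2$flags$dreb2_nls)

  plain <- make_protein("single-AP2-with-WLG", seed = 13, id = "pl")
  h3 <- find_consensus_domains(c(pl = plain$sequence))
  cl3 <- subgroup_dreb(classify_superfamily(plain$sequence, h3),
                       plain$sequence)
  expect_identical(cl3$subgroup, "other-A")

  both <- make_protein("single-AP2-with-WLG", c("DREB1-NLS", "CMIV-1"),
                       seed = 14, id = "b")
  h4 <- find_consensus_domains(c(b = both$sequence))
  expect_error(subgroup_dreb(classify_superfamily(both$sequence, h4),
                             both$sequence), "ambiguous")
})

test_that("physchem matches hand-computed oracle values", {
  expect_equal(physchem("AAA")$gravy, 1.8, tolerance = 1e-9)
  expect_equal(physchem("VVV")$aliphatic_index, 290, tolerance = 1e-9)
  expect_equal(physchem("GGGGG")$mw, 5 * 57.0519 + 18.01524,
               tolerance = 1e-6)
  # mixed composition, assembled from the constant tables by hand:
  # MW(ACD) = 71.0788 + 103.1388 + 115.0886 + water
  expect_equal(physchem("ACD")$mw, 307.32164, tolerance = 1e-4)
  expect_equal(physchem("ACD")$gravy, (1.8 + 2.5 - 3.5) / 3,
               tolerance = 1e-9)
  # instability: II(AC) = 10/2 * DIWV(A,C) = 5 * 44.94
  expect_equal(physchem("AC")$instability_index, 224.7, tolerance = 1e-6)
  expect_error(physchem(""), "empty")
  # X handling: GRAVY renormalised, pI/II unavailable
  px <- suppressWarnings(physchem("AXA"))
  expect_equal(px$gravy, 1.8)
  expect_true(is.na(px$pi))
})

test_that("pI is monotone under basic/acidic residue appends", {
  set.seed(33)
  for (rep in 1:30) {
    pep <- random_protein_seq(sample(8:25, 1))
    base <- physchem(pep)$pi
    expect_gte(physchem(paste0(pep, "K"))$pi, base - 2e-4)
    expect_lte(physchem(paste0(pep, "D"))$pi, base + 2e-4)
  }
})

test_that("allele grouping joins near-identical proteins on homologous chromosomes", {
  prot <- random_protein_seq(80)
  # ~60% identity partner: mutate 32 of 80 positions
  s <- strsplit(prot, "")[[1]]
  idx <- seq_len(32) * 2
  s[idx] <- ifelse(s[idx] == "A", "W", "A")
  far <- paste(s, collapse = "")
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    chromosome = c("Chr2A", "Chr2B", "Chr2B"),
    start = c(100L, 200L, 90000L), end = c(400L, 500L, 90300L),
    strand = "+", protein_id = c("p1", "p2", "p3"),
    cds_id = c("c1", "c2", "c3"), stringsAsFactors = FALSE)
  prots <- c(p1 = prot, p2 = prot, p3 = far)
  loci <- group_alleles(genes, prots)
  expect_identical(loci[1], loci[2])
  expect_false(loci[3] == loci[1])
  # below-threshold homologous-chromosome pair stays split
  loci2 <- group_alleles(genes[c(1, 3), ], prots[c(1, 3)])
  expect_equal(length(unique(loci2)), 2L)
  # single gene forms its own locus
  expect_equal(group_alleles(genes[1, , drop = FALSE], prots[1]), 1L)
  # same-haplotype near-identical pair: warning, separate loci
  genes_same <- genes
  genes_same$chromosome <- c("Chr2A", "Chr2A", "Chr2B")
  expect_warning(l3 <- group_alleles(genes_same, prots), "haplotype")
  expect_false(l3[1] == l3[2])
})

test_that("locus naming follows chromosomal order and is input-order invariant", {
  genes <- data.frame(
    gene_id = c("x", "y", "z", "w"),
    chromosome = c("Chr1A", "Chr1A", "Chr1B", "Chr2A"),
    start = c(500000L, 100000L, 120000L, 50L),
    end = c(500900L, 100900L, 120900L, 950L),
    strand = "+", protein_id = paste0("p", 1:4),
    cds_id = paste0("c", 1:4), stringsAsFactors = FALSE)
  loci <- c(1L, 2L, 2L, 3L)       # y/z co-allelic
  nm <- assign_names(genes, loci, "SsDREB1")
  expect_identical(unname(nm[c("y", "z")]), c("SsDREB1A-1", "SsDREB1A-2"))
  expect_identical(unname(nm[["x"]]), "SsDREB1B")
  expect_identical(unname(nm[["w"]]), "SsDREB1C")
  # permuting the table permutes nothing in the names
  perm <- c(3, 1, 4, 2)
  nm2 <- assign_names(genes[perm, ], loci[perm], "SsDREB1")
  expect_identical(nm2[names(nm)], nm)
  expect_error(assign_names(
    data.frame(gene_id = paste0("g", 1:27), chromosome = "Chr1A",
               start = 1:27 * 1000L, end = 1:27 * 1000L + 10L),
    1:27, "X"), "letters")
})
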