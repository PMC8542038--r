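test_that("planted difference sets match the requested fractions exactly", {
  spec <- genome_spec(stats::setNames(rep(200L, 5), paste0("chr", 1:5)),
                      5e5, seed = 2)
  # no flips: identical labels
  tr0 <- plant_architecture(spec, flip_fraction = 0, seed = 2)
  for (ch in tr0$chroms) expect_identical(ch$labels1, ch$labels2)
  expect_equal(nrow(tr0$flips), 0)

  # 12.1% of 1000 compartment bins: exactly 121 flipped bins recorded
  tr <- plant_architecture(spec, flip_fraction = 0.121, seed = 2)
  expect_equal(nrow(tr$flips), 121)
  n_diff <- sum(vapply(tr$chroms,
                       function(ch) sum(ch$labels1 != ch$labels2), 1L))
  expect_equal(n_diff, 121)

  # weaken half the boundaries: the recorded set is the set difference of
  # condition-wise truths plus the still-present softened boundaries
  tr_w <- plant_architecture(spec, weaken_fraction = 0.5, seed = 3)
  n_bnd <- sum(vapply(tr_w$chroms, function(ch) length(ch$boundaries1), 1L))
  expect_equal(nrow(tr_w$weakened), round(0.5 * n_bnd))
  removed <- sum(vapply(tr_w$chroms, function(ch)
    length(setdiff(ch$boundaries1, ch$boundaries2)), 1L))
  expect_equal(removed, nrow(tr_w$merged))
  soft <- tr_w$weakened[tr_w$weakened$level < 1, ]
  for (k in seq_len(nrow(soft)))
    expect_true(soft$boundary[k] %in%
                  tr_w$chroms[[soft$chrom[k]]]$boundaries2)

  expect_error(plant_architecture(spec, flip_fraction = 1.2),
               class = "hicarch_parameter_error")
})

test_that("weaken_fraction = 0.5 on 10 boundaries puts 5 in the weakened set", {
  # a single long chromosome engineered to carry exactly 10 boundaries
  spec <- genome_spec(c(chrL = 220L), 5e4, seed = 6)
  tr <- NULL
  for (s in 1:20) {
    cand <- plant_architecture(spec, seed = s, tad_size = 20L)
    if (length(cand$chroms$chrL$boundaries1) == 10L) { tr <- cand; break }
  }
  expect_false(is.null(tr))
  trw <- plant_architecture(spec, weaken_fraction = 0.5, seed = tr$seed,
                            tad_size = 20L)
  expect_equal(nrow(trw$weakened), 5L)
})

test_that("expected_contact composes multipliers over the decay baseline", {
  spec <- genome_spec(c(chrT = 40L), 5e5, seed = 1)
  tr <- plant_architecture(spec, seed = 1, depth = 100, alpha = 1,
                           rho = 1.5, tau = 2)
  # pin the architecture by hand: alternating labels, one boundary, no loops
  tr$chroms$chrT$labels1 <- tr$chroms$chrT$labels2 <-
    rep(c("A", "B"), 20)
  tr$chroms$chrT$boundaries1 <- tr$chroms$chrT$boundaries2 <- 20L
  tr$chroms$chrT$loops1 <- tr$chroms$chrT$loops2 <-
    tr$chroms$chrT$loops1[0, ]
  # adjacent pair across the boundary with opposite labels: pure baseline
  expect_equal(expected_contact(tr, 20, 21, "chrT"), 100)
  # same-TAD same-compartment pair: rho * tau = 3x the decayed baseline
  expect_equal(expected_contact(tr, 4, 6, "chrT"), 100 * 1.5 * 2 / 2)
  expect_equal(expected_contact(tr, 30, 31, "chrT") / 100, 2) # B/A adjacent same TAD
  expect_error(expected_contact(tr, 1, 2, "chrT", chrom_j = "chrX"),
               class = "hicarch_domain_error")
})

test_that("expected_matrix equals the brute-force double loop and is symmetric", {
  tr <- toy_truth(n = 50L, seed = 8, flip_fraction = 0.1,
                  weaken_fraction = 0.5, loop_loss_fraction = 0.3,
                  tad_size = 10L)
  for (cond in 1:2) {
    E <- expected_matrix(tr, "chrT", cond)
    expect_equal(E, oracle_expected_matrix(tr, "chrT", cond))
    expect_equal(E, t(E))
  }
})

test_that("sampling is seed-deterministic, Poisson-calibrated, and zero at zero depth", {
  tr <- toy_truth(n = 50L, seed = 4, depth = 1e6)
  m1 <- sample_contact_matrix(tr, 1, seed = 99)
  m2 <- sample_contact_matrix(tr, 1, seed = 99)
  expect_identical(m1$chrT$counts, m2$chrT$counts)

  # entrywise mean over 200 replicates within 3 standard errors of E
  E <- expected_matrix(tr, "chrT", 1)
  acc <- matrix(0, 50, 50)
  for (s in 1:200) acc <- acc + sample_contact_matrix(tr, 1, seed = s)$chrT$counts
  avg <- acc / 200
  se <- sqrt(E / 200)
  z <- abs(avg - E) / (se + 1e-12)
  # 3-SE entrywise with the usual Gaussian allowance for 2500 entries
  expect_gte(mean(z <= 3), 0.99)
  expect_true(all(z <= 5.5))

  # total-count Poisson concentration
  tot <- sum(m1$chrT$counts[upper.tri(m1$chrT$counts, diag = TRUE)])
  tot_e <- sum(E[upper.tri(E, diag = TRUE)])
  expect_lt(abs(tot - tot_e), 4 * sqrt(tot_e))

  tr0 <- toy_truth(n = 30L, seed = 4, depth = 0)
  expect_true(all(sample_contact_matrix(tr0, 1, seed = 1)$chrT$counts == 0))
})

test_that("marker tracks follow the condition labels at the requested snr", {
  tr <- toy_truth(n = 500L, seed = 10)
  lab <- tr$chroms$chrT$labels1
  # noiseless limit: active track is a two-level indicator of A bins
  tk <- generate_marker_tracks(tr, 1, snr = Inf, seed = 1)$chrT
  expect_equal(sort(unique(tk$H3K27ac$values)), c(2, 10))
  expect_true(all((tk$H3K27ac$values == 10) == (lab == "A")))
  expect_true(all((tk$H3K9me3$values == 10) == (lab == "B")))

  # snr = 5: strong correlation with the A indicator over 500 bins
  tk5 <- generate_marker_tracks(tr, 1, snr = 5, seed = 2)$chrT
  expect_gt(cor(tk5$H3K27ac$values, as.numeric(lab == "A")), 0.8)
  expect_gt(cor(tk5$H3K4me1$values, as.numeric(lab == "A")), 0.8)
  expect_lt(cor(tk5$H3K27me3$values, as.numeric(lab == "A")), -0.8)

  # all-B chromosome: active track statistically flat
  trB <- toy_truth(n = 60L, seed = 3)
  trB$chroms$chrT$labels1 <- rep("B", 60)
  tkB <- generate_marker_tracks(trB, 1, snr = 5, seed = 4)$chrT
  half1 <- tkB$H3K27ac$values[1:30]; half2 <- tkB$H3K27ac$values[31:60]
  expect_gt(t.test(half1, half2)$p.value, 0.01)
})

test_that("gene table couples fold change to switch direction", {
  tr <- toy_truth(n = 300L, seed = 5, flip_fraction = 0.2)
  g <- generate_gene_table(tr, n_genes = 2000L, de_effect = 4, seed = 7)
  lfc <- log2((g$fpkm_ko + 0.01) / (g$fpkm_wt + 0.01))
  m_ab <- mean(lfc[g$true_class == "A->B"])
  m_st <- mean(lfc[startsWith(g$true_class, "stable")])
  m_ba <- mean(lfc[g$true_class == "B->A"])
  expect_true(m_ab < m_st && m_st < m_ba)

  # near-null effect: class medians all near zero
  g0 <- generate_gene_table(tr, n_genes = 2000L, de_effect = 1 + 1e-9,
                            seed = 7, background_de = 0)
  lfc0 <- log2((g0$fpkm_ko + 0.01) / (g0$fpkm_wt + 0.01))
  for (cl in unique(g0$true_class))
    expect_lt(abs(median(lfc0[g0$true_class == cl])), 0.1)

  # midpoint assignment: the recorded class is the midpoint bin's class
  comp_bs <- tr$spec$bin_size * tr$comp_factor
  mid_bin <- floor((g$start + g$end) / 2 / comp_bs) + 1
  l1 <- tr$chroms$chrT$labels1[mid_bin]; l2 <- tr$chroms$chrT$labels2[mid_bin]
  cls <- ifelse(l1 == l2, paste("stable", l1), paste0(l1, "->", l2))
  expect_identical(g$true_class, cls)
})

test_that("generators are byte-identical under identical seeds", {
  spec <- genome_spec(c(chr1 = 60L, chr2 = 40L), 5e5, seed = 12)
  tr_a <- plant_architecture(spec, flip_fraction = 0.1,
                             weaken_fraction = 0.3, loop_loss_fraction = 0.2,
                             seed = 12)
  tr_b <- plant_architecture(spec, flip_fraction = 0.1,
                             weaken_fraction = 0.3, loop_loss_fraction = 0.2,
                             seed = 12)
  expect_identical(tr_a, tr_b)
  expect_identical(generate_marker_tracks(tr_a, 1, snr = 5, seed = 3),
                   generate_marker_tracks(tr_b, 1, snr = 5, seed = 3))
  expect_identical(generate_gene_table(tr_a, 100L, 2, seed = 5),
                   generate_gene_table(tr_b, 100L, 2, seed = 5))
})

test_that("file writers round-trip tracks, genes and truth", {
  tr <- toy_truth(n = 30L, seed = 2)
  tk <- generate_marker_tracks(tr, 1, snr = 5, seed = 1)$chrT$H3K27ac
  f <- withr::local_tempfile()
  write_bedgraph(tk, f)
  bg <- read.table(f)
  expect_equal(nrow(bg), 30)
  expect_equal(bg$V2[1], 0)
  expect_equal(bg$V3[2] - bg$V2[2], tk$bin_size)
  expect_equal(bg$V4, tk$values, tolerance = 1e-6)

  g <- generate_gene_table(tr, 50L, 2, seed = 3)
  write_gene_table(g, f)
  g2 <- read_gene_table(f)
  expect_equal(g2$fpkm_wt, g$fpkm_wt, tolerance = 1e-6)
  expect_identical(g2$de_flag, g$de_flag)

  write_truth_json(tr, f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(unlist(j$chromosomes$chrT$labels1), tr$chroms$chrT$labels1)
  expect_equal(j$params$rho, tr$params$rho)
})
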