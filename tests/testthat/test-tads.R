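make_kr <- function(M, masked = rep(FALSE, nrow(M))) {
  contact_matrix(M, "chrT", 5e4, normalized = "kr",
                 balancing = ifelse(masked, NA_real_, 1), masked = masked)
}

test_that("binSignal dips exactly at an ideal block boundary", {
  n <- 30
  blk <- c(rep(1, 15), rep(2, 15))
  M <- ifelse(outer(blk, blk, "=="), 10, 1)
  bs <- bin_signal(make_kr(M), w = 5)
  interior <- 6:24
  expect_equal(which.min(bs[interior]) + 5L, 15L)
})

test_that("binSignal equals the brute-force cross-window mean", {
  M <- random_symmetric_counts(20, seed = 13)
  expect_equal(bin_signal(make_kr(M), w = 5),
               oracle_bin_signal(M, w = 5))
  # with masked bins
  msk <- rep(FALSE, 20); msk[c(4, 11)] <- TRUE
  expect_equal(bin_signal(make_kr(M, msk), w = 5),
               oracle_bin_signal(M, w = 5, masked = msk))
  # all matrices up to 50 bins
  for (n in c(35, 50)) {
    Mn <- random_symmetric_counts(n, seed = n)
    expect_equal(bin_signal(make_kr(Mn), w = 7),
                 oracle_bin_signal(Mn, w = 7))
  }
  expect_error(bin_signal(make_kr(M), w = 10),
               class = "hicarch_parameter_error")
})

test_that("binSignal is flat on a uniform matrix", {
  M <- matrix(4, 24, 24)
  bs <- bin_signal(make_kr(M), w = 5)
  expect_equal(unique(bs[5:19]), 4)
})

test_that("smoothing is a centred running mean with end shrinkage", {
  expect_equal(smooth_signal(c(1, 2, 3, 4), 3), c(1.5, 2, 3, 3.5))
  x <- rnorm(10)
  expect_identical(smooth_signal(x, 1), x)
  expect_equal(smooth_signal(rep(2, 8), 5), rep(2, 8))
  expect_error(smooth_signal(x, 2), class = "hicarch_parameter_error")
  # flagged bins propagate
  y <- c(1, NA, 3, 4, 5)
  sm <- smooth_signal(y, 3)
  expect_true(is.na(sm[2]))
  expect_false(anyNA(sm[-2]))
})

test_that("boundary calling finds planted minima, ignores monotone signal, breaks ties left", {
  # single planted boundary on deep synthetic data
  tr <- toy_truth(n = 100L, seed = 91, tad_size = 45L, depth = 1e6)
  b_true <- tr$chroms$chrT$boundaries1
  expect_length(b_true, 1L)
  kr <- kr_balance(sample_contact_matrix(tr, 1, seed = 23)$chrT)
  tads <- call_tads(kr)
  expect_true(any(abs(tads$boundaries - b_true) <= 1))

  # monotone signal: no boundaries, one whole-extent domain
  mono <- call_boundaries(seq(1, 5, length.out = 40), w = 5)
  expect_length(mono$boundaries, 0L)
  expect_equal(nrow(mono$domains), 1L)
  expect_equal(mono$domains$end - mono$domains$start + 1L, 40L)

  # plateau of tied minima: leftmost bin wins
  sig <- c(5, 5, 5, 4, 1, 1, 1, 4, 5, 5, 5)
  pl <- call_boundaries(sig, w = 3, min_depth = 0.5)
  expect_equal(pl$boundaries, 5L)
})

test_that("domains tile the unmasked extent without overlap", {
  tr <- toy_truth(n = 120L, seed = 92, tad_size = 20L, depth = 1e6)
  kr <- kr_balance(sample_contact_matrix(tr, 1, seed = 29)$chrT)
  tads <- call_tads(kr)
  d <- tads$domains
  expect_true(all(d$end >= d$start))
  expect_equal(d$start[-1], d$end[-nrow(d)] + 1L)
  ok <- which(!is.na(tads$smoothed))
  expect_equal(sum(d$end - d$start + 1L), max(ok) - min(ok) + 1L)
})

test_that("boundary strength measures insulation depth and responds to it", {
  two_block <- function(depletion) {
    n <- 30
    blk <- c(rep(1, 15), rep(2, 15))
    M <- ifelse(outer(blk, blk, "=="), 10, 10 * (1 - depletion))
    call_tads(make_kr(M), w = 5)
  }
  t_weak <- two_block(0.5); t_strong <- two_block(0.9)
  expect_length(t_weak$boundaries, 1L)
  s_weak <- unname(t_weak$strength[1]); s_strong <- unname(t_strong$strength[1])
  expect_gt(s_weak, 0)
  expect_gt(s_strong, s_weak)

  # flat matrix: zero strength at any forced boundary
  flat <- call_boundaries(rep(3, 30), w = 5, min_depth = 0)
  flat$boundaries <- 15L
  flat$domains <- data.frame(start = c(1L, 16L), end = c(15L, 30L))
  flat <- boundary_strength(flat)
  expect_equal(unname(flat$strength[1]), 0)

  # stored strengths equal recomputation from the stored binSignal
  tr <- toy_truth(n = 120L, seed = 93, tad_size = 20L, depth = 1e6)
  tads <- call_tads(kr_balance(sample_contact_matrix(tr, 1, 31)$chrT))
  re <- boundary_strength(tads)
  expect_identical(re$strength, tads$strength)
})

test_that("boundary positions are invariant to matrix rescaling", {
  tr <- toy_truth(n = 100L, seed = 94, tad_size = 20L, depth = 1e6)
  kr <- kr_balance(sample_contact_matrix(tr, 1, seed = 37)$chrT)
  kr2 <- kr
  kr2$counts <- kr$counts * 7.5
  expect_identical(call_tads(kr)$boundaries, call_tads(kr2)$boundaries)
})

test_that("boundary comparison matches within slack and classifies changes", {
  tr <- toy_truth(n = 120L, seed = 95, tad_size = 20L, depth = 1e6)
  kr <- kr_balance(sample_contact_matrix(tr, 1, seed = 41)$chrT)
  tads <- call_tads(kr)
  # identity: everything unchanged
  cmp <- compare_boundaries(tads, tads)
  expect_equal(unname(cmp$counts[["unchanged"]]), length(tads$boundaries))
  expect_equal(unname(cmp$counts[["lost"]] + cmp$counts[["gained"]]), 0L)

  # slack 0 with positions offset by one: lost + gained, never matched
  t2 <- tads
  t2$boundaries <- tads$boundaries + 1L
  names(t2$strength) <- as.character(t2$boundaries)
  cmp0 <- compare_boundaries(tads, t2, match_slack = 0L)
  expect_equal(nrow(cmp0$matched), 0L)
  expect_equal(unname(cmp0$counts[["lost"]]), length(tads$boundaries))
  expect_equal(unname(cmp0$counts[["gained"]]), length(tads$boundaries))

  bad <- t2; bad$bin_size <- 1
  expect_error(compare_boundaries(tads, bad),
               class = "hicarch_alignment_error")
})

test_that("tad_stats arithmetic and the merge phenomenon", {
  one <- call_boundaries(c(rep(2, 40)), w = 5, min_depth = 1e9,
                         bin_size = 5e4)
  st <- tad_stats(one)
  expect_equal(unname(st[["n_domains"]]), 1)
  expect_equal(unname(st[["mean_size_mb"]]), 2.0)

  # removing a shared boundary merges two domains: fewer, larger
  tr <- toy_truth(n = 120L, seed = 96, tad_size = 20L, depth = 1e6)
  tads <- call_tads(kr_balance(sample_contact_matrix(tr, 1, 43)$chrT))
  merged <- tads
  merged$boundaries <- tads$boundaries[-1]
  brk <- c(tads$domains$start[1] - 1L, merged$boundaries,
           tads$domains$end[nrow(tads$domains)])
  merged$domains <- data.frame(start = head(brk, -1) + 1L, end = brk[-1])
  expect_equal(unname(tad_stats(merged)[["n_domains"]]),
               unname(tad_stats(tads)[["n_domains"]]) - 1)
  expect_gt(tad_stats(merged)[["mean_size_mb"]],
            tad_stats(tads)[["mean_size_mb"]])

  # independent recount from the domain list
  len <- tads$domains$end - tads$domains$start + 1L
  expect_equal(unname(tad_stats(tads)[["mean_size_mb"]]),
               sum(len) / length(len) * tads$bin_size / 1e6)
})

test_that("planted boundary weakening yields merged, larger condition-2 domains", {
  hits <- 0; n1 <- c(); n2 <- c(); ms1 <- c(); ms2 <- c()
  weak_frac <- c()
  for (s in 1:3) {
    spec <- genome_spec(c(c1 = 200L, c2 = 200L), 5e4, seed = s)
    tr <- plant_architecture(spec, weaken_fraction = 0.5, seed = s,
                             comp_factor = 10L, tad_size = 20L)
    m1 <- sample_contact_matrix(tr, 1, seed = 100 + s)
    m2 <- sample_contact_matrix(tr, 2, seed = 200 + s)
    tot1 <- 0; tot2 <- 0; sz1 <- c(); sz2 <- c(); wk_ok <- 0; wk_n <- 0
    for (nm in names(tr$chroms)) {
      t1 <- call_tads(kr_balance(m1[[nm]]))
      t2 <- call_tads(kr_balance(m2[[nm]]))
      tot1 <- tot1 + tad_stats(t1)[["n_domains"]]
      tot2 <- tot2 + tad_stats(t2)[["n_domains"]]
      sz1 <- c(sz1, tad_stats(t1)[["mean_size_mb"]])
      sz2 <- c(sz2, tad_stats(t2)[["mean_size_mb"]])
      cmp <- compare_boundaries(t1, t2)
      wk <- tr$weakened[tr$weakened$chrom == nm, ]
      for (r in seq_len(nrow(wk))) {
        wk_n <- wk_n + 1
        mrow <- cmp$matched[abs(cmp$matched$position1 - wk$boundary[r]) <= 2, ]
        if (nrow(mrow) && any(mrow$class == "weaker")) wk_ok <- wk_ok + 1
      }
    }
    n1 <- c(n1, tot1); n2 <- c(n2, tot2)
    ms1 <- c(ms1, mean(sz1)); ms2 <- c(ms2, mean(sz2))
    weak_frac <- c(weak_frac, wk_ok / wk_n)
  }
  expect_true(all(n2 < n1))
  expect_true(all(ms2 > ms1))
  expect_true(all(weak_frac >= 0.8))
})
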