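# Independent oracles used across the suite. Each reimplements the target
# quantity by the most transparent route available (dictionary accumulation,
# double loops, power iteration, alternating scaling), never by calling the
# package's own code path.

# Sinkhorn-Knopp alternating row/column scaling to a common target row sum,
# run to a tight tolerance; the balanced matrix (not the vectors) is the
# comparable object.
oracle_sinkhorn <- function(A, target = mean(rowSums(A)), tol = 1e-12,
                            max_iter = 1e5) {
  r <- rep(1, nrow(A)); cvec <- rep(1, ncol(A))
  for (it in seq_len(max_iter)) {
    r <- target / as.vector(A %*% cvec)
    cvec <- target / as.vector(t(A) %*% r)
    B <- diag(r) %*% A %*% diag(cvec)
    if (max(abs(rowSums(B) - target)) < tol &&
        max(abs(colSums(B) - target)) < tol) break
  }
  # symmetrise the output of the asymmetric iteration
  (B + t(B)) / 2
}

# power iteration for the top eigenvector of a symmetric PSD-ish matrix
oracle_power_iteration <- function(C, iters = 5000, tol = 1e-14) {
  v <- rep(1, nrow(C)) + seq_len(nrow(C)) / nrow(C)
  v <- v / sqrt(sum(v^2))
  for (i in seq_len(iters)) {
    w <- as.vector(C %*% v)
    w <- w / sqrt(sum(w^2))
    if (max(abs(w - v)) < tol || max(abs(w + v)) < tol) { v <- w; break }
    v <- w
  }
  v
}

# brute-force TopDom binSignal by explicit double loop over the cross-window
oracle_bin_signal <- function(counts, w, masked = rep(FALSE, nrow(counts))) {
  n <- nrow(counts)
  out <- rep(NA_real_, n)
  for (i in seq_len(n - 1)) {
    vals <- c()
    for (u in max(1, i - w + 1):i) {
      for (v in (i + 1):min(n, i + w)) {
        if (masked[u] || masked[v]) next
        vals <- c(vals, counts[u, v])
      }
    }
    if (length(vals)) out[i] <- mean(vals)
  }
  out
}

# brute-force donut annulus mean with stripe and mask exclusion
oracle_donut <- function(counts, i, j, r_inner, r_outer,
                         masked = rep(FALSE, nrow(counts))) {
  vals <- c()
  for (u in (i - r_outer):(i + r_outer)) {
    for (v in (j - r_outer):(j + r_outer)) {
      cd <- max(abs(u - i), abs(v - j))
      if (cd <= r_inner || cd > r_outer) next
      if (u == i || v == j) next
      if (masked[u] || masked[v]) next
      vals <- c(vals, counts[u, v])
    }
  }
  mean(vals)
}

# expected contact matrix by a literal double loop over expected_contact
oracle_expected_matrix <- function(truth, chrom, condition) {
  n <- truth$chroms[[chrom]]$n_fine
  E <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      E[i, j] <- expected_contact(truth, i, j, chrom, condition = condition)
  E
}

# small ready-made truth objects -------------------------------------------

# one chromosome, fine grid only (compartments at the fine grid)
toy_truth <- function(n = 60L, seed = 42L, ...) {
  spec <- genome_spec(c(chrT = as.integer(n)), 5e5, seed = seed)
  plant_architecture(spec, seed = seed, ...)
}

# run the compartment stage for one condition and return profiles keyed by
# chromosome (the standard recovery pipeline used by several tests)
recover_profiles <- function(truth, condition, seed, snr = 5) {
  mats <- sample_contact_matrix(truth, condition, seed = seed)
  tracks <- generate_marker_tracks(truth, condition = condition, snr = snr,
                                   seed = seed + 1L)
  out <- list()
  for (nm in names(mats)) {
    oe <- distance_normalize(kr_balance(mats[[nm]]))
    p <- orient_and_label(correlation_pc1(oe),
                          tracks[[nm]][c("H3K4me1", "H3K27ac")],
                          tracks[[nm]][c("H3K9me3", "H3K27me3")])
    out[[nm]] <- compartment_degree(oe, p)
  }
  out
}

random_symmetric_counts <- function(n, seed, scale = 50) {
  set.seed(seed)
  M <- matrix(stats::runif(n * n, 1, scale), n, n)
  M <- (M + t(M)) / 2
  M
}
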