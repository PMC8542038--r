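#' Donut-background expected count for one pixel
#'
#' Local expected value of pixel (i, j): the mean balanced count over the
#' Chebyshev annulus `r_inner < max(|u-i|, |v-j|) <= r_outer`, excluding the
#' pixel's own row and column stripes inside the annulus and any masked
#' bins. The pixel must sit at least `r_outer` from the matrix edge and far
#' enough off-diagonal (`j - i > 2 r_outer`) that the annulus lies entirely
#' in the upper triangle.
#'
#' @param m `contact_matrix` with `normalized = "kr"`.
#' @param i,j pixel bin indices (1-based, i < j).
#' @param r_inner,r_outer annulus radii in bins (`r_outer > r_inner >= 1`).
#' @return expected count for one pixel (mean over the annulus).
#' @export
donut_expected <- function(m, i, j, r_inner = 2L, r_outer = 5L) {
  if (r_inner < 1L || r_outer <= r_inner)
    err_param("need r_outer > r_inner >= 1")
  n <- m$n_bins
  if (i - r_outer < 1L || j + r_outer > n || j - i <= 2L * r_outer)
    err_domain("pixel too close to the matrix edge or diagonal for the donut")
  keep <- !m$masked
  tot <- 0; cnt <- 0L
  for (u in (i - r_outer):(i + r_outer)) {
    for (v in (j - r_outer):(j + r_outer)) {
      cd <- max(abs(u - i), abs(v - j))
      if (cd <= r_inner || cd > r_outer) next
      if (u == i || v == j) next
      if (!keep[u] || !keep[v]) next
      tot <- tot + m$counts[u, v]
      cnt <- cnt + 1L
    }
  }
  if (cnt == 0L) err_degenerate("donut annulus entirely masked")
  tot / cnt
}

# summed-area table with zero padding: S[a+1, b+1] = sum X[1:a, 1:b]
sat <- function(X) {
  n <- nrow(X)
  S <- matrix(0, n + 1L, n + 1L)
  S[-1L, -1L] <- apply(apply(X, 2, cumsum), 1, cumsum) |> t()
  S
}

# vectorised box sums over a padded SAT for index vectors r1..r2 x c1..c2
box_sum <- function(S, r1, r2, c1, c2) {
  np <- nrow(S)
  at <- function(a, b) S[(b - 1L) * np + a]
  at(r2 + 1L, c2 + 1L) - at(r1, c2 + 1L) - at(r2 + 1L, c1) + at(r1, c1)
}

# donut expected values for all pixels at once (same definition as
# donut_expected, computed via summed-area tables)
donut_expected_bulk <- function(m, i, j, r_inner, r_outer) {
  keep <- as.numeric(!m$masked)
  X <- m$counts * outer(keep, keep)
  V <- outer(keep, keep)
  SX <- sat(X); SV <- sat(V)
  RX <- t(apply(cbind(0, X), 1, cumsum))   # row prefix sums, zero-padded
  RV <- t(apply(cbind(0, V), 1, cumsum))
  CX <- apply(rbind(0, X), 2, cumsum)      # column prefix sums
  CV <- apply(rbind(0, V), 2, cumsum)
  n <- m$n_bins
  stripe_row <- function(P, i, c1, c2) P[(c2 * n) + i] - P[((c1 - 1L) * n) + i]
  ann <- function(S) box_sum(S, i - r_outer, i + r_outer,
                             j - r_outer, j + r_outer) -
    box_sum(S, i - r_inner, i + r_inner, j - r_inner, j + r_inner)
  row_str <- function(P) {
    full <- P[((j + r_outer) * n) + i] - P[((j - r_outer - 1L) * n) + i]
    inn <- P[((j + r_inner) * n) + i] - P[((j - r_inner - 1L) * n) + i]
    full - inn
  }
  col_str <- function(P) {
    np <- n + 1L
    at <- function(r, c) P[(c - 1L) * np + r]
    (at(i + r_outer + 1L, j) - at(i - r_outer, j)) -
      (at(i + r_inner + 1L, j) - at(i - r_inner, j))
  }
  tot <- ann(SX) - row_str(RX) - col_str(CX)
  cnt <- ann(SV) - row_str(RV) - col_str(CV)
  ifelse(cnt > 0, tot / cnt, NA_real_)
}

#' Call chromatin loops by donut enrichment
#'
#' Simplified HiCCUPS-style caller: every eligible pixel (off-diagonal
#' separation of at least `max(min_sep, 2 r_outer + 1)` bins, full donut
#' inside the matrix, both bins unmasked) gets a Poisson upper-tail p-value
#' of its rounded balanced count against the donut expected value,
#' Benjamini-Hochberg correction is applied across all eligible pixels of
#' the chromosome, and pixels passing the FDR with observed > expected are
#' merged into 8-connected clusters, keeping each cluster's most significant
#' pixel as the loop call. Besides the FDR, a called pixel must exceed its
#' donut background by the fold factor `min_enrich`: at deep sequencing the
#' Poisson test alone flags any mild excess over the annulus - in particular
#' domain-corner pixels whose enrichment approaches the within-TAD contact
#' boost - so the fold threshold must dominate the strongest non-loop
#' architectural multiplier (the default of 2 equals the within-TAD boost a
#' domain corner can at most approach but never attain). A fold threshold
#' over the local background is the standard HiCCUPS guard.
#'
#' @param m `contact_matrix` with `normalized = "kr"`.
#' @param fdr BH false-discovery-rate threshold in (0, 1).
#' @param min_sep minimum bin separation of candidate pixels (default 2).
#' @param r_inner,r_outer donut radii in bins (defaults 2 and 5).
#' @param min_enrich minimum observed/expected fold enrichment of a called
#'   pixel (default 2).
#' @return `loop_set` with one row per called loop.
#' @export
call_loops <- function(m, fdr = 0.1, min_sep = 2L, r_inner = 2L,
                       r_outer = 5L, min_enrich = 2) {
  if (m$normalized != "kr") err_state("call_loops expects a KR-balanced matrix")
  if (fdr <= 0 || fdr >= 1) err_param("fdr must be in (0, 1)")
  n <- m$n_bins
  keep <- !m$masked
  empty <- data.frame(i = integer(0), j = integer(0), observed = numeric(0),
                      expected = numeric(0), p_value = numeric(0),
                      q_value = numeric(0))
  mk <- function(px) structure(
    list(chrom = m$chrom, bin_size = m$bin_size, pixels = px, fdr = fdr,
         r_inner = r_inner, r_outer = r_outer, min_sep = min_sep,
         n_tested = if (exists("i_v", inherits = FALSE)) length(i_v) else 0L),
    class = "loop_set")
  sep_min <- max(min_sep, 2L * r_outer + 1L)
  if (n < sep_min + 2L * r_outer + 2L) return(mk(empty))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i_v <- idx[, 1]; j_v <- idx[, 2]
  ok <- (j_v - i_v) >= sep_min & i_v - r_outer >= 1L & j_v + r_outer <= n &
    keep[i_v] & keep[j_v]
  i_v <- i_v[ok]; j_v <- j_v[ok]
  if (!length(i_v)) return(mk(empty))
  exp_v <- donut_expected_bulk(m, i_v, j_v, r_inner, r_outer)
  def <- !is.na(exp_v)
  i_v <- i_v[def]; j_v <- j_v[def]; exp_v <- exp_v[def]
  obs <- round(m$counts[(j_v - 1L) * n + i_v])
  p <- stats::ppois(obs - 1, exp_v, lower.tail = FALSE)
  q <- stats::p.adjust(p, "BH")
  hit <- which(q <= fdr & obs > exp_v & obs >= min_enrich * exp_v)
  if (!length(hit)) return(mk(empty))
  hi <- i_v[hit]; hj <- j_v[hit]
  # 8-connected clustering of significant pixels
  comp <- rep(NA_integer_, length(hit))
  nc <- 0L
  for (s in seq_along(hit)) {
    if (!is.na(comp[s])) next
    nc <- nc + 1L
    queue <- s
    comp[s] <- nc
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      nb <- which(is.na(comp) &
                    pmax(abs(hi - hi[cur]), abs(hj - hj[cur])) <= 1L)
      comp[nb] <- nc
      queue <- c(queue, nb)
    }
  }
  rep_rows <- vapply(seq_len(nc), function(cc) {
    members <- which(comp == cc)
    members[order(p[hit][members], q[hit][members],
                  hi[members], hj[members])][1]
  }, 1L)
  px <- data.frame(i = hi[rep_rows], j = hj[rep_rows],
                   observed = obs[hit][rep_rows],
                   expected = exp_v[hit][rep_rows],
                   p_value = p[hit][rep_rows], q_value = q[hit][rep_rows])
  px <- px[order(px$i, px$j), , drop = FALSE]
  rownames(px) <- NULL
  mk(px)
}

#' @export
print.loop_set <- function(x, ...) {
  cat(sprintf("<loop_set> %s: %d loops @ %s bp (FDR %.2g, donut %d-%d)\n",
              x$chrom, nrow(x$pixels), format(x$bin_size, big.mark = ","),
              x$fdr, x$r_inner, x$r_outer))
  invisible(x)
}

#' Compare loop sets between two conditions
#'
#' Loops are matched greedily by Chebyshev distance of their pixel
#' coordinates within `slack` bins; unmatched loops are lost (condition 1
#' only) or gained (condition 2 only).
#'
#' @param l1,l2 `loop_set`s on the same grid.
#' @param slack maximum matching distance in bins (default 2).
#' @return list with `shared` (data.frame of matched pixel pairs), `lost`,
#'   `gained` (pixel data.frames), and `counts`.
#' @export
compare_loops <- function(l1, l2, slack = 2L) {
  if (!identical(l1$chrom, l2$chrom) || l1$bin_size != l2$bin_size)
    err_align("loop sets are not on the same chromosome grid")
  p1 <- l1$pixels; p2 <- l2$pixels
  pairs <- expand.grid(k1 = seq_len(nrow(p1)), k2 = seq_len(nrow(p2)))
  if (nrow(pairs)) {
    pairs$d <- pmax(abs(p1$i[pairs$k1] - p2$i[pairs$k2]),
                    abs(p1$j[pairs$k1] - p2$j[pairs$k2]))
    pairs <- pairs[pairs$d <= slack, , drop = FALSE]
    pairs <- pairs[order(pairs$d, pairs$k1), , drop = FALSE]
  }
  used1 <- logical(nrow(p1)); used2 <- logical(nrow(p2))
  m1 <- integer(0); m2 <- integer(0)
  for (r in seq_len(nrow(pairs))) {
    k1 <- pairs$k1[r]; k2 <- pairs$k2[r]
    if (used1[k1] || used2[k2]) next
    used1[k1] <- TRUE; used2[k2] <- TRUE
    m1 <- c(m1, k1); m2 <- c(m2, k2)
  }
  shared <- data.frame(i1 = p1$i[m1], j1 = p1$j[m1],
                       i2 = p2$i[m2], j2 = p2$j[m2])
  list(shared = shared,
       lost = p1[!used1, , drop = FALSE],
       gained = p2[!used2, , drop = FALSE],
       counts = c(shared = nrow(shared), lost = sum(!used1),
                  gained = sum(!used2), n1 = nrow(p1), n2 = nrow(p2)))
}

#' Write loops as BEDPE
#'
#' Columns: chrom1, start1, end1, chrom2, start2, end2, observed, expected,
#' q-value.
#'
#' @param loops `loop_set`.
#' @param path output file.
#' @export
write_loops_bedpe <- function(loops, path) {
  p <- loops$pixels
  bs <- loops$bin_size
  utils::write.table(
    data.frame(loops$chrom, (p$i - 1L) * bs, p$i * bs,
               loops$chrom, (p$j - 1L) * bs, p$j * bs,
               p$observed, format(p$expected, digits = 6),
               format(p$q_value, digits = 6)),
    path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
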