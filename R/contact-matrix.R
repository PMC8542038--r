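#' Construct a per-chromosome contact matrix
#'
#' The central container of the package: a symmetric, non-negative, dense
#' matrix of binned intra-chromosomal contact counts plus its normalisation
#' state. Balanced (`kr`) and observed/expected (`oe`) matrices carry the
#' Knight-Ruiz balancing vector and a logical mask of dropped bins.
#'
#' @param counts symmetric numeric matrix of non-negative counts.
#' @param chrom chromosome name.
#' @param bin_size bin width in bp.
#' @param normalized one of `"raw"`, `"kr"`, `"oe"`.
#' @param balancing per-bin positive weights (`NA` for masked bins); required
#'   when `normalized != "raw"`.
#' @param masked logical per-bin mask (TRUE = excluded from analysis).
#' @return `contact_matrix` object.
#' @export
contact_matrix <- function(counts, chrom, bin_size, normalized = "raw",
                           balancing = NULL, masked = NULL) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (ncol(counts) != n) err_param("counts must be square")
  if (any(counts < 0)) err_param("counts must be non-negative")
  if (max(abs(counts - t(counts))) > 1e-8 * max(1, max(abs(counts))))
    err_param("counts must be symmetric")
  normalized <- match.arg(normalized, c("raw", "kr", "oe"))
  if (normalized != "raw" && is.null(balancing))
    err_param("balanced matrices must carry their balancing vector")
  if (is.null(masked)) masked <- rep(FALSE, n)
  structure(
    list(chrom = chrom, bin_size = as.numeric(bin_size), n_bins = n,
         counts = unname(counts), balancing = balancing,
         normalized = normalized, masked = masked),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d x %d bins @ %s bp [%s]%s\n",
              x$chrom, x$n_bins, x$n_bins,
              format(x$bin_size, big.mark = ","), x$normalized,
              if (any(x$masked)) sprintf(", %d masked", sum(x$masked)) else ""))
  cat(sprintf("  total counts: %.4g\n", sum(x$counts)))
  invisible(x)
}

#' @export
summary.contact_matrix <- function(object, ...) {
  ut <- object$counts[upper.tri(object$counts, diag = TRUE)]
  out <- list(chrom = object$chrom, n_bins = object$n_bins,
              normalized = object$normalized, masked = sum(object$masked),
              total = sum(ut), nonzero = mean(ut > 0))
  class(out) <- "summary.contact_matrix"
  out
}

#' @export
print.summary.contact_matrix <- function(x, ...) {
  cat(sprintf("%s: %d bins [%s], %d masked, total %.4g, %.1f%% nonzero\n",
              x$chrom, x$n_bins, x$normalized, x$masked, x$total,
              100 * x$nonzero))
  invisible(x)
}

#' Per-bin signal track
#'
#' Bin-aligned real-valued signal (e.g. a histone mark) matching a contact
#' matrix grid.
#'
#' @param values numeric per-bin signal, all finite.
#' @param chrom chromosome name.
#' @param bin_size bin width in bp.
#' @param mark_name track label (e.g. `"H3K27ac"`).
#' @return `bin_track` object.
#' @export
bin_track <- function(values, chrom, bin_size, mark_name = "signal") {
  if (!all(is.finite(values))) err_param("track values must be finite")
  structure(list(chrom = chrom, bin_size = as.numeric(bin_size),
                 values = as.numeric(values), mark_name = mark_name),
            class = "bin_track")
}

#' @export
print.bin_track <- function(x, ...) {
  cat(sprintf("<bin_track> %s on %s: %d bins @ %s bp, mean %.3f\n",
              x$mark_name, x$chrom, length(x$values),
              format(x$bin_size, big.mark = ","), mean(x$values)))
  invisible(x)
}

#' Read sparse-triplet contact matrices
#'
#' Parses whitespace-separated lines `chrom bin_i bin_j count` (0-based bin
#' indices) into one raw symmetric `contact_matrix` per chromosome of the
#' genome spec. Entries listed once with i <= j are mirrored; duplicate
#' (i, j) records are summed.
#'
#' @param path triplet text file.
#' @param genome `genome_spec` describing the grid the file must fit.
#' @return named list of `contact_matrix` (one per spec chromosome, all-zero
#'   matrices for chromosomes absent from the file).
#' @export
read_triplets <- function(path, genome) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("chrom", "i", "j", "count"),
                          colClasses = c("character", "integer", "integer",
                                         "numeric"))
  bad <- which(!df$chrom %in% names(genome$chromosomes))
  if (length(bad))
    err_format(sprintf("line %d: unknown chromosome '%s'", bad[1],
                       df$chrom[bad[1]]))
  nb <- genome$chromosomes[df$chrom]
  oob <- which(df$i < 0L | df$j < 0L | df$i >= nb | df$j >= nb)
  if (length(oob))
    err_format(sprintf("line %d: bin index out of range for %s",
                       oob[1], df$chrom[oob[1]]))
  out <- list()
  for (nm in names(genome$chromosomes)) {
    n <- genome$chromosomes[[nm]]
    m <- matrix(0, n, n)
    sub <- df[df$chrom == nm, , drop = FALSE]
    if (nrow(sub)) {
      i <- pmin(sub$i, sub$j) + 1L
      j <- pmax(sub$i, sub$j) + 1L
      # duplicates accumulate
      for (k in seq_len(nrow(sub))) m[i[k], j[k]] <- m[i[k], j[k]] + sub$count[k]
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
    }
    out[[nm]] <- contact_matrix(m, nm, genome$bin_size)
  }
  out
}

#' Write contact matrices as sparse triplets
#'
#' Upper-triangle (i <= j, 0-based) nonzero entries, whitespace-separated.
#'
#' @param mats `contact_matrix` or list of them.
#' @param path output file.
#' @export
write_triplets <- function(mats, path) {
  if (inherits(mats, "contact_matrix")) mats <- list(mats)
  con <- file(path, "w"); on.exit(close(con))
  for (m in mats) {
    idx <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0,
                 arr.ind = TRUE)
    if (nrow(idx)) {
      o <- order(idx[, 1], idx[, 2])
      idx <- idx[o, , drop = FALSE]
      writeLines(sprintf("%s %d %d %s", m$chrom, idx[, 1] - 1L, idx[, 2] - 1L,
                         format(m$counts[idx], trim = TRUE, scientific = FALSE)),
                 con)
    }
  }
  invisible(path)
}

#' Write a small matrix as dense TSV
#' @param m `contact_matrix`.
#' @param path output file.
#' @export
write_dense_tsv <- function(m, path) {
  utils::write.table(m$counts, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a balancing vector as 2-column TSV (bin, weight; NA for masked)
#' @param m balanced `contact_matrix`.
#' @param path output file.
#' @export
write_balancing_tsv <- function(m, path) {
  if (is.null(m$balancing)) err_state("matrix carries no balancing vector")
  utils::write.table(
    data.frame(bin = seq_len(m$n_bins) - 1L,
               weight = ifelse(is.na(m$balancing), "NA",
                               format(m$balancing, digits = 10))),
    path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Coarsen a contact matrix by block summation
#'
#' Aggregates `factor` x `factor` blocks of bins by summation, the standard
#' way a fine-resolution Hi-C map is re-binned to a coarser resolution.
#' Trailing bins that do not fill a complete block are dropped.
#'
#' @param m raw `contact_matrix`.
#' @param factor integer >= 1, fine bins per coarse bin.
#' @return raw `contact_matrix` at `bin_size * factor`.
#' @export
coarsen_matrix <- function(m, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) err_param("factor must be >= 1")
  if (factor == 1L) return(m)
  if (m$normalized != "raw") err_state("coarsen raw matrices, then balance")
  nc <- m$n_bins %/% factor
  if (nc < 2L) err_param("coarsening leaves fewer than 2 bins")
  grp <- rep(seq_len(nc), each = factor)
  keep <- seq_len(nc * factor)
  a <- rowsum(m$counts[keep, keep, drop = FALSE], grp)
  a <- t(rowsum(t(a), grp))
  contact_matrix(a, m$chrom, m$bin_size * factor)
}

#' Knight-Ruiz balancing of a raw contact matrix
#'
#' Balances a symmetric contact matrix so every retained row has equal total
#' visibility, via symmetric alternating (Sinkhorn-style) scaling: the
#' returned matrix is `B[i,j] = v[i] v[j] C[i,j]` with each unmasked row of B
#' summing to the mean unmasked raw row sum, to within `tol` (relative).
#' Rows with zero total, plus rows whose total falls below the
#' `mask_percentile` quantile of nonzero row sums, are masked first - the
#' standard guard against unmappable bins that stall the balancing.
#'
#' @param m raw `contact_matrix`.
#' @param tol relative row-sum tolerance (default 1e-8).
#' @param max_iter iteration cap (default 3000).
#' @param mask_percentile quantile of nonzero row sums below which rows are
#'   masked (default 0.01).
#' @return `contact_matrix` with `normalized = "kr"`, balancing vector stored
#'   (`NA` at masked bins), masked rows/columns left at zero.
#' @export
kr_balance <- function(m, tol = 1e-8, max_iter = 3000L, mask_percentile = 0.01) {
  if (m$normalized != "raw") err_state("kr_balance expects a raw matrix")
  rs <- rowSums(m$counts)
  masked <- rs == 0
  if (any(!masked) && mask_percentile > 0) {
    # inverse-ECDF quantile so that small matrices never lose their minimum row
    thr <- stats::quantile(rs[!masked], mask_percentile, type = 1, names = FALSE)
    masked <- masked | rs < thr
  }
  keep <- which(!masked)
  if (length(keep) < 2L)
    err_degenerate("fewer than 2 unmasked bins; cannot balance")
  A <- m$counts[keep, keep, drop = FALSE]
  target <- mean(rowSums(A))
  v <- rep(1, length(keep))
  res <- Inf
  for (it in seq_len(max_iter)) {
    r <- v * as.vector(A %*% v)          # current row sums of D_v A D_v
    if (any(r <= 0))
      err_degenerate("balancing produced a zero row; mask more bins")
    res <- max(abs(r / target - 1))
    if (res <= tol) break
    v <- v * sqrt(target / r)
  }
  if (res > tol)
    err_convergence(sprintf(
      "KR balancing did not converge in %d iterations (residual %.3g > tol %.3g)",
      max_iter, res, tol), residual = res)
  bal <- matrix(0, m$n_bins, m$n_bins)
  bal[keep, keep] <- A * outer(v, v)
  w <- rep(NA_real_, m$n_bins)
  w[keep] <- v
  contact_matrix(bal, m$chrom, m$bin_size, normalized = "kr",
                 balancing = w, masked = masked)
}

#' Observed/expected (distance) normalisation
#'
#' Divides every entry of a balanced matrix by the mean of all unmasked
#' entries at the same genomic distance (diagonal offset) on that chromosome,
#' removing the power-law distance decay. Offsets whose mean is zero yield
#' zero entries.
#'
#' @param m `contact_matrix` with `normalized = "kr"`.
#' @return `contact_matrix` with `normalized = "oe"`.
#' @export
distance_normalize <- function(m) {
  if (m$normalized != "kr")
    err_state("distance_normalize expects a KR-balanced matrix")
  n <- m$n_bins
  keep <- !m$masked
  off <- abs(.row(c(n, n)) - .col(c(n, n)))
  ok <- outer(keep, keep, "&")
  # per-offset mean over unmasked entries
  sums <- rowsum(m$counts[ok], off[ok])
  cnts <- rowsum(rep(1, sum(ok)), off[ok])
  mu <- rep(0, n)                       # offsets 0..n-1
  mu[as.integer(rownames(sums)) + 1L] <- sums / cnts
  denom <- mu[off + 1L]
  oe <- ifelse(denom > 0, m$counts / denom, 0)
  oe[!ok] <- 0
  dim(oe) <- c(n, n)
  contact_matrix(oe, m$chrom, m$bin_size, normalized = "oe",
                 balancing = m$balancing, masked = m$masked)
}
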