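#' TopDom-style binSignal
#'
#' For each bin i, the mean balanced contact frequency between the window of
#' `w` bins ending at i and the window of `w` bins starting at i + 1 (the
#' cross-window straddling the putative boundary after bin i). Windows are
#' clipped at chromosome ends; masked bins are excluded from the mean; bins
#' whose cross-window is empty are flagged `NA`.
#'
#' @param m `contact_matrix` with `normalized = "kr"`.
#' @param w window half-width in bins (>= 1, < n_bins / 2).
#' @return numeric binSignal vector (length `n_bins`, `NA` where undefined).
#' @export
bin_signal <- function(m, w = 5L) {
  if (m$normalized != "kr") err_state("bin_signal expects a KR-balanced matrix")
  w <- as.integer(w)
  n <- m$n_bins
  if (w < 1L) err_param("w must be >= 1")
  if (w >= n / 2) err_param("w must be smaller than half the chromosome")
  keep <- !m$masked
  out <- rep(NA_real_, n)
  for (i in seq_len(n - 1L)) {
    u <- max(1L, i - w + 1L):i
    v <- (i + 1L):min(n, i + w)
    u <- u[keep[u]]; v <- v[keep[v]]
    if (!length(u) || !length(v)) next
    out[i] <- mean(m$counts[u, v, drop = FALSE])
  }
  out
}

#' Running-mean smoothing of the binSignal
#'
#' Centered running mean of odd width `span`, shrunk at the ends; `NA`
#' (flagged) input bins stay `NA`, and `NA`s inside a window are skipped.
#'
#' @param binsignal numeric vector.
#' @param span odd window width (>= 1).
#' @return smoothed vector.
#' @export
smooth_signal <- function(binsignal, span = 3L) {
  span <- as.integer(span)
  if (span < 1L || span %% 2L == 0L) err_param("span must be odd and >= 1")
  if (span == 1L) return(binsignal)
  h <- span %/% 2L
  n <- length(binsignal)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(binsignal[i])) next
    win <- binsignal[max(1L, i - h):min(n, i + h)]
    out[i] <- mean(win, na.rm = TRUE)
  }
  out
}

#' Call TAD boundaries as prominent local minima
#'
#' A boundary sits at bin i when the smoothed binSignal at i is the minimum
#' of its +-w neighbourhood (leftmost bin of a tied plateau) and its
#' prominence - the smaller of the left and right neighbourhood maxima minus
#' the value at i - reaches `min_depth`. Domains are the intervals between
#' consecutive boundaries and the ends of the unmasked extent; a boundary
#' bin closes the domain on its left.
#'
#' @param smoothed smoothed binSignal from [smooth_signal()].
#' @param w neighbourhood half-width in bins (use the binSignal window).
#' @param min_depth prominence threshold; default 0.1 of the signal scale
#'   (the 10-90 percentile span of the smoothed signal).
#' @param binsignal optional raw binSignal stored alongside (defaults to
#'   `smoothed`).
#' @param chrom,bin_size grid metadata for the returned set.
#' @return `tad_set` object.
#' @export
call_boundaries <- function(smoothed, w = 5L, min_depth = NULL,
                            binsignal = smoothed, chrom = "chr",
                            bin_size = 1) {
  n <- length(smoothed)
  ok <- which(!is.na(smoothed))
  if (!length(ok)) err_degenerate("binSignal entirely undefined")
  if (is.null(min_depth)) {
    q <- stats::quantile(smoothed, c(0.1, 0.9), na.rm = TRUE, names = FALSE)
    min_depth <- 0.1 * (q[2] - q[1])
  }
  bnd <- integer(0)
  for (i in ok) {
    if (i <= min(ok) || i >= max(ok)) next
    left <- smoothed[max(1L, i - w):(i - 1L)]
    right <- smoothed[(i + 1L):min(n, i + w)]
    left <- left[!is.na(left)]; right <- right[!is.na(right)]
    if (!length(left) || !length(right)) next
    v <- smoothed[i]
    if (v > min(c(left, right))) next
    # leftmost bin of a tied plateau: the left neighbour must lie above
    if (!is.na(smoothed[i - 1L]) && smoothed[i - 1L] <= v) next
    prom <- min(max(left), max(right)) - v
    if (prom >= min_depth) bnd <- c(bnd, i)
  }
  ext <- range(ok)
  brk <- c(ext[1] - 1L, bnd[bnd >= ext[1] & bnd < ext[2]], ext[2])
  domains <- data.frame(start = head(brk, -1) + 1L, end = brk[-1])
  structure(
    list(chrom = chrom, bin_size = bin_size, w = w,
         binsignal = binsignal, smoothed = smoothed,
         boundaries = bnd, domains = domains, strength = NULL,
         min_depth = min_depth),
    class = "tad_set"
  )
}

#' Call TADs from a balanced matrix
#'
#' Convenience wrapper: binSignal, smoothing, boundary calling and boundary
#' strength in one step.
#'
#' @param m `contact_matrix` with `normalized = "kr"`.
#' @param w binSignal window in bins (default 5, the TopDom default).
#' @param span smoothing span (odd, default 3).
#' @param min_depth prominence threshold (default: 0.1 of signal scale).
#' @return `tad_set` with boundary strengths filled.
#' @export
call_tads <- function(m, w = 5L, span = 3L, min_depth = NULL) {
  bs <- bin_signal(m, w)
  sm <- smooth_signal(bs, span)
  tads <- call_boundaries(sm, w = w, min_depth = min_depth, binsignal = bs,
                          chrom = m$chrom, bin_size = m$bin_size)
  boundary_strength(tads)
}

#' @export
print.tad_set <- function(x, ...) {
  st <- tad_stats(x)
  cat(sprintf("<tad_set> %s: %d domains (mean %.2f Mb), %d boundaries, w = %d\n",
              x$chrom, st[["n_domains"]], st[["mean_size_mb"]],
              length(x$boundaries), x$w))
  invisible(x)
}

#' Boundary strength (insulation depth)
#'
#' Strength of boundary b is the mean binSignal over the interiors of its
#' two flanking domains minus the binSignal at b - the depth of the
#' insulation dip; larger means stronger insulation. Domain interiors
#' exclude the domains' edge bins where the domain is long enough.
#'
#' @param tads `tad_set`.
#' @return the `tad_set` with `$strength` filled (named by boundary bin).
#' @export
boundary_strength <- function(tads) {
  bs <- tads$binsignal
  strength <- numeric(0)
  for (b in tads$boundaries) {
    di <- which(tads$domains$start <= b & tads$domains$end >= b)
    flank <- integer(0)
    for (d in c(di, di + 1L)) {
      if (d < 1L || d > nrow(tads$domains)) next
      s <- tads$domains$start[d]; e <- tads$domains$end[d]
      interior <- if (e - s >= 2L) (s + 1L):(e - 1L) else s:e
      flank <- c(flank, interior)
    }
    flank <- setdiff(flank, tads$boundaries)
    val <- mean(bs[flank], na.rm = TRUE) - bs[b]
    strength[as.character(b)] <- val
  }
  tads$strength <- strength
  tads
}

#' Compare TAD boundaries between two conditions
#'
#' Boundaries are matched greedily by nearest position within `match_slack`
#' bins; each matched pair is classified by the relative strength change
#' `(s2 - s1)/s1`: below `-change_threshold` is `weaker`, above
#' `+change_threshold` is `stronger`, otherwise `unchanged`. Unmatched
#' boundaries are reported as lost (condition 1 only) or gained (condition 2
#' only).
#'
#' @param t1,t2 `tad_set`s on the same grid with strengths filled.
#' @param match_slack maximum matching distance in bins (default 2).
#' @param change_threshold relative-change threshold (default 0.1).
#' @return list with `matched` (data.frame position1, position2, s1, s2,
#'   class), `lost`, `gained`, and `counts`.
#' @export
compare_boundaries <- function(t1, t2, match_slack = 2L,
                               change_threshold = 0.1) {
  if (!identical(t1$chrom, t2$chrom) || t1$bin_size != t2$bin_size)
    err_align("TAD sets are not on the same chromosome grid")
  if (match_slack < 0) err_param("match_slack must be >= 0")
  b1 <- t1$boundaries; b2 <- t2$boundaries
  pairs <- expand.grid(k1 = seq_along(b1), k2 = seq_along(b2))
  if (nrow(pairs)) {
    pairs$d <- abs(b1[pairs$k1] - b2[pairs$k2])
    pairs <- pairs[pairs$d <= match_slack, , drop = FALSE]
    pairs <- pairs[order(pairs$d, pairs$k1), , drop = FALSE]
  }
  used1 <- logical(length(b1)); used2 <- logical(length(b2))
  m1 <- integer(0); m2 <- integer(0)
  for (r in seq_len(nrow(pairs))) {
    k1 <- pairs$k1[r]; k2 <- pairs$k2[r]
    if (used1[k1] || used2[k2]) next
    used1[k1] <- TRUE; used2[k2] <- TRUE
    m1 <- c(m1, k1); m2 <- c(m2, k2)
  }
  s1 <- unname(t1$strength[as.character(b1[m1])])
  s2 <- unname(t2$strength[as.character(b2[m2])])
  rel <- (s2 - s1) / pmax(abs(s1), 1e-12)
  cls <- ifelse(rel < -change_threshold, "weaker",
                ifelse(rel > change_threshold, "stronger", "unchanged"))
  matched <- data.frame(position1 = b1[m1], position2 = b2[m2],
                        s1 = s1, s2 = s2, class = cls)
  matched <- matched[order(matched$position1), , drop = FALSE]
  rownames(matched) <- NULL
  lost <- b1[!used1]; gained <- b2[!used2]
  list(matched = matched, lost = lost, gained = gained,
       counts = c(stronger = sum(cls == "stronger"),
                  unchanged = sum(cls == "unchanged"),
                  weaker = sum(cls == "weaker"),
                  lost = length(lost), gained = length(gained)))
}

#' Domain count and mean size
#'
#' @param tads `tad_set`.
#' @return named numeric: `n_domains` and `mean_size_mb` (megabases).
#' @export
tad_stats <- function(tads) {
  len <- tads$domains$end - tads$domains$start + 1L
  c(n_domains = nrow(tads$domains),
    mean_size_mb = mean(len) * tads$bin_size / 1e6)
}

#' Write TAD domains / boundaries as BED
#'
#' Domains: chrom, start, end, domain_id. Boundaries: chrom, start, end,
#' name, strength in the score column.
#'
#' @param tads `tad_set`.
#' @param path output file.
#' @export
write_tads_bed <- function(tads, path) {
  d <- tads$domains
  utils::write.table(
    data.frame(tads$chrom, (d$start - 1L) * tads$bin_size,
               d$end * tads$bin_size,
               sprintf("domain_%03d", seq_len(nrow(d)))),
    path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tads_bed
#' @export
write_boundaries_bed <- function(tads, path) {
  b <- tads$boundaries
  utils::write.table(
    data.frame(tads$chrom, (b - 1L) * tads$bin_size, b * tads$bin_size,
               sprintf("boundary_%03d", seq_along(b)),
               format(unname(tads$strength[as.character(b)]), digits = 6)),
    path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
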