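#' First principal component of the O/E correlation matrix
#'
#' The A/B compartment signal: Pearson correlation matrix of the
#' observed/expected map over unmasked bins, then the eigenvector of its
#' largest eigenvalue (unit norm). The sign is arbitrary at this stage -
#' orientation against histone marks is a separate step. Bins whose O/E row
#' has zero variance are added to the mask.
#'
#' @param m `contact_matrix` with `normalized = "oe"`.
#' @return numeric vector of length `n_bins` with `NA` at masked bins;
#'   attributes `chrom` and `bin_size` carry the grid.
#' @export
correlation_pc1 <- function(m) {
  if (m$normalized != "oe")
    err_state("correlation_pc1 expects an O/E-normalized matrix")
  keep <- which(!m$masked)
  sub <- m$counts[keep, keep, drop = FALSE]
  sdv <- apply(sub, 2, stats::sd)
  keep <- keep[sdv > 0]
  if (length(keep) < 10L)
    err_degenerate("fewer than 10 unmasked, non-degenerate bins for PCA")
  sub <- m$counts[keep, keep, drop = FALSE]
  C <- stats::cor(sub)
  ev <- eigen(C, symmetric = TRUE)
  v <- ev$vectors[, 1]
  v <- v / sqrt(sum(v^2))
  out <- rep(NA_real_, m$n_bins)
  out[keep] <- v
  attr(out, "chrom") <- m$chrom
  attr(out, "bin_size") <- m$bin_size
  out
}

#' Orient PC1 by histone marks and label compartments
#'
#' The raw eigenvector's sign is arbitrary, so it is anchored to chromatin
#' state: with `s` the sum of Pearson correlations of PC1 with the active
#' marks minus the sum with the repressive marks, the vector is flipped when
#' `s < 0`. Bins with oriented PC1 > 0 become compartment A, < 0 become B;
#' exact zeros take the label of the nearest nonzero bin (ties towards B).
#' When `|s|` falls below `threshold` the orientation is ambiguous and an
#' error asks for a manual sign choice rather than guessing silently.
#'
#' @param pc1 unoriented PC1 from [correlation_pc1()].
#' @param active_tracks list of `bin_track`s for active marks
#'   (H3K4me1, H3K27ac).
#' @param inactive_tracks list of `bin_track`s for repressive marks
#'   (H3K9me3, H3K27me3).
#' @param threshold ambiguity threshold on `|s|` (default 0.05).
#' @return `compartment_profile` object.
#' @export
orient_and_label <- function(pc1, active_tracks, inactive_tracks,
                             threshold = 0.05) {
  chrom <- attr(pc1, "chrom"); bin_size <- attr(pc1, "bin_size")
  n <- length(pc1)
  ok <- !is.na(pc1)
  corr_with <- function(tr) {
    if (length(tr$values) != n)
      err_align("track length does not match the PC1 grid")
    stats::cor(pc1[ok], tr$values[ok])
  }
  s <- sum(vapply(active_tracks, corr_with, 1)) -
    sum(vapply(inactive_tracks, corr_with, 1))
  if (abs(s) < threshold)
    err_ambiguous(sprintf(
      paste0("orientation statistic |s| = %.3g below threshold %.3g; ",
             "choose the PC1 sign manually for this chromosome"),
      abs(s), threshold), s = s)
  v <- as.numeric(pc1)
  if (s < 0) v <- -v
  lab <- rep(NA_character_, n)
  lab[ok & v > 0] <- "A"
  lab[ok & v < 0] <- "B"
  zero <- which(ok & v == 0)
  for (z in zero) {
    nz <- which(ok & v != 0)
    if (!length(nz)) { lab[z] <- "B"; next }
    d <- abs(nz - z)
    near <- nz[d == min(d)]
    lab[z] <- if (length(near) > 1L &&
                  length(unique(lab[near])) > 1L) "B" else lab[near[1]]
  }
  structure(
    list(chrom = chrom, bin_size = bin_size, pc1 = v, label = lab,
         degree = NULL, masked = !ok, orientation_s = s),
    class = "compartment_profile"
  )
}

#' @export
print.compartment_profile <- function(x, ...) {
  nA <- sum(x$label == "A", na.rm = TRUE)
  nB <- sum(x$label == "B", na.rm = TRUE)
  cat(sprintf("<compartment_profile> %s: %d bins @ %s bp (A: %d, B: %d, masked: %d)\n",
              x$chrom, length(x$pc1), format(x$bin_size, big.mark = ","),
              nA, nB, sum(x$masked)))
  if (!is.null(x$degree))
    cat(sprintf("  compartment degree in [%.2f, %.2f]\n",
                min(x$degree, na.rm = TRUE), max(x$degree, na.rm = TRUE)))
  invisible(x)
}

#' Compartment degree from oriented PC1
#'
#' A continuous per-bin index of compartment strength in [-1, 1], used as the
#' radial-positioning signal for 3D modelling: the oriented PC1 rescaled by
#' its maximum absolute entry, so the most A-like bin has degree +1 and the
#' most B-like bin approaches -1.
#'
#' @param m the O/E `contact_matrix` the profile came from (grid check).
#' @param profile `compartment_profile` from [orient_and_label()].
#' @return the profile with `$degree` filled.
#' @export
compartment_degree <- function(m, profile) {
  if (!identical(m$chrom, profile$chrom) ||
      m$bin_size != profile$bin_size)
    err_align("matrix and profile grids differ")
  v <- profile$pc1
  if (all(is.na(v))) err_degenerate("all bins masked; no degree defined")
  mx <- max(abs(v), na.rm = TRUE)
  if (mx == 0) err_degenerate("PC1 identically zero; no degree defined")
  profile$degree <- v / mx
  profile
}

#' Classify compartment switches between two conditions
#'
#' Per-bin classes `stable A`, `stable B`, `A->B`, `B->A` (masked when either
#' profile is masked), with summary percentages over unmasked bins. The
#' switched fraction is the sum of the two switching classes.
#'
#' @param p1,p2 `compartment_profile`s on the identical grid.
#' @return `switch_report` object.
#' @export
classify_switches <- function(p1, p2) {
  if (!identical(p1$chrom, p2$chrom) || p1$bin_size != p2$bin_size ||
      length(p1$label) != length(p2$label))
    err_align("profiles are not on the same chromosome grid")
  n <- length(p1$label)
  cls <- rep(NA_character_, n)
  ok <- !p1$masked & !p2$masked
  for (k in which(ok)) {
    a <- p1$label[k]; b <- p2$label[k]
    cls[k] <- if (a == b) paste("stable", a) else paste0(a, "->", b)
  }
  lv <- c("stable A", "stable B", "A->B", "B->A")
  tab <- table(factor(cls[ok], levels = lv))
  pct <- if (sum(ok)) 100 * as.numeric(tab) / sum(ok) else rep(NA_real_, 4)
  names(pct) <- lv
  structure(
    list(chrom = p1$chrom, bin_size = p1$bin_size, class = cls,
         masked = !ok, percentages = pct,
         switched_percent = pct[["A->B"]] + pct[["B->A"]]),
    class = "switch_report"
  )
}

#' @export
print.switch_report <- function(x, ...) {
  cat(sprintf("<switch_report> %s: %d bins, %.1f%% switched\n",
              x$chrom, length(x$class), x$switched_percent))
  p <- x$percentages
  cat(sprintf("  stable A %.1f%% | stable B %.1f%% | A->B %.1f%% | B->A %.1f%%\n",
              p[["stable A"]], p[["stable B"]], p[["A->B"]], p[["B->A"]]))
  invisible(x)
}

#' Aggregate switch reports over chromosomes
#'
#' Pools the per-bin classes of several chromosomes' switch reports into
#' genome-wide percentages.
#'
#' @param reports list of `switch_report`s.
#' @return named numeric: the four class percentages plus `switched_percent`.
#' @export
switch_summary <- function(reports) {
  lv <- c("stable A", "stable B", "A->B", "B->A")
  cls <- unlist(lapply(reports, function(r) r$class[!r$masked]))
  tab <- table(factor(cls, levels = lv))
  pct <- 100 * as.numeric(tab) / length(cls)
  names(pct) <- lv
  c(pct, switched_percent = pct[["A->B"]] + pct[["B->A"]])
}

#' Write a compartment profile as BED-like TSV
#'
#' Columns: chrom, start, end, pc1, label, degree; masked rows carry "NA".
#'
#' @param profile `compartment_profile`.
#' @param path output file.
#' @export
write_profile_bed <- function(profile, path) {
  n <- length(profile$pc1)
  deg <- profile$degree %||% rep(NA_real_, n)
  utils::write.table(
    data.frame(profile$chrom, (seq_len(n) - 1L) * profile$bin_size,
               seq_len(n) * profile$bin_size,
               ifelse(is.na(profile$pc1), "NA", format(profile$pc1, digits = 6)),
               ifelse(is.na(profile$label), "NA", profile$label),
               ifelse(is.na(deg), "NA", format(deg, digits = 6))),
    path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a switch report as TSV plus JSON summary
#' @param report `switch_report`.
#' @param path TSV path; the JSON summary goes to `paste0(path, ".json")`.
#' @export
write_switch_report <- function(report, path) {
  n <- length(report$class)
  utils::write.table(
    data.frame(report$chrom, (seq_len(n) - 1L) * report$bin_size,
               seq_len(n) * report$bin_size,
               ifelse(is.na(report$class), "NA", report$class)),
    path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  jsonlite::write_json(as.list(c(report$percentages,
                                 switched_percent = report$switched_percent)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
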