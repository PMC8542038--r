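#' Plant a two-condition genome architecture
#'
#' Builds the ground truth for a synthetic two-condition Hi-C experiment:
#' alternating A/B compartment blocks, TAD boundaries, focal loop pixels, and
#' the condition-2 perturbations observed when a chromatin remodeller is
#' lost - compartment flips, TAD-boundary weakening (with a fraction of the
#' weakened boundaries merging away entirely), and loop loss. The truth is
#' planted on one multi-resolution ladder: compartment labels live on a grid
#' of `comp_factor` fine bins, TAD boundaries on a grid of `tad_factor` fine
#' bins, loops on the fine grid itself, mirroring the usual 500-kb / 50-kb /
#' 25-kb analysis ladder from a single library.
#'
#' @param spec `genome_spec` at the fine (loop) resolution; each chromosome's
#'   bin count must be divisible by `comp_factor`.
#' @param flip_fraction fraction of compartment bins whose label flips in
#'   condition 2 (rounded to the nearest count, recorded exactly).
#' @param weaken_fraction fraction of TAD boundaries weakened in condition 2.
#' @param loop_loss_fraction fraction of loops absent from condition 2.
#' @param seed integer seed (defaults to the spec's seed).
#' @param comp_factor fine bins per compartment bin (integer multiple of
#'   `tad_factor`).
#' @param tad_factor fine bins per TAD bin.
#' @param mean_comp_block mean compartment block length in compartment bins.
#' @param tad_size target TAD length in TAD bins (boundary spacing, jittered).
#' @param alpha power-law distance-decay exponent (> 0).
#' @param rho same-compartment contact enrichment (> 1).
#' @param tau within-TAD contact enrichment (> 1).
#' @param lambda_loop loop-pixel contact enrichment (> 1).
#' @param depth expected contact count at unit bin distance with no
#'   architecture multipliers (the sequencing-depth scale).
#' @param weaken_level fraction of the TAD enrichment leaking across a
#'   weakened boundary in condition 2 (0 = intact insulation, 1 = full merge).
#' @param merge_fraction fraction of the weakened set whose boundary is
#'   removed outright in condition 2 (TAD merging).
#' @return `architecture_truth` object recording both conditions' labels,
#'   boundaries and loops, the model parameters, and the planted difference
#'   sets (`$flips`, `$weakened` with its `$merged` subset, `$lost_loops`).
#' @export
plant_architecture <- function(spec, flip_fraction = 0, weaken_fraction = 0,
                               loop_loss_fraction = 0, seed = spec$seed,
                               comp_factor = 1L, tad_factor = 1L,
                               mean_comp_block = 5L, tad_size = 20L,
                               alpha = 1.0, rho = 1.4, tau = 2.0,
                               lambda_loop = 3.0, depth = 1e6,
                               weaken_level = 0.5, merge_fraction = 0.15) {
  for (f in c(flip_fraction, weaken_fraction, loop_loss_fraction))
    if (f < 0 || f > 1) err_param("fractions must lie in [0, 1]")
  if (alpha <= 0 || rho < 1 || tau < 1 || lambda_loop < 1 || depth < 0)
    err_param("require alpha > 0, rho >= 1, tau >= 1, lambda_loop >= 1, depth >= 0")
  comp_factor <- as.integer(comp_factor); tad_factor <- as.integer(tad_factor)
  if (comp_factor %% tad_factor != 0L)
    err_param("comp_factor must be an integer multiple of tad_factor")
  if (any(spec$chromosomes %% comp_factor != 0L))
    err_param("chromosome bin counts must be divisible by comp_factor")

  set.seed(seed)
  chroms <- list()
  for (nm in names(spec$chromosomes)) {
    n_fine <- spec$chromosomes[[nm]]
    n_comp <- n_fine %/% comp_factor
    n_tad  <- n_fine %/% tad_factor

    # alternating compartment blocks, lengths ~ block-size +- 40%
    labels <- character(0)
    cur <- sample(c("A", "B"), 1)
    lo <- max(2L, floor(0.6 * mean_comp_block))
    hi <- max(lo, ceiling(1.4 * mean_comp_block))
    while (length(labels) < n_comp) {
      labels <- c(labels, rep(cur, sample(lo:hi, 1)))
      cur <- if (cur == "A") "B" else "A"
    }
    labels <- labels[seq_len(n_comp)]

    # jittered boundary ladder on the TAD grid, interior only
    bnd <- integer(0)
    if (n_tad > 2L * tad_size) {
      pos <- seq(tad_size, n_tad - tad_size %/% 2L, by = tad_size)
      pos <- pos + sample(-2:2, length(pos), replace = TRUE)
      pos <- pos[pos >= 4L & pos <= n_tad - 4L]
      pos <- sort(unique(pos))
      if (length(pos) > 1L) pos <- pos[c(TRUE, diff(pos) >= 4L)]
      bnd <- as.integer(pos)
    }

    # focal loops on the fine grid, clear of edges and the diagonal so the
    # donut caller can reach them; no two loops within Chebyshev distance 3
    n_loops <- max(3L, round(n_fine / 25))
    max_sep <- min(60L, n_fine %/% 3L)
    li <- integer(0); lj <- integer(0)
    tries <- 0L
    while (length(li) < n_loops && tries < 50L * n_loops) {
      tries <- tries + 1L
      sep <- sample(12:max_sep, 1)
      if (n_fine - 6L - sep < 7L) next
      i <- sample(7:(n_fine - 6L - sep), 1)
      j <- i + sep
      if (length(li) &&
          any(pmax(abs(li - i), abs(lj - j)) <= 3L)) next
      li <- c(li, i); lj <- c(lj, j)
    }
    o <- order(li, lj)
    loops <- data.frame(i = li[o], j = lj[o],
                        strength = rep(lambda_loop, length(li)))

    chroms[[nm]] <- list(n_fine = n_fine, n_comp = n_comp, n_tad = n_tad,
                         labels1 = labels, labels2 = labels,
                         boundaries1 = bnd, boundaries2 = bnd,
                         weaken_levels = numeric(0),
                         loops1 = loops, loops2 = loops)
  }

  # --- condition-2 perturbations, counted genome-wide ---
  comp_index <- do.call(rbind, lapply(names(chroms), function(nm)
    data.frame(chrom = nm, bin = seq_len(chroms[[nm]]$n_comp))))
  n_flip <- round(flip_fraction * nrow(comp_index))
  flips <- comp_index[sample.int(nrow(comp_index), n_flip), , drop = FALSE]
  rownames(flips) <- NULL
  for (k in seq_len(nrow(flips))) {
    nm <- flips$chrom[k]; b <- flips$bin[k]
    chroms[[nm]]$labels2[b] <-
      if (chroms[[nm]]$labels2[b] == "A") "B" else "A"
  }

  bnd_index <- do.call(rbind, lapply(names(chroms), function(nm) {
    b <- chroms[[nm]]$boundaries1
    if (length(b)) data.frame(chrom = nm, boundary = b) else NULL
  }))
  weakened <- merged <- NULL
  if (!is.null(bnd_index) && nrow(bnd_index)) {
    n_w <- round(weaken_fraction * nrow(bnd_index))
    weakened <- bnd_index[sample.int(nrow(bnd_index), n_w), , drop = FALSE]
    rownames(weakened) <- NULL
    n_m <- round(merge_fraction * n_w)
    msel <- if (n_m > 0) sample.int(n_w, n_m) else integer(0)
    weakened$level <- rep(weaken_level, n_w)
    if (length(msel)) weakened$level[msel] <- 1.0
    merged <- weakened[msel, c("chrom", "boundary"), drop = FALSE]
    for (k in seq_len(nrow(weakened))) {
      nm <- weakened$chrom[k]; b <- weakened$boundary[k]
      if (weakened$level[k] >= 1) {
        chroms[[nm]]$boundaries2 <-
          setdiff(chroms[[nm]]$boundaries2, b)
      } else {
        wl <- chroms[[nm]]$weaken_levels
        wl[as.character(b)] <- weakened$level[k]
        chroms[[nm]]$weaken_levels <- wl
      }
    }
  } else {
    weakened <- data.frame(chrom = character(0), boundary = integer(0),
                           level = numeric(0))
    merged <- weakened[, 1:2]
  }

  loop_index <- do.call(rbind, lapply(names(chroms), function(nm) {
    l <- chroms[[nm]]$loops1
    if (nrow(l)) data.frame(chrom = nm, row = seq_len(nrow(l))) else NULL
  }))
  lost <- data.frame(chrom = character(0), i = integer(0), j = integer(0))
  if (!is.null(loop_index) && nrow(loop_index)) {
    n_l <- round(loop_loss_fraction * nrow(loop_index))
    sel <- loop_index[sample.int(nrow(loop_index), n_l), , drop = FALSE]
    for (nm in unique(sel$chrom)) {
      rows <- sel$row[sel$chrom == nm]
      l1 <- chroms[[nm]]$loops1
      lost <- rbind(lost, data.frame(chrom = nm, i = l1$i[rows], j = l1$j[rows]))
      chroms[[nm]]$loops2 <- l1[-rows, , drop = FALSE]
    }
    rownames(lost) <- NULL
  }

  structure(
    list(spec = spec, comp_factor = comp_factor, tad_factor = tad_factor,
         params = list(alpha = alpha, rho = rho, tau = tau,
                       lambda_loop = lambda_loop, depth = depth,
                       weaken_level = weaken_level,
                       merge_fraction = merge_fraction),
         chroms = chroms, flips = flips, weakened = weakened,
         merged = merged, lost_loops = lost, seed = as.integer(seed)),
    class = "architecture_truth"
  )
}

#' @export
print.architecture_truth <- function(x, ...) {
  nb <- sum(vapply(x$chroms, function(ch) length(ch$boundaries1), 1L))
  nl <- sum(vapply(x$chroms, function(ch) nrow(ch$loops1), 1L))
  cat(sprintf(paste0(
    "<architecture_truth> %d chromosome(s), fine bin %s bp ",
    "(comp x%d, tad x%d)\n",
    "  planted: %d compartment flips, %d weakened boundaries ",
    "(%d merged), %d lost loops\n",
    "  of %d compartment bins, %d boundaries, %d loops\n"),
    length(x$chroms), format(x$spec$bin_size, big.mark = ","),
    x$comp_factor, x$tad_factor, nrow(x$flips), nrow(x$weakened),
    nrow(x$merged), nrow(x$lost_loops),
    sum(vapply(x$chroms, function(ch) ch$n_comp, 1L)), nb, nl))
  invisible(x)
}

# per-TAD-bin domain id implied by a boundary list (boundary = last bin of
# its left domain)
tad_ids <- function(n_tad, boundaries) {
  ids <- integer(n_tad)
  brk <- c(0L, sort(boundaries), n_tad)
  for (k in seq_len(length(brk) - 1L))
    ids[(brk[k] + 1L):brk[k + 1L]] <- k
  ids
}

# per-fine-bin architecture vectors for one chromosome / condition
fine_architecture <- function(truth, chrom, condition) {
  ch <- truth$chroms[[chrom]]
  if (is.null(ch)) err_domain(sprintf("unknown chromosome '%s'", chrom))
  if (!condition %in% c(1, 2)) err_param("condition must be 1 or 2")
  n <- ch$n_fine
  lab <- if (condition == 1) ch$labels1 else ch$labels2
  bnd <- if (condition == 1) ch$boundaries1 else ch$boundaries2
  loops <- if (condition == 1) ch$loops1 else ch$loops2
  list(
    n = n,
    lab_fine = lab[ceiling(seq_len(n) / truth$comp_factor)],
    tad_fine = tad_ids(ch$n_tad, bnd)[ceiling(seq_len(n) / truth$tad_factor)],
    boundaries = bnd, loops = loops,
    weaken = if (condition == 2) ch$weaken_levels else numeric(0)
  )
}

#' Expected contact count under the generative model
#'
#' The generative model is a power-law distance decay modulated by
#' multiplicative architecture terms:
#' `E[i,j] = depth * max(|i-j|, 1)^(-alpha) * m(i,j)`, where `m` multiplies
#' `rho` when the bins share a compartment label, `tau` when they share a
#' TAD, `lambda_loop` when (i, j) is a planted loop pixel, and
#' `1 + w (tau - 1)` when the pair spans a boundary weakened to residual
#' leak `w` in condition 2. Intra-chromosomal only.
#'
#' @param truth `architecture_truth`.
#' @param i,j fine bin indices (1-based).
#' @param chrom chromosome of bin i.
#' @param chrom_j chromosome of bin j (must equal `chrom`).
#' @param condition 1 or 2.
#' @return expected count (non-negative scalar).
#' @export
expected_contact <- function(truth, i, j, chrom, chrom_j = chrom,
                             condition = 1) {
  if (!identical(chrom, chrom_j))
    err_domain("model is intra-chromosomal: cross-chromosome pair requested")
  arch <- fine_architecture(truth, chrom, condition)
  if (i < 1 || j < 1 || i > arch$n || j > arch$n)
    err_domain("bin index out of range")
  p <- truth$params
  m <- 1
  if (arch$lab_fine[i] == arch$lab_fine[j]) m <- m * p$rho
  ti <- arch$tad_fine[i]; tj <- arch$tad_fine[j]
  if (ti == tj) {
    m <- m * p$tau
  } else if (abs(ti - tj) == 1 && length(arch$weaken)) {
    b <- sort(arch$boundaries)[min(ti, tj)]
    w <- arch$weaken[as.character(b)]
    if (!is.na(w)) m <- m * (1 + w * (p$tau - 1))
  }
  lo <- min(i, j); hi <- max(i, j)
  if (nrow(arch$loops) && any(arch$loops$i == lo & arch$loops$j == hi)) {
    s <- arch$loops$strength[arch$loops$i == lo & arch$loops$j == hi][1]
    m <- m * s
  }
  p$depth * max(abs(i - j), 1)^(-p$alpha) * m
}

#' Full expected contact matrix for one chromosome
#'
#' Vectorised construction of the `expected_contact` surface over all bin
#' pairs.
#'
#' @inheritParams expected_contact
#' @return n x n numeric matrix of expectations.
#' @export
expected_matrix <- function(truth, chrom, condition = 1) {
  arch <- fine_architecture(truth, chrom, condition)
  p <- truth$params
  n <- arch$n
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  E <- p$depth * pmax(d, 1)^(-p$alpha)
  E <- E * ifelse(outer(arch$lab_fine, arch$lab_fine, "=="), p$rho, 1)
  Mt <- ifelse(outer(arch$tad_fine, arch$tad_fine, "=="), p$tau, 1)
  if (length(arch$weaken)) {
    for (bs in names(arch$weaken)) {
      b <- as.integer(bs)
      lid <- which(sort(arch$boundaries) == b)   # id of the left-side domain
      w <- arch$weaken[[bs]]
      cross <- outer(arch$tad_fine == lid, arch$tad_fine == lid + 1L) |
        outer(arch$tad_fine == lid + 1L, arch$tad_fine == lid)
      Mt[cross] <- 1 + w * (p$tau - 1)
    }
  }
  E <- E * Mt
  if (nrow(arch$loops)) {
    for (k in seq_len(nrow(arch$loops))) {
      i <- arch$loops$i[k]; j <- arch$loops$j[k]; s <- arch$loops$strength[k]
      E[i, j] <- E[i, j] * s
      E[j, i] <- E[j, i] * s
    }
  }
  E
}

#' Sample a Poisson contact map from the planted truth
#'
#' Upper-triangle entries (diagonal included) are drawn independently as
#' `Poisson(E[i,j])` and mirrored, giving one raw symmetric `contact_matrix`
#' per chromosome at the fine resolution.
#'
#' @param truth `architecture_truth`.
#' @param condition 1 or 2.
#' @param seed integer seed; identical seeds give identical matrices.
#' @return named list of raw `contact_matrix`.
#' @export
sample_contact_matrix <- function(truth, condition, seed) {
  if (!condition %in% c(1, 2)) err_param("condition must be 1 or 2")
  set.seed(seed)
  out <- list()
  for (nm in names(truth$chroms)) {
    E <- expected_matrix(truth, nm, condition)
    n <- nrow(E)
    ut <- upper.tri(E, diag = TRUE)
    M <- matrix(0, n, n)
    M[ut] <- stats::rpois(sum(ut), E[ut])
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    out[[nm]] <- contact_matrix(M, nm, truth$spec$bin_size)
  }
  out
}

#' Generate histone-mark tracks at compartment resolution
#'
#' Four bin tracks per chromosome: H3K4me1 and H3K27ac (active, high over A
#' bins), H3K9me3 and H3K27me3 (repressive, high over B bins), with Gaussian
#' noise of standard deviation `mu_high / snr`, following the requested
#' condition's labels.
#'
#' @param truth `architecture_truth`.
#' @param condition 1 or 2.
#' @param snr signal-to-noise ratio (> 0; `Inf` gives noiseless indicators).
#' @param seed integer seed.
#' @param mu_high,mu_low mean signal over enriched / depleted bins.
#' @return named list per chromosome, each a named list of four `bin_track`s.
#' @export
generate_marker_tracks <- function(truth, condition = 1, snr = 5, seed = 1L,
                                   mu_high = 10, mu_low = 2) {
  if (snr <= 0) err_param("snr must be positive")
  set.seed(seed)
  marks <- c(H3K4me1 = "active", H3K27ac = "active",
             H3K9me3 = "inactive", H3K27me3 = "inactive")
  sdv <- if (is.finite(snr)) mu_high / snr else 0
  comp_bs <- truth$spec$bin_size * truth$comp_factor
  out <- list()
  for (nm in names(truth$chroms)) {
    ch <- truth$chroms[[nm]]
    lab <- if (condition == 1) ch$labels1 else ch$labels2
    tr <- list()
    for (mk in names(marks)) {
      base <- if (marks[[mk]] == "active") {
        ifelse(lab == "A", mu_high, mu_low)
      } else {
        ifelse(lab == "A", mu_low, mu_high)
      }
      tr[[mk]] <- bin_track(base + stats::rnorm(length(base), 0, sdv),
                            nm, comp_bs, mk)
    }
    out[[nm]] <- tr
  }
  out
}

#' Generate a gene table coupled to compartment switching
#'
#' Genes are placed uniformly over compartment bins; a gene in an A-to-B bin
#' is down-regulated by `de_effect` in expectation, a B-to-A gene
#' up-regulated, genes in stable bins carry no systematic change (a small
#' `background_de` fraction of them get a planted effect of random sign so
#' that differential expression and switching are not perfectly confounded).
#' Expression is log-normal around the planted effect; `de_flag` records the
#' planted effect's direction.
#'
#' @param truth `architecture_truth`.
#' @param n_genes number of genes (> 0).
#' @param de_effect fold-change multiplier (>= 1) tied to switch direction.
#' @param seed integer seed.
#' @param background_de fraction of stable-bin genes with a planted effect of
#'   random direction.
#' @return data.frame with columns gene, chrom, start, end, fpkm_wt,
#'   fpkm_ko, de_flag, true_class (bp coordinates 0-based half-open).
#' @export
generate_gene_table <- function(truth, n_genes, de_effect, seed = 1L,
                                background_de = 0.05) {
  if (n_genes <= 0) err_param("n_genes must be positive")
  if (de_effect < 1) err_param("de_effect must be >= 1")
  set.seed(seed)
  comp_bs <- truth$spec$bin_size * truth$comp_factor
  sizes <- vapply(truth$chroms, function(ch) ch$n_comp, 1L)
  chrom <- sample(names(sizes), n_genes, replace = TRUE,
                  prob = sizes / sum(sizes))
  bin <- vapply(chrom, function(nm) sample.int(sizes[[nm]], 1), 1L)
  len <- round(stats::runif(n_genes, 2000, 50000))
  mid <- round((bin - 1) * comp_bs + stats::runif(n_genes, 0, comp_bs))
  lims <- sizes[chrom] * comp_bs
  mid <- pmin(pmax(mid, ceiling(len / 2)), lims - ceiling(len / 2) - 1)
  start <- mid - len %/% 2L
  end <- start + len
  bin <- floor(mid / comp_bs) + 1L           # bin of the actual midpoint

  cls <- character(n_genes)
  eff <- rep(1, n_genes)
  for (k in seq_len(n_genes)) {
    ch <- truth$chroms[[chrom[k]]]
    l1 <- ch$labels1[bin[k]]; l2 <- ch$labels2[bin[k]]
    cls[k] <- if (l1 == l2) paste("stable", l1) else paste0(l1, "->", l2)
  }
  eff[cls == "A->B"] <- 1 / de_effect
  eff[cls == "B->A"] <- de_effect
  stable <- which(startsWith(cls, "stable"))
  bg <- stable[stats::runif(length(stable)) < background_de]
  eff[bg] <- de_effect^sample(c(-1, 1), length(bg), replace = TRUE)

  fpkm_wt <- stats::rlnorm(n_genes, log(8), 1)
  fpkm_ko <- fpkm_wt * eff * stats::rlnorm(n_genes, 0, 0.25)
  data.frame(
    gene = sprintf("gene%04d", seq_len(n_genes)),
    chrom = chrom, start = start, end = end,
    fpkm_wt = fpkm_wt, fpkm_ko = fpkm_ko,
    de_flag = ifelse(eff < 1, "down", ifelse(eff > 1, "up", "ns")),
    true_class = cls, row.names = NULL
  )
}

#' Write a bin track as 4-column bedGraph (0-based half-open)
#' @param track `bin_track`.
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  n <- length(track$values)
  utils::write.table(
    data.frame(track$chrom, (seq_len(n) - 1L) * track$bin_size,
               seq_len(n) * track$bin_size,
               format(track$values, trim = TRUE)),
    path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read the gene table TSV
#' @param genes gene table data.frame.
#' @param path file path.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gene_table
#' @export
read_gene_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Serialise the planted truth as JSON
#' @param truth `architecture_truth`.
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  x <- list(
    bin_size = truth$spec$bin_size, comp_factor = truth$comp_factor,
    tad_factor = truth$tad_factor, params = truth$params, seed = truth$seed,
    chromosomes = lapply(truth$chroms, function(ch)
      list(n_fine = ch$n_fine, labels1 = ch$labels1, labels2 = ch$labels2,
           boundaries1 = ch$boundaries1, boundaries2 = ch$boundaries2,
           loops1 = ch$loops1, loops2 = ch$loops2)),
    flips = truth$flips, weakened = truth$weakened,
    lost_loops = truth$lost_loops)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
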