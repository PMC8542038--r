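#' Annotate genes with their compartment-switch class
#'
#' Each gene is assigned to the compartment bin containing its midpoint
#' (the unambiguous rule for genes straddling bin edges) and inherits that
#' bin's switch class from the two-condition report; genes in masked bins
#' are flagged `masked`. Log2 fold changes use a pseudocount to guard
#' against zero expression.
#'
#' @param genes data.frame with columns gene, chrom, start, end (0-based,
#'   half-open bp), fpkm_wt, fpkm_ko and optionally de_flag.
#' @param reports named list of `switch_report`s (one per chromosome).
#' @param pseudocount FPKM pseudocount for log2 fold change (default 0.01).
#' @return the gene table with added columns assigned_bin (1-based), log2fc,
#'   switch_class.
#' @export
annotate_genes <- function(genes, reports, pseudocount = 0.01) {
  if (inherits(reports, "switch_report"))
    reports <- stats::setNames(list(reports), reports$chrom)
  missing <- setdiff(unique(genes$chrom), names(reports))
  if (length(missing))
    err_annotation(sprintf("no switch report for chromosome '%s'", missing[1]))
  bin <- integer(nrow(genes))
  cls <- character(nrow(genes))
  for (k in seq_len(nrow(genes))) {
    rep_k <- reports[[genes$chrom[k]]]
    mid <- (genes$start[k] + genes$end[k]) / 2
    b <- floor(mid / rep_k$bin_size) + 1L
    if (b < 1L || b > length(rep_k$class))
      err_annotation(sprintf("gene %s midpoint outside chromosome grid",
                             genes$gene[k]))
    bin[k] <- b
    cls[k] <- if (rep_k$masked[b]) "masked" else rep_k$class[b]
  }
  genes$assigned_bin <- bin
  genes$log2fc <- log2((genes$fpkm_ko + pseudocount) /
                         (genes$fpkm_wt + pseudocount))
  genes$switch_class <- cls
  genes
}

#' Fold-change distribution by switch class
#'
#' Per switch class: gene count, median, mean and IQR of log2 fold change,
#' plus a two-sided Wilcoxon rank-sum test comparing the A->B and B->A
#' classes. Empty classes are reported with n = 0 and no test.
#'
#' @param genes annotated gene table from [annotate_genes()].
#' @return list with `summary` (data.frame per class) and `test` (list:
#'   name, statistic, p_value; `NULL` when either switching class is empty).
#' @export
fold_change_by_class <- function(genes, ...) {
  if (is.null(genes$switch_class) || is.null(genes$log2fc))
    err_state("gene table must be annotated first")
  lv <- c("stable A", "stable B", "A->B", "B->A")
  rows <- lapply(lv, function(cl) {
    x <- genes$log2fc[genes$switch_class == cl]
    data.frame(class = cl, n = length(x),
               median = if (length(x)) stats::median(x) else NA_real_,
               mean = if (length(x)) mean(x) else NA_real_,
               iqr = if (length(x)) stats::IQR(x) else NA_real_)
  })
  ab <- genes$log2fc[genes$switch_class == "A->B"]
  ba <- genes$log2fc[genes$switch_class == "B->A"]
  test <- NULL
  if (length(ab) && length(ba)) {
    wt <- stats::wilcox.test(ab, ba, alternative = "two.sided", exact = FALSE)
    test <- list(name = "Wilcoxon rank-sum", statistic = unname(wt$statistic),
                 p_value = wt$p.value)
  }
  list(summary = do.call(rbind, rows), test = test)
}

#' Candidate genes modulated by compartment switching
#'
#' The intersection of differential expression and compartment switching
#' with direction concordance: down-regulated genes in A->B bins and
#' up-regulated genes in B->A bins; DE genes in stable compartments are
#' disregarded. DE genes in switched bins with discordant direction are
#' returned separately so that a purely positional overlap is recoverable.
#'
#' @param genes annotated gene table with a `de_flag` column
#'   (`up`/`down`/`ns`).
#' @return list with `candidates`, `discordant` (data.frames) and `venn`
#'   (counts: de_only, switch_only, overlap - the DE x switched-bin Venn
#'   before the concordance filter).
#' @export
candidate_genes <- function(genes) {
  if (is.null(genes$de_flag) || is.null(genes$switch_class))
    err_state("gene table must carry de_flag and switch_class")
  de <- genes$de_flag %in% c("up", "down")
  sw <- genes$switch_class %in% c("A->B", "B->A")
  conc <- (genes$de_flag == "down" & genes$switch_class == "A->B") |
    (genes$de_flag == "up" & genes$switch_class == "B->A")
  list(
    candidates = genes[de & sw & conc, , drop = FALSE],
    discordant = genes[de & sw & !conc, , drop = FALSE],
    venn = c(de_only = sum(de & !sw), switch_only = sum(sw & !de),
             overlap = sum(de & sw))
  )
}

#' Write the integration outputs
#'
#' Annotated genes as TSV; class summary and Venn counts as JSON.
#'
#' @param genes annotated gene table.
#' @param path TSV path; JSON goes to `paste0(path, ".json")`.
#' @export
write_integration <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", row.names = FALSE, quote = FALSE)
  fc <- fold_change_by_class(genes)
  cand <- candidate_genes(genes)
  jsonlite::write_json(
    list(classes = fc$summary, test = fc$test,
         venn = as.list(cand$venn),
         n_candidates = nrow(cand$candidates)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
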