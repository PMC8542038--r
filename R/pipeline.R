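#' Default pipeline configuration
#'
#' A complete, desk-scale configuration for [run_pipeline()]: a small
#' synthetic two-condition genome with planted compartment flips, boundary
#' weakening and loop loss, analysed at a three-level resolution ladder
#' (fine = loop grid; TAD grid = `tad_factor` fine bins; compartment grid =
#' `comp_factor` fine bins). Every analysis default decided by the package
#' (masking percentile, KR tolerance, TopDom window, donut radii, 3D force
#' constants) is spelled out here so a run records its full parameterisation.
#'
#' @param out_dir output directory.
#' @param seed master seed; all stage seeds derive from it.
#' @return named list, a valid `RunConfig`.
#' @export
default_config <- function(out_dir = tempfile("hicarch_run_"), seed = 1L) {
  list(
    out_dir = out_dir, seed = as.integer(seed),
    chromosomes = c(chrA = 160L, chrB = 120L), bin_size = 25000,
    comp_factor = 4L, tad_factor = 2L,
    flip_fraction = 0.121, weaken_fraction = 0.5, loop_loss_fraction = 0.3,
    alpha = 1.0, rho = 1.4, tau = 2.0, lambda_loop = 3.0, depth = 1e6,
    snr = 5, n_genes = 400L, de_effect = 4,
    kr_tol = 1e-8, kr_max_iter = 3000L, mask_percentile = 0.01,
    tad_w = 5L, tad_span = 3L, tad_min_depth = NULL,
    match_slack = 2L, change_threshold = 0.1,
    loop_fdr = 0.1, r_inner = 2L, r_outer = 5L, min_sep = 2L,
    nucleus_R = 10, bond_length = 0.5, k_b = 50, k_r = 5, k_rep = 10,
    n_steps = 1500L, n_restarts = 2L
  )
}

validate_config <- function(config) {
  req <- c("out_dir", "seed", "chromosomes", "bin_size", "comp_factor",
           "tad_factor")
  miss <- setdiff(req, names(config))
  if (length(miss))
    err_param(sprintf("config is missing field '%s'", miss[1]))
  if (config$comp_factor %% config$tad_factor != 0L)
    err_param("the TAD resolution must divide the compartment resolution")
  if (config$tad_factor < 1L || config$comp_factor < config$tad_factor)
    err_param("need comp_factor >= tad_factor >= 1 (fine grid is the loop grid)")
  if (any(config$chromosomes %% config$comp_factor != 0L))
    err_param("chromosome bin counts must be divisible by comp_factor")
  invisible(config)
}

stage_seed <- function(seed, k) (as.integer(seed) * 131L + k * 7919L) %% 2147483629L

#' Run the full two-condition analysis pipeline
#'
#' Executes, per condition: synthetic contact maps from the planted truth,
#' KR balancing, A/B compartment calling (O/E correlation PC1, oriented by
#' the generated histone-mark tracks, with compartment degree), TAD calling
#' at the TAD resolution, loop calling at the fine resolution, and 3D
#' conformation optimisation; then all cross-condition comparisons
#' (compartment switches, boundary classes, loop loss) and the
#' expression-by-switch integration. All outputs land in `config$out_dir`
#' as plain-text files, and a manifest with parameter values and md5
#' checksums of every output is written; identical configs yield identical
#' checksums.
#'
#' @param config list from [default_config()] (possibly modified).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config()) {
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, sprintf(...))
  spec <- genome_spec(config$chromosomes, config$bin_size,
                      seed = config$seed)
  truth <- plant_architecture(
    spec, flip_fraction = config$flip_fraction,
    weaken_fraction = config$weaken_fraction,
    loop_loss_fraction = config$loop_loss_fraction,
    seed = stage_seed(config$seed, 1L),
    comp_factor = config$comp_factor, tad_factor = config$tad_factor,
    alpha = config$alpha, rho = config$rho, tau = config$tau,
    lambda_loop = config$lambda_loop, depth = config$depth)
  write_truth_json(truth, out("truth.json"))

  profiles <- list(); tads <- list(); loops <- list(); confs <- list()
  for (cond in 1:2) {
    mats <- sample_contact_matrix(truth, cond,
                                  seed = stage_seed(config$seed, 10L + cond))
    write_triplets(mats, out("contacts_cond%d.txt", cond))
    tracks <- generate_marker_tracks(truth, condition = cond,
                                     snr = config$snr,
                                     seed = stage_seed(config$seed, 20L + cond))
    pr <- list(); td <- list(); lp <- list()
    for (nm in names(mats)) {
      kr_fine <- kr_balance(mats[[nm]], tol = config$kr_tol,
                            max_iter = config$kr_max_iter,
                            mask_percentile = config$mask_percentile)
      lp[[nm]] <- call_loops(kr_fine, fdr = config$loop_fdr,
                             min_sep = config$min_sep,
                             r_inner = config$r_inner,
                             r_outer = config$r_outer)
      m_tad <- kr_balance(coarsen_matrix(mats[[nm]], config$tad_factor),
                          tol = config$kr_tol,
                          max_iter = config$kr_max_iter,
                          mask_percentile = config$mask_percentile)
      td[[nm]] <- call_tads(m_tad, w = config$tad_w, span = config$tad_span,
                            min_depth = config$tad_min_depth)
      m_comp <- kr_balance(coarsen_matrix(mats[[nm]], config$comp_factor),
                           tol = config$kr_tol,
                           max_iter = config$kr_max_iter,
                           mask_percentile = config$mask_percentile)
      oe <- distance_normalize(m_comp)
      pc1 <- correlation_pc1(oe)
      act <- tracks[[nm]][c("H3K4me1", "H3K27ac")]
      ina <- tracks[[nm]][c("H3K9me3", "H3K27me3")]
      prof <- orient_and_label(pc1, act, ina)
      pr[[nm]] <- compartment_degree(oe, prof)
      write_profile_bed(pr[[nm]], out("compartments_%s_cond%d.bed", nm, cond))
      write_tads_bed(td[[nm]], out("tads_%s_cond%d.bed", nm, cond))
      write_boundaries_bed(td[[nm]], out("boundaries_%s_cond%d.bed", nm, cond))
      write_loops_bedpe(lp[[nm]], out("loops_%s_cond%d.bedpe", nm, cond))
      for (mk in names(tracks[[nm]]))
        write_bedgraph(tracks[[nm]][[mk]],
                       out("%s_%s_cond%d.bedgraph", mk, nm, cond))
    }
    tgts <- radial_targets(pr, R = config$nucleus_R)
    confs[[cond]] <- optimize_conformation(
      tgts, R = config$nucleus_R, bond_length = config$bond_length,
      k_b = config$k_b, k_r = config$k_r, k_rep = config$k_rep,
      n_steps = config$n_steps, n_restarts = config$n_restarts,
      seed = stage_seed(config$seed, 30L + cond))
    write_xyz(confs[[cond]], out("conformation_cond%d.xyz", cond))
    profiles[[cond]] <- pr; tads[[cond]] <- td; loops[[cond]] <- lp
  }

  # cross-condition comparisons
  reports <- list(); bnd_cmp <- list(); loop_cmp <- list()
  for (nm in names(truth$chroms)) {
    reports[[nm]] <- classify_switches(profiles[[1]][[nm]],
                                       profiles[[2]][[nm]])
    write_switch_report(reports[[nm]], out("switches_%s.tsv", nm))
    bnd_cmp[[nm]] <- compare_boundaries(tads[[1]][[nm]], tads[[2]][[nm]],
                                        match_slack = config$match_slack,
                                        change_threshold = config$change_threshold)
    utils::write.table(bnd_cmp[[nm]]$matched, out("boundary_classes_%s.tsv", nm),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    loop_cmp[[nm]] <- compare_loops(loops[[1]][[nm]], loops[[2]][[nm]],
                                    slack = config$match_slack)
    jsonlite::write_json(as.list(loop_cmp[[nm]]$counts),
                         out("loop_comparison_%s.json", nm),
                         auto_unbox = TRUE, digits = NA)
  }
  genome_switch <- switch_summary(reports)

  genes <- generate_gene_table(truth, n_genes = config$n_genes,
                               de_effect = config$de_effect,
                               seed = stage_seed(config$seed, 40L))
  write_gene_table(genes, out("genes.tsv"))
  annotated <- annotate_genes(genes, reports)
  write_integration(annotated, out("genes_annotated.tsv"))

  files <- sort(list.files(config$out_dir, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    parameters = config[setdiff(names(config), "out_dir")],
    seed = config$seed,
    switch_summary = as.list(genome_switch),
    boundary_counts = as.list(Reduce(`+`, lapply(bnd_cmp, `[[`, "counts"))),
    loop_counts = as.list(Reduce(`+`, lapply(loop_cmp, `[[`, "counts"))),
    compactness = list(cond1 = compactness_score(confs[[1]]),
                       cond2 = compactness_score(confs[[2]])),
    n_candidates = nrow(candidate_genes(annotated)$candidates),
    checksums = as.list(stats::setNames(unname(tools::md5sum(files)),
                                        basename(files)))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
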