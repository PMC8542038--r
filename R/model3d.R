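#' Radial targets from compartment degree
#'
#' Maps each bead's compartment degree to a target distance from the nuclear
#' centre via the linear rule `target = R (0.5 - 0.35 degree)`: the most
#' active bead (degree +1) is pulled to 0.15 R near the centre, the most
#' repressive (degree -1) to 0.85 R near the periphery, and masked beads sit
#' at the neutral 0.5 R. Active-towards-the-centre is the modelling
#' convention adopted here (see the package vignette for discussion).
#'
#' @param profiles a `compartment_profile` with degree filled, or a named
#'   list of them (one per chromosome/chain).
#' @param R nucleus radius in model length units.
#' @param center,slope coefficients of the linear degree-to-radius map.
#' @return named list of per-bead target-radius vectors, one per chain.
#' @export
radial_targets <- function(profiles, R = 10, center = 0.5, slope = 0.35) {
  if (inherits(profiles, "compartment_profile")) {
    profiles <- stats::setNames(list(profiles), profiles$chrom)
  }
  lapply(profiles, function(p) {
    if (is.null(p$degree)) err_state("profile has no compartment degree")
    deg <- p$degree
    deg[is.na(deg)] <- 0
    if (any(abs(deg) > 1 + 1e-9)) err_param("degree must lie in [-1, 1]")
    R * (center - slope * deg)
  })
}

#' Optimise a bead-on-string conformation
#'
#' Coarse-grained polymer model of the genome: one bead per bin, one chain
#' per chromosome, subject to (i) chain connectivity - harmonic bonds of
#' rest length `bond_length` between consecutive beads, (ii) a radial bias
#' potential pulling each bead to its compartment-degree target radius, and
#' (iii) soft-core excluded-volume repulsion below `sigma`. Starting from
#' seed-reproducible random coordinates inside the nuclear sphere, the
#' energy is minimised by noisy damped gradient descent with geometrically
#' decaying noise followed by a monotone descent phase; `n_restarts`
#' independent starts are run and the lowest-energy result kept.
#'
#' @param targets named list of per-bead target radii (from
#'   [radial_targets()]).
#' @param R nucleus radius.
#' @param bond_length bond rest length (much smaller than `R`).
#' @param k_b,k_r,k_rep bond, radial-bias, and repulsion force constants.
#' @param sigma soft-core repulsion range (default `0.8 * bond_length`).
#' @param n_steps optimisation steps per restart (default 5000).
#' @param lr gradient step size.
#' @param noise initial annealing noise amplitude (default
#'   `0.1 * bond_length`).
#' @param gtol termination threshold on the max-abs gradient component.
#' @param n_restarts random restarts; the lowest final energy wins.
#' @param seed integer seed; the whole trajectory is reproducible.
#' @return `conformation_3d` object.
#' @export
optimize_conformation <- function(targets, R = 10, bond_length = 0.5,
                                  k_b = 50, k_r = 5, k_rep = 10,
                                  sigma = 0.8 * bond_length,
                                  n_steps = 5000L, lr = 2e-3,
                                  noise = 0.1 * bond_length, gtol = 1e-4,
                                  n_restarts = 5L, seed = 1L) {
  if (n_steps < 1L) err_param("n_steps must be >= 1")
  if (bond_length >= R) err_param("bond_length must be well below R")
  nb <- vapply(targets, length, 1L)
  chain <- rep(seq_along(targets), nb)
  tgt <- unlist(targets, use.names = FALSE)
  n <- length(tgt)
  set.seed(seed)
  best <- NULL
  restart_energies <- numeric(n_restarts)
  for (rs in seq_len(n_restarts)) {
    r0 <- R * stats::runif(n)^(1 / 3)
    dir <- matrix(stats::rnorm(3 * n), n, 3)
    dir <- dir / sqrt(rowSums(dir^2))
    x0 <- dir * r0
    fit <- optimize_conf_cpp(x0, as.integer(chain), tgt, bond_length,
                             k_b, k_r, k_rep, sigma, as.integer(n_steps),
                             lr, noise, gtol)
    restart_energies[rs] <- fit$final_energy
    if (is.null(best) || fit$final_energy < best$final_energy) best <- fit
  }
  splits <- split(seq_len(n), chain)
  chains <- lapply(seq_along(targets), function(k)
    best$coords[splits[[k]], , drop = FALSE])
  names(chains) <- names(targets)
  structure(
    list(chains = chains, target_radius = targets, R = R,
         params = list(bond_length = bond_length, k_b = k_b, k_r = k_r,
                       k_rep = k_rep, sigma = sigma, lr = lr, noise = noise,
                       gtol = gtol),
         n_steps = as.integer(n_steps), seed = as.integer(seed),
         final_energy = best$final_energy,
         initial_energy = best$initial_energy,
         energy_trace = best$energy_trace, grad_max = best$grad_max,
         restart_energies = restart_energies),
    class = "conformation_3d"
  )
}

#' @export
print.conformation_3d <- function(x, ...) {
  cat(sprintf(paste0("<conformation_3d> %d chain(s), %d beads, R = %g\n",
                     "  final energy %.4g (from %.4g), max |grad| %.3g, ",
                     "%d restart(s)\n"),
              length(x$chains), sum(vapply(x$chains, nrow, 1L)), x$R,
              x$final_energy, x$initial_energy, x$grad_max,
              length(x$restart_energies)))
  invisible(x)
}

#' Energy and gradient of a conformation
#'
#' Evaluates the model energy (bonds + radial bias + soft-core repulsion)
#' and its analytic gradient at arbitrary coordinates - the hook for
#' numerical verification of the optimizer's force field.
#'
#' @param coords n x 3 coordinate matrix.
#' @param chain integer chain id per bead.
#' @param target per-bead target radius.
#' @param bond_length,k_b,k_r,k_rep,sigma model parameters as in
#'   [optimize_conformation()].
#' @return list with `energy` (scalar) and `gradient` (n x 3 matrix).
#' @export
conformation_energy <- function(coords, chain, target, bond_length = 0.5,
                                k_b = 50, k_r = 5, k_rep = 10,
                                sigma = 0.8 * bond_length) {
  conf_energy_cpp(as.matrix(coords), as.integer(chain), as.numeric(target),
                  bond_length, k_b, k_r, k_rep, sigma)
}

#' Radial distribution by compartment label
#'
#' Mean and standard deviation of bead distance from the nuclear centre for
#' A beads, B beads and masked beads, per chain and pooled.
#'
#' @param conf `conformation_3d`.
#' @param profiles named list of `compartment_profile`s aligned to the
#'   chains.
#' @return data.frame with columns chain, label, n, mean_radius, sd_radius
#'   (chain `"all"` pools every chain).
#' @export
radial_profile <- function(conf, profiles) {
  rows <- list()
  all_r <- list(A = numeric(0), B = numeric(0), masked = numeric(0))
  for (nm in names(conf$chains)) {
    p <- profiles[[nm]]
    if (is.null(p)) err_align(sprintf("no profile for chain '%s'", nm))
    xyz <- conf$chains[[nm]]
    if (nrow(xyz) != length(p$label))
      err_align(sprintf("bead/label count mismatch on '%s'", nm))
    r <- sqrt(rowSums(xyz^2))
    lab <- ifelse(is.na(p$label), "masked", p$label)
    for (lv in c("A", "B", "masked")) {
      sel <- r[lab == lv]
      all_r[[lv]] <- c(all_r[[lv]], sel)
      rows[[length(rows) + 1L]] <-
        data.frame(chain = nm, label = lv, n = length(sel),
                   mean_radius = if (length(sel)) mean(sel) else NA_real_,
                   sd_radius = if (length(sel) > 1) stats::sd(sel) else NA_real_)
    }
  }
  for (lv in c("A", "B", "masked")) {
    sel <- all_r[[lv]]
    rows[[length(rows) + 1L]] <-
      data.frame(chain = "all", label = lv, n = length(sel),
                 mean_radius = if (length(sel)) mean(sel) else NA_real_,
                 sd_radius = if (length(sel) > 1) stats::sd(sel) else NA_real_)
  }
  do.call(rbind, rows)
}

#' Chain compactness score
#'
#' Mean Euclidean distance over all within-chain bead pairs, pooled across
#' chains - larger means a looser (less compact) genome fold. Above
#' `max_pairs` pairs the pair set is deterministically strided.
#'
#' @param conf `conformation_3d`.
#' @param max_pairs subsampling threshold (default 1e5).
#' @return mean pairwise within-chain distance (scalar).
#' @export
compactness_score <- function(conf, max_pairs = 1e5) {
  tot <- 0; cnt <- 0
  for (xyz in conf$chains) {
    if (nrow(xyz) < 2L) next
    d <- as.vector(stats::dist(xyz))
    if (length(d) > max_pairs) {
      stride <- ceiling(length(d) / max_pairs)
      d <- d[seq(1L, length(d), by = stride)]
    }
    tot <- tot + sum(d)
    cnt <- cnt + length(d)
  }
  if (cnt == 0) err_param("need at least 2 beads in some chain")
  tot / cnt
}

#' Write a conformation as multi-chain XYZ text
#'
#' One record per bead: chain, bin, x, y, z (tab separated).
#'
#' @param conf `conformation_3d`.
#' @param path output file.
#' @export
write_xyz <- function(conf, path) {
  rows <- do.call(rbind, lapply(names(conf$chains), function(nm) {
    xyz <- conf$chains[[nm]]
    data.frame(chain = nm, bin = seq_len(nrow(xyz)) - 1L,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }))
  utils::write.table(format(rows, digits = 8, trim = TRUE), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
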