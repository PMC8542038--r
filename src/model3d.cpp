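#include <Rcpp.h>
using namespace Rcpp;

// Bead-on-string energy:
//   U = sum_bonds k_b (|x_{i+1}-x_i| - b)^2
//     + sum_beads k_r (|x_i| - t_i)^2
//     + sum_{i<j, |x_i-x_j|<sigma} k_rep (sigma - |x_i-x_j|)^2
// Bonds run between consecutive beads of the same chain; repulsion is a
// soft core over all bead pairs (both chains).

static double energy_grad(const NumericMatrix &x, const IntegerVector &chain,
                          const NumericVector &target, double bond,
                          double k_b, double k_r, double k_rep, double sigma,
                          NumericMatrix &g) {
  int n = x.nrow();
  double U = 0.0;
  std::fill(g.begin(), g.end(), 0.0);
  const double eps = 1e-12;

  for (int i = 0; i + 1 < n; ++i) {
    if (chain[i] != chain[i + 1]) continue;
    double dx = x(i + 1, 0) - x(i, 0);
    double dy = x(i + 1, 1) - x(i, 1);
    double dz = x(i + 1, 2) - x(i, 2);
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dd = d - bond;
    U += k_b * dd * dd;
    double c = (d > eps) ? 2.0 * k_b * dd / d : 0.0;
    g(i + 1, 0) += c * dx; g(i + 1, 1) += c * dy; g(i + 1, 2) += c * dz;
    g(i, 0) -= c * dx;     g(i, 1) -= c * dy;     g(i, 2) -= c * dz;
  }

  for (int i = 0; i < n; ++i) {
    double r = std::sqrt(x(i, 0) * x(i, 0) + x(i, 1) * x(i, 1) +
                         x(i, 2) * x(i, 2));
    double dr = r - target[i];
    U += k_r * dr * dr;
    double c = (r > eps) ? 2.0 * k_r * dr / r : 0.0;
    g(i, 0) += c * x(i, 0); g(i, 1) += c * x(i, 1); g(i, 2) += c * x(i, 2);
  }

  if (k_rep > 0.0 && sigma > 0.0) {
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = x(j, 0) - x(i, 0);
        if (std::abs(dx) >= sigma) continue;
        double dy = x(j, 1) - x(i, 1);
        double dz = x(j, 2) - x(i, 2);
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 >= sigma * sigma) continue;
        double d = std::sqrt(d2);
        double dd = sigma - d;
        U += k_rep * dd * dd;
        double c = (d > eps) ? -2.0 * k_rep * dd / d : 0.0;
        g(j, 0) += c * dx; g(j, 1) += c * dy; g(j, 2) += c * dz;
        g(i, 0) -= c * dx; g(i, 1) -= c * dy; g(i, 2) -= c * dz;
      }
    }
  }
  return U;
}

// [[Rcpp::export]]
List conf_energy_cpp(NumericMatrix x, IntegerVector chain,
                     NumericVector target, double bond, double k_b,
                     double k_r, double k_rep, double sigma) {
  NumericMatrix g(x.nrow(), 3);
  double U = energy_grad(x, chain, target, bond, k_b, k_r, k_rep, sigma, g);
  return List::create(_["energy"] = U, _["gradient"] = g);
}

// Damped noisy gradient descent (simulated-annealing flavour) followed by a
// monotone descent phase with adaptive step size. Noise uses R's RNG so a
// set.seed() on the R side makes the whole trajectory reproducible. The
// descent phase starts from the best configuration seen so far, so the
// returned energy never exceeds the initial energy.
// [[Rcpp::export]]
List optimize_conf_cpp(NumericMatrix x0, IntegerVector chain,
                       NumericVector target, double bond, double k_b,
                       double k_r, double k_rep, double sigma,
                       int n_steps, double lr0, double noise0, double gtol) {
  RNGScope rngScope;
  int n = x0.nrow();
  NumericMatrix x = clone(x0);
  NumericMatrix g(n, 3), best(n, 3);

  double U = energy_grad(x, chain, target, bond, k_b, k_r, k_rep, sigma, g);
  double U_init = U;
  double U_best = U;
  std::copy(x.begin(), x.end(), best.begin());

  int n1 = (int)std::floor(0.6 * n_steps);
  double decay = (n1 > 0) ? std::pow(1e-3, 1.0 / n1) : 1.0;
  double noise = noise0;
  for (int s = 0; s < n1; ++s) {
    for (int k = 0; k < 3 * n; ++k)
      x[k] += -lr0 * g[k] + noise * norm_rand();
    U = energy_grad(x, chain, target, bond, k_b, k_r, k_rep, sigma, g);
    if (!std::isfinite(U))
      stop("energy diverged during annealing; reduce the step size (lr)");
    if (U < U_best) {
      U_best = U;
      std::copy(x.begin(), x.end(), best.begin());
    }
    noise *= decay;
  }

  // monotone phase from the best configuration seen
  std::copy(best.begin(), best.end(), x.begin());
  U = energy_grad(x, chain, target, bond, k_b, k_r, k_rep, sigma, g);
  double lr = lr0;
  int n2 = n_steps - n1;
  int ckpt_every = std::max(1, n2 / 50);
  std::vector<double> trace;
  trace.push_back(U);
  NumericMatrix xtry(n, 3), gtry(n, 3);
  double gmax = R_PosInf;
  for (int s = 0; s < n2; ++s) {
    gmax = 0.0;
    for (int k = 0; k < 3 * n; ++k)
      gmax = std::max(gmax, std::abs(g[k]));
    if (gmax < gtol) break;
    for (int k = 0; k < 3 * n; ++k) xtry[k] = x[k] - lr * g[k];
    double Utry = energy_grad(xtry, chain, target, bond, k_b, k_r, k_rep,
                              sigma, gtry);
    if (std::isfinite(Utry) && Utry <= U) {
      std::copy(xtry.begin(), xtry.end(), x.begin());
      std::copy(gtry.begin(), gtry.end(), g.begin());
      U = Utry;
      lr = std::min(lr * 1.1, lr0 * 10.0);
    } else {
      lr *= 0.5;
      if (lr < 1e-14) break;
    }
    if ((s + 1) % ckpt_every == 0) trace.push_back(U);
  }
  trace.push_back(U);

  return List::create(_["coords"] = x, _["final_energy"] = U,
                      _["initial_energy"] = U_init,
                      _["energy_trace"] = NumericVector(trace.begin(),
                                                        trace.end()),
                      _["grad_max"] = gmax);
}
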