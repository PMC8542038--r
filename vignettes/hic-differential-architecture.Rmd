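---
title: "Differential 3D chromatin architecture from Hi-C: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential 3D chromatin architecture from Hi-C: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicarch)
```

# Scope

`hicarch` compares the 3D genome organisation of two conditions (e.g. a
chromatin-remodeller knockout against wild type) from binned
intra-chromosomal Hi-C contact matrices, at the three folding scales the
field distinguishes: megabase A/B compartments, sub-megabase topologically
associating domains (TADs), and focal chromatin loops, plus a coarse-grained
3D conformation model and an integration of expression changes with
compartment switching. Every stage is validated against a synthetic
two-condition generator with planted, recoverable ground truth; this
vignette records the models, the tunable parameters, and the design choices
made where the underlying methods literature leaves the details open.

# The synthetic generator

The generator is the package's study design: it emulates the statistical
structure of real intra-chromosomal Hi-C and plants condition differences
with exact bookkeeping.

The expected contact between fine bins $i$ and $j$ is

$$E[i,j] \;=\; d\,\max(|i-j|,1)^{-\alpha}\; \rho^{[\ell_i=\ell_j]}\;
\tau^{[t_i=t_j]}\; \lambda^{[(i,j)\in L]},$$

a power-law distance decay (exponent $\alpha$, depth scale $d$) modulated by
multiplicative architecture terms: $\rho$ for same-compartment pairs (the
checkerboard), $\tau$ for same-TAD pairs (the triangles), $\lambda$ for
planted loop pixels (focal peaks). Counts are independent Poisson draws of
$E$, symmetrised. Defaults $\alpha = 1$, $\rho = 1.4$, $\tau = 2$,
$\lambda = 3$, $d = 10^6$ were chosen once so that each feature is visible
without caricature: each downstream caller must work from realistic, not
overwhelming, signal.

Architecture lives on one multi-resolution ladder from a single truth:
loops on the fine grid, TAD boundaries on a grid of `tad_factor` fine bins,
compartment labels on a grid of `comp_factor` fine bins (mirroring the
common 25 kb / 50 kb / 500 kb analysis ladder); fine matrices are coarsened
by block summation before analysis at the coarser scales.

Condition 2 differs from condition 1 in exactly the requested fractions:

* **Compartment flips.** `flip_fraction` of compartment bins (sampled
  genome-wide, both directions equally likely) swap their A/B label.
* **Boundary weakening.** `weaken_fraction` of TAD boundaries are weakened.
  Most receive a residual cross-boundary contact boost
  $1 + w(\tau - 1)$ with leak $w = 0.5$ - still detectable, measurably
  weaker; a `merge_fraction` (default 0.15) of the selected set is removed
  outright, merging the flanking domains. The mix realises both halves of
  the weakening phenomenology: boundaries that soften and domains that
  merge or vanish.
* **Loop loss.** `loop_loss_fraction` of loops are absent from condition 2.

Histone-mark tracks (H3K4me1/H3K27ac active, H3K9me3/H3K27me3 repressive)
are two-level signals over the condition's labels with Gaussian noise of
standard deviation $\mu_\text{high}/\text{snr}$. The gene table places genes
uniformly over compartment bins; genes in A$\to$B bins are down-regulated by
`de_effect` in expectation, B$\to$A the reverse, and a small background
fraction (5%) of stable-bin genes get a planted effect of random sign so
that differential expression and switching are not perfectly confounded.
Expression noise is log-normal; the DE flag records the planted direction
(differential-expression calling itself is treated as an input, not
recomputed).

What the generator does **not** emulate: inter-chromosomal contacts,
replicate-level batch effects, mappability structure beyond dropped bins,
distance-dependent dispersion beyond Poisson, or sequence-level features.
Passing planted-truth tests therefore demonstrates the correctness and
calibration of the algorithms under a faithful statistical cartoon - not
performance on real libraries, where overdispersion and artefacts are
harsher.

# Matrix normalisation

**Balancing.** `kr_balance()` performs Knight-Ruiz-style matrix balancing
as symmetric alternating (Sinkhorn) scaling: the returned matrix is
$B = D_v C D_v$ with every retained row summing to the mean raw unmasked
row sum, to relative tolerance `tol` ($10^{-8}$ by default, capped at 3000
iterations). Keeping row sums on the raw count scale (rather than 1) keeps
balanced entries interpretable as near-counts, which the loop caller's
Poisson test relies on. Rows with zero total, plus rows below the 1st
percentile of nonzero row sums (inverse-ECDF quantile, so tiny matrices
never lose their minimum row), are masked first - the standard guard
against unmappable bins that stall balancing.

**O/E.** `distance_normalize()` divides each entry by the mean unmasked
entry at its diagonal offset; empty offsets yield zero rather than
dividing by zero.

# A/B compartments

Per chromosome - never genome-wide - the Pearson correlation matrix of the
O/E map is computed over unmasked bins and its leading eigenvector is the
compartment signal (PC1). Two details are deliberate:

* **Sign orientation.** An eigenvector's sign is arbitrary, so PC1 is
  anchored to chromatin state: with
  $s = \sum_{\text{active}} r(\text{PC1}, \text{track}) -
  \sum_{\text{repressive}} r(\text{PC1}, \text{track})$, the vector is
  flipped when $s < 0$; bins with oriented PC1 $> 0$ are A. When
  $|s| < 0.05$ the orientation is ambiguous and the package raises an
  error asking for a manual sign choice - silent guessing on an ambiguous
  chromosome would corrupt every downstream switch call.
* **Compartment degree.** The continuous activity index used by the 3D
  model is the oriented PC1 rescaled by its maximum absolute entry, giving
  a per-bin value in $[-1, 1]$. This is the simplest monotone index
  computable directly from the contact matrix; it is a package decision,
  recorded here because the literature offers several inequivalent
  definitions.

Switch classification is a per-bin label comparison (stable A, stable B,
A$\to$B, B$\to$A; masked if masked in either condition), with percentages
over unmasked bins.

# TADs

The boundary statistic is the TopDom binSignal: for bin $i$, the mean
balanced contact between the $w$ bins ending at $i$ and the $w$ bins
starting at $i+1$ ($w = 5$ by default, the TopDom default), clipped at
chromosome ends and skipping masked bins. After a centred running-mean
smoothing (span 3), boundaries are strict local minima over a $\pm w$
neighbourhood (leftmost bin of a tied plateau) whose prominence - the
smaller flanking maximum minus the minimum - reaches `min_depth`, by
default 0.1 of the smoothed signal's 10-90 percentile span. Domains are the
intervals between consecutive boundaries.

Boundary strength is the insulation depth: mean binSignal over the
interiors of the two flanking domains minus the binSignal at the boundary.
Two-condition comparison matches boundaries greedily by nearest position
within `match_slack` (2 bins - sampling jitter moves minima by about a bin
at realistic depth) and classifies matched pairs by relative strength
change against `change_threshold` (0.1); unmatched boundaries are reported
as lost or gained, which is how fully merged domains appear.

# Loops

The caller is a deliberately transparent, simplified donut-background
method. For every eligible pixel (both bins unmasked, full annulus inside
the matrix, separation at least $2 r_\text{outer} + 1$ bins so the annulus
stays strictly in the upper triangle), the local expected value is the mean
balanced count over the Chebyshev annulus
$r_\text{inner} < \max(|u-i|,|v-j|) \le r_\text{outer}$ (defaults 2 and 5),
excluding the pixel's own row and column stripes. The pixel's rounded
balanced count gets a Poisson upper-tail p-value against that expected
value (balanced counts are near-counts under the row-sum convention above -
an approximation, noted as such), Benjamini-Hochberg correction is applied
across all eligible pixels of the chromosome, and significant pixels are
merged into 8-connected clusters keeping each cluster's most significant
pixel.

A called pixel must additionally exceed its donut background by
`min_enrich` = 2. This fold threshold carries real weight: at deep
sequencing the Poisson test alone certifies arbitrarily small excesses, and
pixels at domain corners - whose annulus blends within-TAD with outside-TAD
cells - show enrichments approaching the within-domain boost itself. The
threshold therefore has to dominate the strongest non-loop multiplier the
contact structure can produce (2 equals the generator's $\tau$; for data
with stronger domain enrichment it should be raised accordingly). The
converse limitation: a true loop whose annulus straddles a TAD boundary has
an inflated background and can fall below the threshold, so recall is
highest for loops whose local neighbourhood is architecturally homogeneous.
The full HiCCUPS addresses both effects with extra filters (horizontal,
vertical, lower-left) that this package intentionally omits; no claim of
pixel-level concordance with HiCCUPS is made.

Loop sets are compared by greedy Chebyshev matching within `slack` bins;
unmatched calls are lost or gained.

# 3D conformation model

One bead per bin, one chain per chromosome (the chain count follows the
input profiles; a mouse genome yields the usual 21 chains). The energy is

$$U = \sum_\text{bonds} k_b\,(\lVert x_{i+1}-x_i\rVert - b)^2
    + \sum_\text{beads} k_r\,(\lVert x_i\rVert - t_i)^2
    + \sum_{i<j,\ \lVert x_i - x_j\rVert < \sigma}
      k_\text{rep}\,(\sigma - \lVert x_i-x_j\rVert)^2,$$

connectivity plus a radial bias potential plus soft-core excluded volume.
Radial targets come from the compartment degree by the linear map
$t = R\,(0.5 - 0.35\,\text{degree})$: the most active bead is pulled to
$0.15R$, the most repressive to $0.85R$, masked beads sit at $0.5R$. Active
chromatin towards the nuclear centre is the modelling convention adopted
here, consistent with the radial ordering this package is designed to
reproduce; much literature places active chromatin peripherally within
territories, so the convention is flagged rather than claimed universal.

Optimisation starts from seed-reproducible uniform random coordinates in
the sphere and runs two phases: noisy damped gradient descent with
geometrically decaying noise (a simulated-annealing flavour) for 60% of the
steps, then monotone descent with an adaptive step size from the best
configuration seen, terminating early when the maximum gradient component
falls below `gtol`. The returned energy therefore never exceeds the initial
energy, and recorded trajectory checkpoints are non-increasing. Defaults
$k_b = 50$, $k_r = 5$, $k_\text{rep} = 10$, $\sigma = 0.8\,b$, 5000 steps,
5 restarts keeping the lowest energy (all restart energies are reported)
were fixed so that the two-bead analytic case converges to within 1% and
planted A/B profiles separate radially; the gradient implementation is
verified against finite differences in the test suite. `n_restarts` and
the annealing noise matter for reproducibility of comparisons: when
contrasting two conditions, use identical optimizer seeds (common random
numbers) so conformational differences reflect the input profiles.

**Known limitation.** The model sees only the compartment degree; TAD and
loop differences never reach it. Consequently the only condition contrast
it can express is the degree profile, and symmetric compartment flips leave
the distribution of radial targets statistically unchanged. The mean
within-chain pairwise distance (`compactness_score()`) accordingly shows no
robust systematic difference between the two synthetic conditions: across
repeated paired runs the sign of the difference is near a coin flip. The
radial A-versus-B ordering, by contrast, is a direct and robust consequence
of the bias potential. Interpret compactness contrasts from this model
with corresponding caution.

# Expression integration

Genes are assigned to the compartment bin containing their midpoint (the
unambiguous rule for genes straddling bin edges) and inherit that bin's
switch class. Log2 fold changes use a pseudocount of 0.01 FPKM to avoid
infinities at zero expression. Per-class summaries use medians, means and
IQRs, with a two-sided Wilcoxon rank-sum test between the two switching
classes. The candidate list intersects differential expression with
switching under direction concordance (down-regulated in A$\to$B,
up-regulated in B$\to$A); because the concordance requirement is a package
decision rather than settled convention, discordant DE genes in switched
bins are returned separately, so a purely positional overlap is always
recoverable, and the DE-by-switch Venn counts are reported before the
concordance filter.

# Pipeline and problem sizes

`run_pipeline()` chains the stages per condition and then all
cross-condition comparisons, writing plain-text outputs (sparse triplets,
bedGraph, BED/BEDPE, XYZ, TSV/JSON) and a manifest containing every decided
parameter and the md5 checksum of every output; identical configurations
reproduce identical checksums. Validation rejects resolution ladders where
the TAD grid does not divide the compartment grid before any computation.

The shipped defaults and the test suite run at desk scale - chromosomes of
60-300 bins, depths around $10^6$ expected counts per unit-distance pair,
five-seed replications - sizes chosen so the full validation cycle runs in
seconds while every statistical property under test (Poisson concentration,
eigenvector recovery, FDR calibration, planted-difference recovery) is
well inside its asymptotic regime.

# Numerical and degenerate-input policy

Zero-variance bins are added to the PCA mask; fewer than 10 usable bins is
a degeneracy error. Exact-zero PC1 entries take the label of the nearest
nonzero bin, ties towards B. Balancing of a matrix with fewer than two
unmasked bins, an all-masked degree request, or an entirely masked donut
annulus raise classed errors rather than returning NaN. Offsets with zero
mean map to zero in O/E. Plateau minima in the TAD signal resolve to their
leftmost bin. All randomness flows through explicit integer seeds, and
every generator and the optimizer are bit-reproducible under a fixed seed.
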