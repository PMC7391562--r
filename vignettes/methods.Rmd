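---
title: "Multi-scale presence-background modelling with sampling-bias correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale presence-background modelling with sampling-bias correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(scalesdm)
```

# The problem

Presence-only occurrence records — camera-trap detections, genetically
verified scat — carry no information about where a species is absent, so
habitat models for elusive species such as the snow leopard are built by
contrasting occurrences against *background* points that describe what the
landscape offers. Two methodological problems dominate this setting and this
package implements a tested, reusable treatment of both:

1. **Scale of effect.** A predictor (terrain roughness, grassland cover,
   river density) influences an animal at some characteristic radius around
   each location, and that radius is unknown a priori. Every predictor is
   therefore summarized over circular moving windows at an ordered ladder of
   radii, and the radius at which a single-predictor model discriminates
   best is selected per variable before any multivariate model is built.
2. **Sampling bias.** Survey effort clusters along valleys, roads and
   camera grids. Uncorrected, the model reconstructs the survey design
   rather than the species' niche. Two standard corrections are
   implemented — spatial rarefaction (SR: thin the records to a minimum
   pairwise distance) and Gaussian-kernel background weighting (GK: draw the
   background from an estimate of the survey-effort surface) — and a
   simulation framework measures how much of the damage each correction
   undoes.

# The model

The core estimator is a maximum-entropy (Gibbs) density over the landscape.
With features $f(x)$ (each predictor rescaled to $[0,1]$ by its background
range, plus its square) and coefficients $\lambda$, the model is

$$q_\lambda(x) = \frac{e^{\lambda \cdot f(x)}}{\sum_{x' \in B} e^{\lambda \cdot f(x')}},$$

fitted by maximizing the penalized mean presence log-likelihood

$$\frac{1}{m}\sum_{i=1}^{m} \log q_\lambda(x_i) \;-\; \sum_j \beta_j |\lambda_j|.$$

The presence sample is appended to the background $B$ before normalization.
The per-feature penalties $\beta_j$ follow the published default
regularization for the linear + quadratic feature class: a presence-count
keyed interpolation (1.3 at 0 presences down to 0.05 at 100 or more),
multiplied by the feature's presence-sample standard deviation over
$\sqrt{m}$, with the deviation floored at $1/\sqrt{m}$ so that perfectly
separable features stay finitely penalized. A `reg_multiplier` scales all
penalties; 1 reproduces the defaults.

**Optimization.** The objective is concave; `fit_maxent()` solves it by
accelerated proximal gradient (FISTA with adaptive restart and a
backtracking line search), deterministic given the design, capped at 5,000
iterations with an absolute objective tolerance of `1e-6` (loosen or
tighten per call). The test suite checks the fitted raw surface against an
independent generic convex solver (box-constrained L-BFGS-B on the split
$\lambda = u - w$) to within $10^{-4}$.

**Outputs.** The *raw* output is $q_\lambda$ itself, summing to one over the
background. The *logistic* output is $c\,q/(1 + c\,q)$ with $c = e^H$, $H$
the entropy of the fitted raw distribution; an uninformative model therefore
scores exactly 0.5 everywhere, a convention the tests pin down so it cannot
silently drift.

# Predictors and the window engine

One circular-window definition is used everywhere: a cell belongs to the
window of radius $r$ iff its center lies within $r$ of the focal cell
center. `focal_stat()` computes windowed mean/sd/min/max (population sd;
nodata neighbours excluded; nodata out where the focal cell is nodata) via
exact direct summation for small problems and FFT convolution for large
ones, after centering to avoid cancellation in the variance.

Terrain predictors follow the standard geomorphometric-toolbox definitions:
slope position is the topographic position index (elevation minus windowed
mean), roughness the windowed standard deviation, dissection the Martonne
relief ratio $(z - z_{\min})/(z_{\max} - z_{\min})$ (0 on flats by
convention), and the compound topographic index is
$\ln(a_s/\tan\beta)$ with $a_s$ proxied by (D8 flow accumulation + 1) times
the cell size and $\beta$ the Horn 3×3 slope floored at 0.001 rad. D8
routing uses a fixed neighbour order (E, SE, S, SW, W, NW, N, NE) to break
slope ties, so accumulation is reproducible; pits are terminal.

Landscape-pattern metrics use FRAGSTATS conventions: patches are
8-connected components of equal class, adjacency accounting for the
aggregation index and edge metrics is rook and single-count, windows are
clipped before computation, and the window border contributes no edge.
PLAND, AI and CWED admit exact per-cell moving-window evaluation through
convolutions with "both ends inside the disc" pair kernels; PD, AREA_AM and
GYR_AM require relabeling patches inside every window and are evaluated on
a block lattice on larger grids (the block step is recorded as an attribute
of the output). The contrast matrix for CWED defaults to
$|rank(a)-rank(b)|/(K-1)$ over the ordered class list and is overridable;
published contrast weights for any particular landcover legend can be
passed directly.

# The selection framework

*Univariate scaling.* Each variable is fitted alone at every ladder radius
(27 variables × 9 radii = 243 fits in the full protocol). Per variable the
radius with the highest test AUC wins; ties fall to the smaller
training-minus-test AUC difference (the overfitting proxy), then to the
smaller radius. The second tie-break is this package's own determinism
rule — exact double ties are vanishingly rare but must not depend on sort
order.

*Collinearity.* Pairwise Pearson correlations over a seeded 10,000-cell
subsample; pairs with $|r| \ge 0.7$ are processed in decreasing $|r|$ and
the lower-AUC member is dropped unless already dropped. Constant layers
have no defined correlation; they are reported and treated as uncorrelated.

*Candidates.* Multivariate models take exactly one variable from each of
the five categories (linear/point features, topographic, climatic,
landscape-level landcover, class-level landcover): the candidate set is the
full Cartesian product of the retained per-category lists. All candidates
are evaluated against the *same* background sample so that AUC differences
reflect predictors, not background noise. The ten best by test AUC are
re-evaluated with 10-fold cross-validation and a leave-one-variable-out
jackknife; the jackknife is reported but plays no role in ranking.

*Multi- versus single-scale.* Each retained model is re-evaluated with all
of its variables forced to each single ladder radius (ten models × (9 + 1)
= 100 evaluations); the column averages reproduce the summary row of the
standard comparison table.

# Bias correction and ensemble overlap

The five best models under each correction are averaged cell-wise and
min-max rescaled to $[0,1]$. Overlap between ensembles uses Schoener's
$D = 1 - \tfrac12\sum_i |p_{x,i} - p_{y,i}|$ *after* each surface is
normalized to sum to one over the shared valid cells — the statistic is
defined on probability distributions, and a min-max rescale alone does not
produce one. Surfaces beyond 250,000 cells are block-aggregated to a common
coarse lattice first. The improvement of a correction is
$\Delta D_{geo} = (D_{corrected} - D_{biased})/(1 - D_{biased})$, the
fraction of the gap to the unbiased reference closed by the correction. The
best correction maximizes $\Delta D_{geo}$ among corrections that also
reduce the mean MTSS omission rate below the uncorrected value; if none
does, the global maximum is returned with an explicit
`omission_constraint_unmet` flag.

Reference (unbiased) pseudo-occurrence sets are simulated by subtracting a
*single* shared U(0,1) raster from each of the five reference surfaces,
summing the differences into a cumulative potential surface, dropping a
50,000-point uniform cloud, keeping points on positive cells, and
subsampling; the simulated-biased variant first clips the cloud to a
28,800 m buffer around the original records. Because one U draw is shared,
a point survives at a cell with suitability $s$ (identical surfaces) with
probability exactly $s$ — a property the tests verify by Monte Carlo.

Operational details fixed by design: SR thinning is greedy over a seeded
shuffle, so the retained set is maximal under its visiting order and its
minimum pairwise distance is checked exhaustively in tests. The GK bias
surface is $\sum_k e^{-d_k^2/2\sigma^2}$ rescaled to $(10^{-6}, 1]$; the
floor keeps every cell reachable by the weighted background sampler. GK
background points are drawn *with replacement* in proportion to the bias
surface — the background then represents the survey-effort distribution
itself, which is the bias-file semantics of the standard implementation and
remains correct when the eligible pool is smaller than the requested
20,000 points. SR refits keep the buffer mask of the *full* occurrence set,
so all corrections are trained over the same accessible area.

# The synthetic-data generator

No real occurrence or GIS data ship with the package; the generator
produces landscapes with the statistical structure the pipeline assumes.
Elevation is Gaussian-filtered white noise (default correlation length 4
cells) scaled to 4,500 ± 600 m; landcover quantile-thresholds a second,
smoother field, which guarantees contiguous patches so patch metrics are
non-degenerate; temperature is a 6.5 °C/km lapse-rate transform of the DEM
plus a smooth anomaly (so its rank correlation with elevation is negative
by construction); river, road and settlement densities are kernel-smoothed
counts of random line segments and weighted points (settlement weights 4
down to 1, emulating city–town–village–hamlet tiers). A virtual species is
an inverse-logit combination of declared focal-scaled, standardized
predictors with linear or quadratic response shapes, min-max rescaled;
occurrences are drawn in proportion to suitability — sequential weighted
draws without replacement, which is distributionally identical to rejection
sampling with deduplication — and snap to cell centers. The clustered
design restricts the candidate pool to discs around cluster centers, with
optional center weights to make the survey bias systematic (e.g. an
accessibility surface decaying with elevation) rather than randomly placed.

What the generator does *not* emulate: real GlobCover class frequencies,
anisotropic terrain, autocorrelated detection error, or the geography of
any actual reserve. Passing tests therefore demonstrate that the machinery
recovers known structure under its own assumptions, not that any ecological
conclusion transfers to a particular landscape.

# Study conditions for the packaged experiments

Three experiments (exported as `run_scale_recovery()`,
`run_multiscale_comparison()`, `run_bias_experiment()`) fix the synthetic
conditions once:

* **Scale recovery** — 128 × 128 cells at 90 m, ladder truncated at
  4,800 m (larger windows would not fit the extent; the full nine-radius
  ladder is reserved for grids of 700 cells a side or more), species
  responding linearly (coefficient 3) to focal elevation at 1,200 m, 200
  presences, full-pool background. Univariate scaling must recover 1,200 m.
* **Multi- versus single-scale** — same grid, species with two true scales
  (elevation at 4,800 m, a unimodal temperature response at 300 m); the
  true-scale model is compared with its nine forced-scale twins.
* **Bias correction** — 128 × 128 cells at 720 m (≈ 92 km a side), so the
  fixed correction radii of 1,200–9,600 m stay small relative to the
  extent, as they are in real study areas. Survey bias is hierarchical:
  three regions drawn from an accessibility surface (exponential decay with
  elevation, 400 m e-folding), nine camera-cluster centers of 2,200 m
  radius concentrated inside them via an 8,000 m kernel, 130 biased
  records versus 150 unbiased reference records. Five three-predictor
  models sharing the species' true predictors form the ensembles. These
  sizes keep the full experiment suite within a few minutes on one CPU
  while leaving each fit comfortably identified.

# Numerical choices and degenerate inputs

* Convolution switches from exact direct summation to FFT above ~4·10⁶
  kernel-cell × grid-cell operations; FFT round-off is ~10⁻⁹ relative and
  count rasters are rounded back to integers.
* Windowed variance is computed on globally centered values to avoid
  catastrophic cancellation at elevation magnitudes.
* Flat dissection windows return 0; empty metric windows return nodata;
  single-cell classes contribute aggregation 0 (their maximum adjacency is
  zero).
* A presence split always leaves both partitions non-empty when at least
  two presences exist, so heavily rarefied datasets remain evaluable.
* MTSS threshold ties resolve to the lowest candidate threshold; omission
  counts presences *strictly* below the threshold.
* All stochastic steps take explicit integer seeds; identical
  configuration and seed reproduce results bit-for-bit.

# Known limitations

* Rasters are read and written as ESRI ASCII grids only; inputs must
  already share a projected metric CRS and grid (no reprojection engine).
* Only linear and quadratic features (no hinge/product/threshold), no
  cloglog output, and no model transfer onto other landscapes.
* D8 single-direction routing without sink filling; CTI on closed basins
  treats pits as terminals.
* Patch-based moving-window metrics on large grids are evaluated on a
  block lattice — an explicit, recorded approximation.
* The greedy SR rule is order-dependent by construction (seeded), as in
  common thinning tools; it does not search for the maximum-cardinality
  thinned set.
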