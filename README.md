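# scalesdm

Multi-scale presence-background species distribution models with
sampling-bias correction.

## What this package is for

Habitat models for elusive, wide-ranging species (the motivating case is
the snow leopard in High-Asian mountain landscapes) are usually built from
presence-only records — camera-trap detections and genetically verified
scat — contrasted against background points. Two methodological choices
dominate the quality of such models, and `scalesdm` implements a complete,
tested pipeline for both:

* **Scale-of-effect optimization.** Every predictor (terrain indices,
  climate, landcover pattern metrics, river/road/settlement densities) is
  summarized over circular moving windows at an ordered ladder of radii
  (300 m to 28,800 m), and the best-supported radius is selected per
  variable by single-predictor model performance before multivariate models
  are enumerated under a one-variable-per-category constraint.
* **Sampling-bias correction.** Survey clustering is corrected by spatial
  rarefaction (SR) or Gaussian-kernel background weighting (GK) at four
  radii; corrected ensembles of the top five models are scored against a
  simulated unbiased reference ensemble with Schoener's D, and the best
  correction maximizes the fraction of the overlap gap closed,
  ΔD_geo = (D_corrected − D_biased)/(1 − D_biased), subject to not
  worsening the MTSS omission rate.

At the core is an L1-regularized maximum-entropy model
q(x) = exp(λ·f(x))/Z over the background, with linear + quadratic features,
the published default regularization schedule, and the logistic output
c·q/(1 + c·q), c = e^H. The optimizer is a deterministic proximal-gradient
solver validated against an independent convex-solver oracle in the tests.

A synthetic-landscape and virtual-species generator makes the whole
pipeline testable without any external GIS data: correlated random-field
elevation, a patchy landcover mosaic, lapse-rate temperature, feature
densities, and occurrence sampling under unbiased, clustered, and
hierarchically biased survey designs.

## Worked example

Generate a landscape, define a virtual species that responds to the focal
mean of elevation within 1,200 m, sample occurrences, and let univariate
scaling recover the generating radius:

```r
library(scalesdm)

b <- generate_landscape(c(128, 128), cell_size = 90, n_classes = 5, seed = 7)
species <- define_virtual_species(b, list(
  list(predictor = "dem", scale = 1200, shape = "linear", coefficient = 3)))
occ <- sample_occurrences(species, n = 200, seed = 1)

layers <- lapply(b$ladder, function(s) focal_stat(b$dem, s, "mean"))
names(layers) <- layer_name("ELEV", b$ladder)
mask <- buffer_mask(occ, b$dem, radius = 28800)
design <- build_design(occ, layers, mask, n_background = 20000, seed = 1)

scaling <- univariate_scaling(design, "ELEV", b$ladder)
best_scales(scaling)
#> # A tibble: 1 × 5
#>   variable scale layer     auc_test auc_diff
#>   <chr>    <dbl> <chr>        <dbl>    <dbl>
#> 1 ELEV      1200 ELEV_1200    0.697   0.0237
```

The selected scale is the true generating radius (1,200 m); the test AUC of
~0.70 is what a single moderately informative predictor buys on this
landscape, and `auc_diff` ≈ 0.02 shows little overfitting. Fitting and
evaluating the model at that scale:

```r
model <- fit_maxent(design, layers = "ELEV_1200")
model
#> <maxent_model> 2 features on 1 layers | H = 9.3643 | converged in 41 iters
#>   non-zero coefficients:
#>     ELEV_1200                +30.01414
#>     ELEV_1200^2              -23.57979

eval_report(model, design)
#> # A tibble: 1 × 8
#>   auc_train auc_test auc_diff  mtss omission_train omission_test ...
#> 1     0.721    0.697   0.0237 0.449          0.173          0.22
```

The positive linear and negative quadratic coefficients describe a rising,
saturating response to focal elevation; `mtss` is the
maximum-training-sensitivity-plus-specificity threshold and the omission
columns report the fraction of presences scoring below it. Downstream
stages follow the same tibble-in/tibble-out pattern:
`collinearity_filter()`, `enumerate_candidates()`, `rank_and_retain()`,
`single_vs_multiscale()` for model selection, and `rarefy()`,
`kernel_surface()`, `ensemble_surface()`, `schoener_d()`,
`select_best_correction()` for the bias stage. `autoplot()` methods cover
grids, ensembles and scaling profiles; `tidy()`/`glance()` cover fitted
models. The packaged experiments `run_scale_recovery()`,
`run_multiscale_comparison()` and `run_bias_experiment()` reproduce the
full simulation studies; their conditions are documented in
`vignettes/methods.Rmd`.

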