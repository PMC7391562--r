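# Rarefaction, kernel bias surfaces, reference-occurrence simulation,
# ensembles, Schoener's D and the best-correction rule.

test_that("rarefaction enforces the minimum pairwise distance", {
  occ1 <- tibble::tibble(x = 100, y = 100, source = "s")
  expect_equal(nrow(rarefy(occ1, 500)), 1)
  occ2 <- tibble::tibble(x = c(0, 200), y = c(0, 0), source = "s")
  expect_equal(nrow(rarefy(occ2, 400)), 1)
  # 5 collinear points spaced 0.6 * radius apart
  r <- 1000
  occ5 <- tibble::tibble(x = seq(0, by = 0.6 * r, length.out = 5), y = 0,
                         source = "s")
  for (seed in 1:10) {
    kept <- rarefy(occ5, r, seed = seed)
    d <- as.matrix(dist(cbind(kept$x, kept$y)))
    expect_true(all(d[upper.tri(d)] >= r))
    # maximality: no dropped point is >= r from every kept point
    dropped <- dplyr::anti_join(occ5, kept, by = c("x", "y"))
    if (nrow(dropped)) {
      for (i in seq_len(nrow(dropped))) {
        expect_true(any(sqrt((kept$x - dropped$x[i])^2 +
                             (kept$y - dropped$y[i])^2) < r))
      }
    }
  }
})

test_that("rarefied synthetic occurrences always satisfy the radius", {
  sp <- fixture_species()
  occ <- sample_occurrences(sp, 300, design = "clustered",
                            cluster_centers = 4, cluster_radius = 3000,
                            seed = 2)
  for (r in c(1200, 2400)) {
    kept <- rarefy(occ, r, seed = 3)
    d <- as.matrix(dist(cbind(kept$x, kept$y)))
    expect_true(all(d[upper.tri(d)] >= r))
    expect_lt(nrow(kept), nrow(occ))
  }
})

test_that("kernel surface has Gaussian shape and equal cluster maxima", {
  g <- sdm_grid(matrix(0, 41, 41), cell_size = 100)
  cc <- cell_centers(g)
  occ <- tibble::tibble(x = cc$x[21], y = cc$y[21], source = "s")
  sigma <- 500
  ks <- kernel_surface(occ, sigma, g)
  expect_equal(which.max(ks$values), which(outer(1:41, 1:41,
    function(i, j) i == 21 & j == 21)))
  # value at distance sigma = exp(-0.5) times the peak
  expect_equal(ks$values[21, 26], exp(-0.5) * ks$values[21, 21],
               tolerance = 1e-9)
  # two distant equal clusters give two equal local maxima
  occ2 <- tibble::tibble(x = cc$x[c(6, 36)], y = cc$y[21], source = "s")
  k2 <- kernel_surface(occ2, 300, g)
  expect_equal(k2$values[21, 6], k2$values[21, 36], tolerance = 1e-9)
  expect_true(all(k2$values >= 1e-6))
  expect_equal(max(k2$values), 1)
})

test_that("reference simulation honours the subtracted-raster construction", {
  g <- sdm_grid(matrix(1, 50, 50), cell_size = 100)
  s1 <- g
  # all surfaces at 1: candidates are nearly the whole cloud
  occ <- simulate_reference_occurrences(rep(list(s1), 5), n = 100,
                                        mode = "FR", n_cloud = 2000, seed = 1)
  expect_equal(nrow(occ), 100)
  # all surfaces at 0: cumulative <= 0 everywhere, simulation exhausted
  s0 <- g; s0$values[] <- 0
  expect_error(simulate_reference_occurrences(rep(list(s0), 5), n = 10,
                                              mode = "FR", n_cloud = 500,
                                              seed = 1),
               "exhausted")
  # SB mode requires and respects the buffer
  expect_error(simulate_reference_occurrences(rep(list(s1), 5), n = 5,
                                              mode = "SB", seed = 1),
               "buffer")
  buf <- g; buf$values[] <- 0; buf$values[, 1:10] <- 1
  sb <- simulate_reference_occurrences(rep(list(s1), 5), n = 50, mode = "SB",
                                       buffer = buf, n_cloud = 5000, seed = 2)
  pc <- points_to_cells(sb$x, sb$y, g)
  expect_true(all(buf$values[pc$cell] == 1))
})

test_that("candidate frequency tracks suitability (single shared U draw)", {
  # with five identical surfaces equal to s, a cloud point at a cell survives
  # iff 5*(s - U) > 0, i.e. with probability s
  g <- sdm_grid(matrix(rep(c(0.2, 0.8), each = 450), 30, 30), cell_size = 100)
  hits_lo <- hits_hi <- n_lo <- n_hi <- 0
  for (seed in 1:20) {
    occ <- try(simulate_reference_occurrences(rep(list(g), 5), n = 50,
                                              mode = "FR", n_cloud = 4000,
                                              seed = seed), silent = TRUE)
    set.seed(seed)  # reproduce the shared U raster and the cloud
    u <- matrix(runif(900), 30, 30)
    px <- g$origin[1] + runif(4000) * 30 * 100
    py <- g$origin[2] - runif(4000) * 30 * 100
    pc <- points_to_cells(px, py, g)
    surv <- g$values[pc$cell] - u[pc$cell] > 0
    lo <- g$values[pc$cell] == 0.2
    hits_lo <- hits_lo + sum(surv & lo); n_lo <- n_lo + sum(lo)
    hits_hi <- hits_hi + sum(surv & !lo); n_hi <- n_hi + sum(!lo)
  }
  # binomial CI at ~40k draws: within about 1.5 percentage points
  expect_lt(abs(hits_lo / n_lo - 0.2), 0.015)
  expect_lt(abs(hits_hi / n_hi - 0.8), 0.015)
})

test_that("ensembles are member-order invariant, rescaled means", {
  g <- sdm_grid(matrix(0, 1, 2), cell_size = 100)
  m1 <- g; m1$values <- matrix(c(0.2, 0.6), 1, 2)
  m2 <- g; m2$values <- matrix(c(0.4, 0.8), 1, 2)
  e <- ensemble_surface(list(m1, m2))
  # means (0.3, 0.7) rescale to (0, 1)
  expect_equal(e$values, matrix(c(0, 1), 1, 2))
  e2 <- ensemble_surface(list(m2, m1))
  expect_equal(e$values, e2$values)
  # five identical members: rescaled copy of any one
  e3 <- ensemble_surface(rep(list(m1), 5))
  expect_equal(e3$values, matrix(c(0, 1), 1, 2))
  expect_error(ensemble_surface(list(m1, sdm_grid(matrix(0, 2, 2), 100))),
               "geometry")
})

test_that("Schoener's D: identity, disjointness, hand value, symmetry", {
  g <- sdm_grid(matrix(0, 1, 2), cell_size = 100)
  a <- g; a$values <- matrix(c(1, 0), 1, 2)
  b <- g; b$values <- matrix(c(0.5, 0.5), 1, 2)
  expect_equal(schoener_d(a, b), 0.5)
  expect_equal(schoener_d(a, a), 1)
  dis <- g; dis$values <- matrix(c(0, 1), 1, 2)
  expect_equal(schoener_d(a, dis), 0)
  set.seed(3)
  x <- sdm_grid(matrix(runif(400), 20, 20), 100)
  y <- sdm_grid(matrix(runif(400), 20, 20), 100)
  expect_equal(schoener_d(x, y), schoener_d(y, x), tolerance = 1e-12)
  expect_equal(schoener_d(x, x), 1, tolerance = 1e-12)
  # D is computed on sum-normalized surfaces: scaling either is a no-op
  expect_equal(schoener_d(x * 3, y), schoener_d(x, y), tolerance = 1e-12)
  z <- g; z$values[] <- 0
  expect_error(schoener_d(z, b), "zero-sum")
})

test_that("coarsening preserves block means and triggers for large grids", {
  g <- sdm_grid(matrix(1:16, 4, 4), cell_size = 100)
  cg <- coarsen(g, 2)
  expect_equal(dim(cg$values), c(2, 2))
  expect_equal(cg$values[1, 1], mean(c(1, 2, 5, 6)))
  expect_equal(cg$cell_size, 200)
  # D via the coarse path equals D computed on pre-coarsened surfaces
  set.seed(4)
  x <- sdm_grid(matrix(runif(10000), 100, 100), 100)
  y <- sdm_grid(matrix(runif(10000), 100, 100), 100)
  expect_equal(schoener_d(x, y, max_cells = 2000),
               schoener_d(coarsen(x, 3), coarsen(y, 3)))
})

test_that("delta_d_geo arithmetic and edge cases", {
  expect_equal(round(delta_d_geo(0.921, 0.810), 3), 0.584)
  expect_equal(delta_d_geo(0.7, 0.7), 0)
  expect_equal(delta_d_geo(1, 0.4), 1)
  expect_error(delta_d_geo(0.9, 1), "d_biased")
})

test_that("the best-correction rule prefers omission-reducing corrections", {
  reports <- tibble::tibble(
    method = c("SR", "SR", "GK", "GK"),
    radius = c(4800, 9600, 4800, 9600),
    delta_d_geo = c(0.43, 0.58, 0.27, 0.43),
    mean_mtss_omission = c(0.42, 0.41, 0.25, 0.29))
  best <- select_best_correction(reports, raw_omission = 0.27)
  expect_equal(best$method, "GK")
  expect_equal(best$radius, 4800)
  expect_false(best$omission_constraint_unmet)
  # all corrections worsen omission: fall back to max delta_d_geo, flagged
  worse <- dplyr::mutate(reports, mean_mtss_omission = 0.5)
  fb <- select_best_correction(worse, raw_omission = 0.27)
  expect_true(fb$omission_constraint_unmet)
  expect_equal(fb$delta_d_geo, 0.58)
  expect_error(select_best_correction(reports[0, ], 0.3), "empty")
})

test_that("correction specs and the bias fit plan enumerate the full stage", {
  specs <- correction_specs()
  expect_equal(nrow(specs), 8)
  expect_setequal(unique(specs$radius), c(1200, 2400, 4800, 9600))
  expect_equal(nrow(correction_specs(include_raw = TRUE)), 9)
  plan <- bias_fit_plan(paste0("M", 1:5))
  expect_equal(nrow(plan), 40)
})

test_that("apply_correction routes SR, GK and RAW appropriately", {
  sp <- fixture_species()
  occ <- sample_occurrences(sp, 100, seed = 4)
  raw <- apply_correction(occ, "RAW")
  expect_identical(raw$occ, occ)
  expect_null(raw$bias)
  sr <- apply_correction(occ, "SR", 2400, seed = 1)
  expect_lt(nrow(sr$occ), nrow(occ))
  gk <- apply_correction(occ, "GK", 2400, grid = sp$suitability)
  expect_identical(gk$occ, occ)
  expect_s3_class(gk$bias, "sdm_grid")
})
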