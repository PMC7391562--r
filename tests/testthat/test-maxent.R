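# Maximum-entropy fitting against an independent convex-solver oracle, plus
# the normalization, invariance and recovery properties of the model.

# (the generic convex-solver oracle lives in helper-oracles.R)

test_that("the fit matches a generic convex-optimizer oracle on raw outputs", {
  for (seed in 1:5) {
    d <- make_design(seed = seed, p = 2)
    m <- fit_maxent(d, tol = 1e-10)
    spec <- m$spec
    Fb <- scalesdm:::expand_features(rbind(d$x_background, d$x_presence), spec)
    Fp <- scalesdm:::expand_features(d$x_presence, spec)
    lam_o <- oracle_fit(Fp, Fb, spec$beta)
    raw_mine <- raw_from_lambda(m$lambdas, Fb)
    raw_oracle <- raw_from_lambda(lam_o, Fb)
    expect_lt(max(abs(raw_mine - raw_oracle)), 1e-4)
  }
})

test_that("raw output normalizes to 1 and entropy is bounded by ln(n)", {
  d <- make_design(seed = 7)
  m <- fit_maxent(d)
  Fb <- scalesdm:::expand_features(rbind(d$x_background, d$x_presence), m$spec)
  raw <- raw_from_lambda(m$lambdas, Fb)
  expect_equal(sum(raw), 1, tolerance = 1e-8)
  expect_gte(m$entropy, 0)
  expect_lte(m$entropy, log(nrow(Fb)) + 1e-9)
})

test_that("no signal shrinks coefficients and the model toward uniform", {
  set.seed(11)
  d <- make_design(n_pres = 80, n_bg = 800, seed = 11, signal = 0)
  m <- fit_maxent(d)
  expect_lt(max(abs(m$lambdas)), 0.5)
  expect_gt(m$entropy, log(880) - 0.01)
  # logistic output of a near-uniform model is near 0.5
  s <- predict(m, d$x_background, type = "logistic")
  expect_lt(max(abs(s - 0.5)), 0.05)
})

test_that("a separating binary predictor gets a positive, capped coefficient", {
  set.seed(13)
  n_bg <- 400
  xb <- cbind(V1 = rep(c(0, 1), each = n_bg / 2), V2 = runif(n_bg))
  xp <- cbind(V1 = rep(1, 50), V2 = runif(50))
  d <- make_design(seed = 13)
  d$x_presence <- xp; d$x_background <- xb; d$train <- rep(TRUE, 50)
  m <- fit_maxent(d, tol = 1e-10)
  lin <- m$lambdas["V1"] + m$lambdas["V1^2"]  # total effect of V1 = 1 vs 0
  expect_gt(lin, 0)
  expect_lt(lin, 50)  # finite despite separation: the L1 penalty caps it
  spec <- m$spec
  Fb <- scalesdm:::expand_features(rbind(xb, xp), spec)
  Fp <- scalesdm:::expand_features(xp, spec)
  lam_o <- oracle_fit(Fp, Fb, spec$beta)
  expect_lt(max(abs(raw_from_lambda(m$lambdas, Fb) - raw_from_lambda(lam_o, Fb))),
            1e-4)
})

test_that("duplicating a predictor leaves the raw surface unchanged", {
  d <- make_design(seed = 17)
  m1 <- fit_maxent(d, tol = 1e-10)
  d2 <- d
  d2$x_presence <- cbind(d$x_presence, V1b = d$x_presence[, 1])
  d2$x_background <- cbind(d$x_background, V1b = d$x_background[, 1])
  colnames(d2$x_presence)[3] <- colnames(d2$x_background)[3] <- "V1b"
  m2 <- fit_maxent(d2, tol = 1e-10)
  r1 <- predict(m1, d$x_background, type = "raw")
  r2 <- predict(m2, d2$x_background, type = "raw")
  expect_lt(max(abs(r1 - r2)), 1e-4)
})

test_that("prediction is invariant under affine rescaling of a predictor", {
  d <- make_design(seed = 19)
  m1 <- fit_maxent(d, tol = 1e-10)
  d2 <- d
  d2$x_presence[, 1] <- 2 * d$x_presence[, 1] - 5
  d2$x_background[, 1] <- 2 * d$x_background[, 1] - 5
  m2 <- fit_maxent(d2, tol = 1e-10)
  expect_lt(max(abs(predict(m1, d$x_background, type = "raw") -
                    predict(m2, d2$x_background, type = "raw"))), 1e-6)
})

test_that("the fit never loses to the null model net of penalty", {
  for (seed in c(2, 23)) {
    d <- make_design(seed = seed)
    m <- fit_maxent(d)
    spec <- m$spec
    Fb <- scalesdm:::expand_features(rbind(d$x_background, d$x_presence), spec)
    Fp <- scalesdm:::expand_features(d$x_presence, spec)
    null_obj <- scalesdm:::maxent_objective(rep(0, length(m$lambdas)),
                                            colMeans(Fp), Fb, spec$beta)
    fit_obj <- scalesdm:::maxent_objective(m$lambdas, colMeans(Fp), Fb,
                                           spec$beta)
    expect_lte(fit_obj, null_obj + 1e-10)
  }
})

test_that("logistic output is a monotone, rank-preserving transform of raw", {
  d <- make_design(seed = 29)
  m <- fit_maxent(d)
  raw <- predict(m, d$x_background, type = "raw")
  lg <- predict(m, d$x_background, type = "logistic")
  expect_true(all(lg > 0 & lg < 1))
  expect_equal(cor(rank(raw), rank(lg)), 1)
  # uniform raw distribution maps to logistic 0.5 (c * q = 1)
  mu <- m
  mu$lambdas[] <- 0
  mu$logZ <- log(nrow(d$x_background) + nrow(d$x_presence))
  mu$entropy <- mu$logZ
  expect_equal(unname(predict(mu, d$x_background, type = "logistic")),
               rep(0.5, nrow(d$x_background)))
})

test_that("grid prediction propagates nodata and refuses missing layers", {
  b <- fixture_bundle()
  sp <- fixture_species()
  occ <- sample_occurrences(sp, 100, seed = 5)
  layers <- list(ELEV_600 = focal_stat(b$dem, 600, "mean"),
                 TEMP_300 = focal_stat(b$temperature, 300, "mean"))
  layers$ELEV_600$values[1:4, 1:4] <- NA
  mask <- buffer_mask(occ, b$dem, 28800)
  d <- build_design(occ, layers, mask, n_background = 1000, seed = 2)
  m <- fit_maxent(d)
  pr <- predict(m, layers)
  expect_true(all(is.na(pr$values[1:4, 1:4])))
  expect_true(all(pr$values[!is.na(pr$values)] >= 0))
  expect_error(predict(m, layers["ELEV_600"]), "missing layer")
})

test_that("design construction honours mask, bias and split bookkeeping", {
  b <- fixture_bundle()
  sp <- fixture_species()
  occ <- sample_occurrences(sp, 220, seed = 6)
  layers <- list(ELEV_600 = focal_stat(b$dem, 600, "mean"))
  mask <- buffer_mask(occ, b$dem, 10000)
  d <- build_design(occ, layers, mask, n_background = 2000, split = 0.75,
                    seed = 3)
  # 75-25 split of 220 presences: 165 train / 55 test
  expect_equal(sum(d$train), 165)
  expect_equal(sum(!d$train), 55)
  expect_true(all(mask$values[d$background_cells] == 1))
  expect_true(all(!is.na(d$x_background)))
  # pool smaller than request: whole pool with a warning
  small_mask <- buffer_mask(occ[1, ], b$dem, 500)
  expect_warning(d2 <- build_design(occ[1:25, ], layers, small_mask,
                                    n_background = 5000, seed = 1), "pool")
  expect_equal(length(d2$background_cells), sum(small_mask$values))
  # constant bias surface reproduces the uniform sampler in distribution
  flat <- b$dem; flat$values[] <- 0.7
  db <- build_design(occ, layers, mask, n_background = 2000, bias = flat,
                     seed = 3)
  du <- build_design(occ, layers, mask, n_background = 2000, seed = 3)
  ks <- suppressWarnings(ks.test(db$x_background[, 1], du$x_background[, 1]))
  expect_gt(ks$p.value, 0.01)
})

test_that("fitted linear effect recovers the generating sign across seeds", {
  b <- fixture_bundle()
  sp <- define_virtual_species(b, list(list(predictor = "dem", scale = 600,
                                            shape = "linear", coefficient = 2)))
  layers <- list(ELEV_600 = focal_stat(b$dem, 600, "mean"))
  hits <- 0
  for (seed in 1:10) {
    occ <- sample_occurrences(sp, 120, seed = seed)
    mask <- buffer_mask(occ, b$dem, 28800)
    d <- build_design(occ, layers, mask, n_background = 1500, seed = seed)
    m <- fit_maxent(d)
    if (m$lambdas["ELEV_600"] > 0) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
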