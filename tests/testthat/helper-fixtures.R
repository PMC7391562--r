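# Shared fixtures, built in code. The landscape bundle and virtual species
# used across files are generated once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture_bundle <- function() {
  if (is.null(.fixtures$bundle)) {
    .fixtures$bundle <- generate_landscape(c(128, 128), cell_size = 90,
                                           n_classes = 5, seed = 7)
  }
  .fixtures$bundle
}

fixture_species <- function() {
  if (is.null(.fixtures$species)) {
    .fixtures$species <- define_virtual_species(
      fixture_bundle(),
      list(list(predictor = "dem", scale = 1200, shape = "linear",
                coefficient = 3),
           list(predictor = "temperature", scale = 300, shape = "quadratic",
                coefficient = -2))
    )
  }
  .fixtures$species
}

# small flat grid with a given matrix
mgrid <- function(m, cell_size = 90) sdm_grid(m, cell_size = cell_size)

# brute-force focal statistic: per-cell loop over the disc
brute_focal <- function(grid, radius, stat = "mean") {
  v <- grid$values
  cs <- grid$cell_size
  nr <- nrow(v); nc <- ncol(v)
  out <- matrix(NA_real_, nr, nc)
  f <- switch(stat, mean = mean, sd = function(z) sqrt(mean((z - mean(z))^2)),
              min = min, max = max)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(v[i, j])) next
    acc <- c()
    for (a in seq_len(nr)) for (b in seq_len(nc)) {
      if (!is.na(v[a, b]) && ((a - i)^2 + (b - j)^2) * cs^2 <= radius^2) {
        acc <- c(acc, v[a, b])
      }
    }
    if (length(acc)) out[i, j] <- f(acc)
  }
  out
}

# clip a circular window out of a landcover matrix, NA outside the disc
clip_window <- function(v, i, j, radius, cell_size) {
  nr <- nrow(v); nc <- ncol(v)
  half <- floor(radius / cell_size)
  i_rng <- max(1, i - half):min(nr, i + half)
  j_rng <- max(1, j - half):min(nc, j + half)
  w <- v[i_rng, j_rng, drop = FALSE]
  for (a in seq_along(i_rng)) for (b in seq_along(j_rng)) {
    if (((i_rng[a] - i)^2 + (j_rng[b] - j)^2) * cell_size^2 > radius^2) {
      w[a, b] <- NA
    }
  }
  w
}

# in-memory design on uniform random predictors, presences biased toward
# high values of predictor 1 (signal strength tunable)
make_design <- function(n_pres = 60, n_bg = 500, p = 2, seed = 1,
                        signal = 1.5) {
  set.seed(seed)
  xb <- matrix(runif(n_bg * p), n_bg, p)
  xp <- matrix(runif(4 * n_pres * p), 4 * n_pres, p)
  keep <- runif(4 * n_pres) < plogis(signal * (2 * xp[, 1] - 1) * 4)
  xp <- xp[keep, , drop = FALSE][seq_len(n_pres), , drop = FALSE]
  colnames(xb) <- colnames(xp) <- paste0("V", seq_len(p))
  structure(list(x_presence = xp, x_background = xb,
                 presence_cells = seq_len(n_pres),
                 background_cells = seq_len(n_bg),
                 train = rep(TRUE, n_pres),
                 grid = list(cell_size = 90, origin = c(0, 0), crs = "t"),
                 n_background_requested = n_bg, split = 0.75, seed = seed,
                 biased = FALSE), class = "sdm_design")
}
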