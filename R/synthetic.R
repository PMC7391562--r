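# Synthetic landscapes and virtual species. The generator reproduces the
# statistical structure the pipeline assumes -- a smooth DEM, a patchy
# categorical landcover mosaic, a temperature field negatively coupled to
# elevation, and kernel-smoothed density surfaces for rivers, roads and
# settlements -- so every downstream stage can be exercised without any
# external GIS download.

#' Scale ladder for a grid extent
#'
#' The full scale ladder spans 300 m to 28,800 m. On small grids the larger
#' windows would not fit, so the ladder is truncated to 4,800 m for grids
#' under 700 cells a side.
#'
#' @param n_cells Smaller dimension of the grid, in cells.
#' @param cell_size Cell size, metres.
#' @return Numeric vector of window radii in metres.
#' @export
scale_ladder <- function(n_cells = 128, cell_size = 90) {
  full <- c(300, 600, 1200, 2400, 4800, 9600, 14400, 19200, 28800)
  if (n_cells >= 700) full else full[full <= 4800]
}

smooth_field <- function(nr, nc, sigma_cells) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  s <- conv2_same(z, gaussian_kernel(sigma_cells))
  (s - mean(s)) / stats::sd(s)
}

#' Generate a synthetic landscape bundle
#'
#' Produces co-registered raster layers: `dem` (elevation, m; a Gaussian-
#' filtered random field), `landcover` (integer classes `1..n_classes` by
#' quantile-thresholding a second smooth field, which guarantees contiguous
#' patches), `temperature` (deg C; a lapse-rate transform of the DEM plus
#' smooth noise, hence negatively correlated with elevation), and
#' `river_density` / `road_density` / `settlement_density` (kernel-smoothed
#' counts of random linear or weighted point features). All layers share
#' geometry and are deterministic in `seed`.
#'
#' @param extent_cells Length-2 integer, `c(nrow, ncol)`; at least 64 x 64.
#' @param cell_size Cell size in metres.
#' @param n_classes Number of landcover classes (1 to 10; 1 is the degenerate
#'   single-class landscape).
#' @param seed Integer seed; identical seeds give bit-identical bundles.
#' @param dem_sigma Correlation length of the DEM field, cells.
#' @param lc_sigma Correlation length of the landcover field, cells.
#' @return A list of class `landscape_bundle` with one `sdm_grid` per layer,
#'   plus `cell_size`, `seed` and the `ladder` of window radii.
#' @export
generate_landscape <- function(extent_cells = c(128, 128), cell_size = 90,
                               n_classes = 5, seed = 1,
                               dem_sigma = 4, lc_sigma = 8) {
  if (length(extent_cells) != 2L || any(extent_cells < 64)) {
    stop("extent must be at least 64 x 64 cells", call. = FALSE)
  }
  if (n_classes < 1 || n_classes > 10) {
    stop("n_classes must be between 1 and 10", call. = FALSE)
  }
  if (cell_size <= 0) stop("cell_size must be > 0", call. = FALSE)
  nr <- as.integer(extent_cells[1]); nc <- as.integer(extent_cells[2])
  set.seed(seed)
  g0 <- function(m) sdm_grid(m, cell_size = cell_size,
                             origin = c(0, nr * cell_size), crs = "synthetic-utm")

  dem <- 4500 + 600 * smooth_field(nr, nc, dem_sigma)

  lcf <- smooth_field(nr, nc, lc_sigma)
  if (n_classes == 1L) {
    lc <- matrix(1, nr, nc)
  } else {
    qs <- stats::quantile(lcf, probs = seq_len(n_classes - 1) / n_classes)
    lc <- matrix(findInterval(lcf, qs) + 1, nr, nc)
  }

  # environmental lapse rate 6.5 degC / km plus smooth local anomaly
  temp <- 32 - 0.0065 * dem + 0.8 * smooth_field(nr, nc, 6)

  seg_density <- function(n_seg, sigma_cells) {
    cnt <- matrix(0, nr, nc)
    for (s in seq_len(n_seg)) {
      r0 <- stats::runif(1, 1, nr); c0 <- stats::runif(1, 1, nc)
      ang <- stats::runif(1, 0, 2 * pi)
      len <- stats::runif(1, 0.2, 0.8) * min(nr, nc)
      tt <- seq(0, len, by = 0.5)
      ri <- pmin(pmax(round(r0 + tt * sin(ang)), 1), nr)
      ci <- pmin(pmax(round(c0 + tt * cos(ang)), 1), nc)
      cells <- unique(cbind(ri, ci))
      cnt[cells] <- cnt[cells] + 1
    }
    pmax(conv2_same(cnt, gaussian_kernel(sigma_cells)), 0) * (1000 / cell_size)
  }
  riv <- seg_density(round(nr * nc / 1300), sigma_cells = 4)
  rd <- seg_density(round(nr * nc / 2700), sigma_cells = 4)

  n_set <- round(nr * nc / 500)
  wts <- sample(1:4, n_set, replace = TRUE, prob = c(0.45, 0.3, 0.15, 0.1))
  cnt <- matrix(0, nr, nc)
  ri <- sample.int(nr, n_set, replace = TRUE)
  ci <- sample.int(nc, n_set, replace = TRUE)
  for (s in seq_len(n_set)) cnt[ri[s], ci[s]] <- cnt[ri[s], ci[s]] + wts[s]
  setd <- pmax(conv2_same(cnt, gaussian_kernel(6)), 0) * (1000 / cell_size)^2

  structure(
    list(dem = g0(dem), landcover = g0(lc), temperature = g0(temp),
         river_density = g0(riv), road_density = g0(rd),
         settlement_density = g0(setd),
         cell_size = cell_size, seed = seed,
         ladder = scale_ladder(min(nr, nc), cell_size)),
    class = "landscape_bundle"
  )
}

#' @export
print.landscape_bundle <- function(x, ...) {
  cat(sprintf("<landscape_bundle> %d x %d cells at %g m (seed %d)\n",
              nrow(x$dem$values), ncol(x$dem$values), x$cell_size, x$seed))
  cat("  layers: dem, landcover (", length(unique(as.vector(x$landcover$values))),
      "classes ), temperature, river/road/settlement density\n")
  cat("  ladder:", paste(x$ladder, collapse = ", "), "m\n")
  invisible(x)
}

continuous_layers <- function(bundle) {
  c("dem", "temperature", "river_density", "road_density", "settlement_density")
}

#' Define a virtual species on a synthetic landscape
#'
#' Suitability is the inverse logit of a linear/quadratic combination of
#' focal-mean predictors, each standardized and summarized at a declared
#' window radius, then min-max rescaled to `[0, 1]`. An empty term list gives
#' the constant 0.5 surface. The declared terms are the species' ground
#' truth, against which scale-recovery and bias-correction experiments are
#' graded.
#'
#' @param bundle A `landscape_bundle`.
#' @param terms List of terms, each `list(predictor=, scale=, shape=,
#'   coefficient=)` with `shape` `"linear"` or `"quadratic"`. `predictor`
#'   must name a continuous bundle layer and `scale` must be in the bundle's
#'   ladder.
#' @param n_presences Nominal presence count carried as metadata.
#' @return List of class `virtual_species` with `suitability` (`sdm_grid`),
#'   `terms`, and `n_presences`.
#' @export
define_virtual_species <- function(bundle, terms = list(), n_presences = 200) {
  stopifnot(inherits(bundle, "landscape_bundle"))
  lp <- matrix(0, nrow(bundle$dem$values), ncol(bundle$dem$values))
  for (tm in terms) {
    if (!tm$predictor %in% continuous_layers(bundle)) {
      stop("unknown predictor: ", tm$predictor, call. = FALSE)
    }
    if (!tm$scale %in% bundle$ladder) {
      stop("scale ", tm$scale, " not in the configured ladder", call. = FALSE)
    }
    if (!tm$shape %in% c("linear", "quadratic")) {
      stop("shape must be linear or quadratic", call. = FALSE)
    }
    f <- focal_stat(bundle[[tm$predictor]], tm$scale, "mean")$values
    z <- (f - mean(f, na.rm = TRUE)) / stats::sd(f, na.rm = TRUE)
    lp <- lp + tm$coefficient * (if (tm$shape == "quadratic") z^2 else z)
  }
  s <- stats::plogis(lp)
  rng <- range(s, na.rm = TRUE)
  if (diff(rng) > 0) s <- (s - rng[1]) / diff(rng)
  suit <- bundle$dem
  suit$values <- s
  structure(list(suitability = suit, terms = terms,
                 n_presences = n_presences, bundle_seed = bundle$seed),
            class = "virtual_species")
}

#' Sample occurrence points from a virtual species
#'
#' Unbiased design: cells are rejection-sampled with acceptance probability
#' proportional to suitability, so occurrence density tracks the true
#' surface. Clustered design: candidate cells are first restricted to discs
#' of `cluster_radius` around randomly placed centers (emulating camera/
#' transect survey clustering), then rejection-sampled the same way.
#' Coordinates snap to cell centers and are deduplicated, so the returned
#' points are unique cells.
#'
#' @param species A `virtual_species`.
#' @param n Number of unique points required.
#' @param design `"unbiased"` or `"clustered"`.
#' @param cluster_centers Number of cluster centers (clustered design).
#' @param cluster_radius Disc radius around each center, metres.
#' @param center_weights Optional `sdm_grid` of non-negative weights for the
#'   cluster-center draw (e.g. an accessibility surface), making the survey
#'   bias systematic rather than random; `NULL` places centers uniformly.
#' @param seed Integer seed.
#' @return Tibble `x`, `y`, `source = "simulated"`.
#' @export
sample_occurrences <- function(species, n, design = c("unbiased", "clustered"),
                               cluster_centers = 5, cluster_radius = 5000,
                               center_weights = NULL, seed = 1) {
  design <- match.arg(design)
  stopifnot(n >= 1)
  grid <- species$suitability
  s <- grid$values
  pool <- which(!is.na(s) & s > 0)
  if (length(pool) < n) stop("suitability has fewer positive cells than n",
                             call. = FALSE)
  set.seed(seed)
  if (design == "clustered") {
    cand <- which(!is.na(s))
    if (is.null(center_weights)) {
      centers <- sample(cand, cluster_centers)
    } else {
      check_same_geometry(grid, center_weights, "suitability and center weights")
      w <- center_weights$values[cand]
      if (any(is.na(w) | w < 0)) {
        stop("center_weights must be non-negative where suitability is valid",
             call. = FALSE)
      }
      centers <- sample(cand, cluster_centers, prob = w)
    }
    nr <- nrow(s)
    crow <- ((centers - 1) %% nr) + 1
    ccol <- ((centers - 1) %/% nr) + 1
    prow <- ((pool - 1) %% nr) + 1
    pcol <- ((pool - 1) %/% nr) + 1
    r_cells2 <- (cluster_radius / grid$cell_size)^2
    keep <- rep(FALSE, length(pool))
    for (k in seq_along(centers)) {
      keep <- keep | ((prow - crow[k])^2 + (pcol - ccol[k])^2) <= r_cells2
    }
    pool <- pool[keep]
    if (length(pool) < n) {
      stop(sprintf("clustered candidate pool (%d cells) smaller than n = %d",
                   length(pool), n), call. = FALSE)
    }
  }
  # successive rejection sampling with deduplication is distributionally
  # identical to sequential weighted draws without replacement
  w <- s[pool]
  if (sum(w > 0) < n) {
    stop("sampling exhausted before placing n unique points", call. = FALSE)
  }
  chosen <- pool[sample.int(length(pool), n, prob = w)]
  nr <- nrow(s)
  row <- ((chosen - 1) %% nr) + 1
  col <- ((chosen - 1) %/% nr) + 1
  cc <- cell_centers(grid)
  out <- tibble::tibble(x = cc$x[col], y = cc$y[row], source = "simulated")
  attr(out, "dataset_tag") <- if (design == "clustered") "RD" else "FR"
  out
}

#' Write a landscape bundle to disk
#'
#' One ESRI ASCII grid per layer plus a JSON sidecar with the cell size,
#' seed and scale ladder.
#'
#' @param bundle A `landscape_bundle`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c(continuous_layers(bundle), "landcover")) {
    write_grid(bundle[[nm]], file.path(dir, paste0(nm, ".asc")))
  }
  jsonlite::write_json(
    list(cell_size = bundle$cell_size, seed = bundle$seed,
         ladder = bundle$ladder),
    file.path(dir, "bundle.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Write occurrences and virtual-species truth
#'
#' @param occ Occurrence tibble (`x`, `y`, `source`).
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(occ[, c("x", "y", "source")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrences
#' @param species A `virtual_species`.
#' @export
write_species_truth <- function(species, path) {
  jsonlite::write_json(
    list(terms = species$terms, n_presences = species$n_presences,
         bundle_seed = species$bundle_seed),
    path, auto_unbox = TRUE)
  invisible(path)
}
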