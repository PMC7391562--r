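# Sampling-bias correction and ensemble overlap. Two correction families:
# spatial rarefaction (SR: thin occurrences to a minimum pairwise distance)
# and Gaussian-kernel bias surfaces (GK: weight the background sample by the
# estimated survey intensity). Ensembles of the top five models are scored
# against a simulated unbiased reference ensemble with Schoener's D, and the
# improvement is expressed as the fraction of the remaining gap closed
# (delta D_geo).

#' Correction specifications
#'
#' The eight corrections evaluated by the bias stage: SR and GK at radii
#' 1,200, 2,400, 4,800 and 9,600 m; optionally the uncorrected RAW row.
#'
#' @param radii Correction radii, metres.
#' @param include_raw Prepend the RAW (no correction) row.
#' @return Tibble with `method` (`"RAW"`, `"SR"`, `"GK"`) and `radius`
#'   (`NA` for RAW).
#' @export
correction_specs <- function(radii = c(1200, 2400, 4800, 9600),
                             include_raw = FALSE) {
  out <- tidyr::crossing(method = c("SR", "GK"), radius = radii) |>
    dplyr::arrange(.data$method, .data$radius)
  if (include_raw) {
    out <- dplyr::bind_rows(tibble::tibble(method = "RAW", radius = NA_real_),
                            out)
  }
  out
}

#' Plan of bias-stage model fits
#'
#' One refit per (model, correction) pair; with the default five retained
#' models and eight corrections this is the 40-fit correction stage.
#'
#' @param model_ids Identifiers of the retained models.
#' @param specs Tibble from [correction_specs()].
#' @return Tibble with `model_id`, `method`, `radius`.
#' @export
bias_fit_plan <- function(model_ids, specs = correction_specs()) {
  tidyr::crossing(model_id = model_ids, specs) |>
    dplyr::arrange(.data$model_id, .data$method, .data$radius)
}

#' Spatial rarefaction (occurrence thinning)
#'
#' Greedy thinning: points are shuffled by `seed`, then kept iff at least
#' `radius` from every already-kept point, so the returned subset has
#' minimum pairwise distance >= `radius` and is maximal under the visiting
#' order.
#'
#' @param occ Occurrence tibble (`x`, `y`).
#' @param radius Minimum pairwise distance, metres (> 0).
#' @param seed Shuffle seed.
#' @return Thinned occurrence tibble (a subset of `occ`).
#' @export
rarefy <- function(occ, radius, seed = 1) {
  stopifnot(radius > 0)
  n <- nrow(occ)
  if (n <= 1) return(occ)
  set.seed(seed)
  ord <- sample.int(n)
  kept <- integer(0)
  r2 <- radius^2
  for (i in ord) {
    if (!length(kept) ||
        all((occ$x[kept] - occ$x[i])^2 + (occ$y[kept] - occ$y[i])^2 >= r2)) {
      kept <- c(kept, i)
    }
  }
  occ[sort(kept), ]
}

#' Gaussian-kernel bias surface
#'
#' Per cell, the sum over occurrences of `exp(-d^2 / (2 sigma^2))` with
#' `sigma = bandwidth`, rescaled to `(1e-6, 1]` (the floor keeps every cell
#' available to the weighted background sampler). Pass the result as the
#' `bias` argument of [build_design()] to apply a GK correction.
#'
#' @param occ Occurrence tibble (`x`, `y`).
#' @param bandwidth Kernel standard deviation, metres (> 0).
#' @param grid Reference `sdm_grid`.
#' @return An `sdm_grid` of sampling weights.
#' @export
kernel_surface <- function(occ, bandwidth, grid) {
  stopifnot(bandwidth > 0)
  cc <- cell_centers(grid)
  v <- matrix(0, nrow(grid$values), ncol(grid$values))
  inv2s2 <- 1 / (2 * bandwidth^2)
  for (k in seq_len(nrow(occ))) {
    dx2 <- (cc$x - occ$x[k])^2
    dy2 <- (cc$y - occ$y[k])^2
    v <- v + exp(-outer(dy2, dx2, "+") * inv2s2)
  }
  v <- v / max(v)
  v <- pmax(v, 1e-6)
  v[is.na(grid$values)] <- NA_real_
  out <- grid
  out$values <- v
  out
}

#' Apply a correction to an occurrence set
#'
#' SR returns a rarefied occurrence set; GK returns the original set plus a
#' kernel bias surface for background weighting; RAW returns both untouched.
#'
#' @param occ Occurrence tibble.
#' @param method `"RAW"`, `"SR"` or `"GK"`.
#' @param radius Correction radius / kernel bandwidth, metres.
#' @param grid Reference `sdm_grid` (needed for GK).
#' @param seed Seed for the SR shuffle.
#' @return List with `occ` and `bias` (`NULL` unless GK).
#' @export
apply_correction <- function(occ, method, radius = NA, grid = NULL, seed = 1) {
  method <- match.arg(method, c("RAW", "SR", "GK"))
  switch(method,
    RAW = list(occ = occ, bias = NULL),
    SR = list(occ = rarefy(occ, radius, seed = seed), bias = NULL),
    GK = list(occ = occ, bias = kernel_surface(occ, radius, grid))
  )
}

#' Simulate reference pseudo-occurrences from top-model surfaces
#'
#' One shared U(0,1) raster is subtracted from each of the five reference
#' suitability surfaces and the differences are summed into a cumulative
#' potential surface. A cloud of `n_cloud` uniform random points is dropped
#' on the full extent; points on cells with positive cumulative potential
#' are candidates. Mode `"FR"` (full random) subsamples `n` of them
#' directly; mode `"SB"` (simulated biased) first clips the candidates to a
#' buffer mask around the original occurrences, reproducing their geographic
#' bias.
#'
#' @param surfaces List of five suitability `sdm_grid`s on a common grid,
#'   values in `[0, 1]`.
#' @param n Number of pseudo-occurrences to return.
#' @param mode `"FR"` or `"SB"`.
#' @param buffer Binary `sdm_grid` (required for `"SB"`).
#' @param n_cloud Size of the uniform point cloud (default 50,000).
#' @param seed Integer seed.
#' @return Occurrence tibble with `source = "simulated"` and the mode as
#'   `dataset_tag` attribute.
#' @export
simulate_reference_occurrences <- function(surfaces, n, mode = c("FR", "SB"),
                                           buffer = NULL, n_cloud = 50000,
                                           seed = 1) {
  mode <- match.arg(mode)
  stopifnot(length(surfaces) >= 1)
  ref <- surfaces[[1]]
  for (s in surfaces) check_same_geometry(ref, s, "reference surfaces")
  if (mode == "SB") {
    if (is.null(buffer)) stop("SB mode requires a buffer mask", call. = FALSE)
    check_same_geometry(ref, buffer, "buffer and surfaces")
  }
  set.seed(seed)
  nr <- nrow(ref$values); nc <- ncol(ref$values)
  u <- matrix(stats::runif(nr * nc), nr, nc)
  cum <- Reduce(`+`, lapply(surfaces, function(s) s$values - u))
  cs <- ref$cell_size
  px <- ref$origin[1] + stats::runif(n_cloud) * nc * cs
  py <- ref$origin[2] - stats::runif(n_cloud) * nr * cs
  pc <- points_to_cells(px, py, ref)
  ok <- !is.na(cum[pc$cell]) & cum[pc$cell] > 0
  if (mode == "SB") ok <- ok & buffer$values[pc$cell] == 1
  cand <- which(ok)
  if (length(cand) < n) {
    stop(sprintf("simulation exhausted: only %d candidate points (< %d)",
                 length(cand), n), call. = FALSE)
  }
  sel <- cand[sample.int(length(cand), n)]
  out <- tibble::tibble(x = px[sel], y = py[sel], source = "simulated")
  attr(out, "dataset_tag") <- mode
  out
}

#' Ensemble of suitability surfaces
#'
#' Cell-wise mean of the member logistic surfaces, min-max rescaled to
#' `[0, 1]` over valid cells.
#'
#' @param surfaces List of member `sdm_grid`s (conventionally the top five
#'   models under one correction).
#' @param correction Optional label (e.g. `"GK4800"`) carried as an
#'   attribute.
#' @return An `sdm_grid` of class `ensemble_surface`.
#' @export
ensemble_surface <- function(surfaces, correction = NULL) {
  stopifnot(length(surfaces) >= 1)
  ref <- surfaces[[1]]
  for (s in surfaces) check_same_geometry(ref, s, "ensemble members")
  m <- Reduce(`+`, lapply(surfaces, function(s) s$values)) / length(surfaces)
  rng <- range(m, na.rm = TRUE)
  if (diff(rng) > 0) m <- (m - rng[1]) / diff(rng)
  out <- ref
  out$values <- m
  class(out) <- c("ensemble_surface", class(out))
  attr(out, "correction") <- correction
  attr(out, "n_members") <- length(surfaces)
  out
}

#' Block-aggregate a grid by an integer factor
#'
#' Mean over `factor x factor` blocks (NA-aware); used to bring very large
#' surfaces to a common coarse lattice before overlap computation.
#'
#' @param grid An `sdm_grid`.
#' @param factor Integer aggregation factor.
#' @return An `sdm_grid` with `factor`-times larger cells.
#' @export
coarsen <- function(grid, factor) {
  factor <- as.integer(factor)
  if (factor <= 1) return(grid)
  v <- grid$values
  nr <- (nrow(v) %/% factor) * factor
  nc <- (ncol(v) %/% factor) * factor
  v <- v[seq_len(nr), seq_len(nc), drop = FALSE]
  arr <- array(v, dim = c(factor, nr %/% factor, factor, nc %/% factor))
  m <- apply(arr, c(2, 4), function(b) {
    if (all(is.na(b))) NA_real_ else mean(b, na.rm = TRUE)
  })
  sdm_grid(m, cell_size = grid$cell_size * factor, origin = grid$origin,
           crs = grid$crs)
}

#' Schoener's D niche overlap in geographic space
#'
#' Both surfaces are normalized to sum to one over the cells valid in both
#' (turning each into a probability distribution over pixels), then
#' `D = 1 - 0.5 * sum_i |p_x,i - p_y,i|`: 1 for identical surfaces, 0 for
#' disjoint support. Surfaces larger than `max_cells` are block-aggregated
#' to a common coarse lattice first.
#'
#' @param x,y `sdm_grid` / `ensemble_surface` objects on a common geometry.
#' @param max_cells Coarsen above this cell count (default 250,000).
#' @return D in `[0, 1]`.
#' @export
schoener_d <- function(x, y, max_cells = 250000) {
  check_same_geometry(x, y, "overlap surfaces")
  if (length(x$values) > max_cells) {
    f <- ceiling(sqrt(length(x$values) / max_cells))
    x <- coarsen(x, f); y <- coarsen(y, f)
  }
  ok <- !is.na(x$values) & !is.na(y$values)
  px <- x$values[ok]; py <- y$values[ok]
  sx <- sum(px); sy <- sum(py)
  if (sx <= 0 || sy <= 0) stop("zero-sum surface; cannot normalize", call. = FALSE)
  1 - 0.5 * sum(abs(px / sx - py / sy))
}

#' Fraction of the overlap gap closed by a correction
#'
#' `(D_corrected - D_biased) / (1 - D_biased)`: 0 means no improvement over
#' the uncorrected model, 1 means the correction recovers the reference
#' model exactly; negative values mean the correction moved the ensemble
#' further from the reference.
#'
#' @param d_corrected D between the corrected ensemble and the reference.
#' @param d_biased D between the uncorrected ensemble and the reference
#'   (must be < 1).
#' @return The improvement fraction (<= 1).
#' @export
delta_d_geo <- function(d_corrected, d_biased) {
  if (any(d_biased >= 1)) {
    stop("d_biased must be < 1 (uncorrected model already identical)",
         call. = FALSE)
  }
  (d_corrected - d_biased) / (1 - d_biased)
}

#' Select the best bias correction
#'
#' Among corrections that reduce the mean MTSS omission rate below the
#' uncorrected (RAW) value and have positive `delta_d_geo`, returns the one
#' maximizing `delta_d_geo`. If no correction satisfies the omission
#' constraint, the global `delta_d_geo` maximum is returned flagged
#' `omission_constraint_unmet`.
#'
#' @param reports Tibble with one row per correction: `method`, `radius`,
#'   `delta_d_geo`, `mean_mtss_omission`.
#' @param raw_omission Mean MTSS omission of the uncorrected models.
#' @return One-row tibble with the winning correction and a logical
#'   `omission_constraint_unmet` column.
#' @export
select_best_correction <- function(reports, raw_omission) {
  if (!nrow(reports)) stop("empty report list", call. = FALSE)
  ok <- reports$mean_mtss_omission < raw_omission & reports$delta_d_geo > 0
  if (any(ok)) {
    pool <- reports[ok, ]
    flag <- FALSE
  } else {
    pool <- reports
    flag <- TRUE
  }
  best <- pool[order(-pool$delta_d_geo, pool$method, pool$radius), ][1, ]
  dplyr::mutate(best, omission_constraint_unmet = flag)
}
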