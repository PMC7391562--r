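# Topographic predictors derived from a DEM. Slope position is the
# topographic position index (elevation minus circular focal mean),
# roughness the windowed standard deviation, dissection the Martonne relief
# ratio, and CTI the compound topographic (wetness) index built on D8 flow
# accumulation. These are the standard geomorphometric-toolbox definitions.

#' Slope position (topographic position index)
#'
#' `dem - focal_mean(dem, radius)`: positive on ridges and upper slopes,
#' negative in valleys, zero on flat or planar terrain.
#'
#' @param dem Elevation `sdm_grid`, metres.
#' @param radius Window radius, metres.
#' @return An `sdm_grid`.
#' @export
slope_position <- function(dem, radius) {
  out <- dem
  out$values <- dem$values - focal_stat(dem, radius, "mean")$values
  out
}

#' Terrain roughness
#'
#' Standard deviation of elevation within the circular window (population
#' form). Zero on constant terrain; scales linearly with elevation relief.
#'
#' @inheritParams slope_position
#' @return An `sdm_grid`.
#' @export
roughness <- function(dem, radius) {
  focal_stat(dem, radius, "sd")
}

#' Martonne dissection
#'
#' `(z - z_min) / (z_max - z_min)` over the circular window; 0 by convention
#' where the window is flat. 1 at the window maximum, 0 at the minimum.
#'
#' @inheritParams slope_position
#' @return An `sdm_grid` in `[0, 1]`.
#' @export
dissection <- function(dem, radius) {
  lo <- focal_stat(dem, radius, "min")$values
  hi <- focal_stat(dem, radius, "max")$values
  rng <- hi - lo
  out <- dem
  out$values <- ifelse(is.na(rng) | rng == 0, ifelse(is.na(rng), NA_real_, 0),
                       (dem$values - lo) / rng)
  out$values[is.na(dem$values)] <- NA_real_
  out
}

# D8 neighbour offsets in the fixed tie-break order E, SE, S, SW, W, NW, N, NE
d8_offsets <- function() {
  list(dr = c(0, 1, 1, 1, 0, -1, -1, -1),
       dc = c(1, 1, 0, -1, -1, -1, 0, 1),
       dist = c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2)))
}

#' D8 flow direction and accumulation
#'
#' Single-direction (D8) routing: each cell drains to the neighbour with the
#' steepest positive descent; slope ties are broken deterministically in the
#' order E, SE, S, SW, W, NW, N, NE. Cells with no downhill neighbour are
#' sinks. Accumulation counts the number of upstream contributing cells
#' (excluding the cell itself), resolved by processing cells in decreasing
#' elevation order.
#'
#' @param dem Elevation `sdm_grid`. Nodata cells are treated as terminals.
#' @return List with `direction` (1-8 index into the offset order, NA for
#'   sinks) and `accumulation` matrices.
#' @export
d8_flow <- function(dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  off <- d8_offsets()
  dirn <- matrix(NA_integer_, nr, nc)
  best <- matrix(0, nr, nc)  # best positive drop so far
  for (k in 1:8) {
    zn <- matrix(NA_real_, nr, nc)
    i_src <- max(1L, 1L - off$dr[k]):min(nr, nr - off$dr[k])
    j_src <- max(1L, 1L - off$dc[k]):min(nc, nc - off$dc[k])
    zn[i_src, j_src] <- z[i_src + off$dr[k], j_src + off$dc[k]]
    drop <- (z - zn) / (off$dist[k] * dem$cell_size)
    better <- !is.na(drop) & drop > best
    dirn[better] <- k
    best[better] <- drop[better]
  }
  acc <- matrix(0, nr, nc)
  ord <- order(z, decreasing = TRUE, na.last = NA)
  rows <- ((ord - 1L) %% nr) + 1L
  cols <- ((ord - 1L) %/% nr) + 1L
  for (t in seq_along(ord)) {
    k <- dirn[ord[t]]
    if (is.na(k)) next
    ti <- rows[t] + off$dr[k]; tj <- cols[t] + off$dc[k]
    if (ti < 1 || ti > nr || tj < 1 || tj > nc || is.na(z[ti, tj])) next
    acc[ti, tj] <- acc[ti, tj] + acc[ord[t]] + 1
  }
  acc[is.na(z)] <- NA_real_
  list(direction = dirn, accumulation = acc)
}

horn_slope <- function(dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  # replicate-pad edges so the 3x3 operator is defined everywhere
  zp <- z[c(1, 1:nr, nr), c(1, 1:nc, nc)]
  sh <- function(di, dj) zp[(1:nr) + 1 + di, (1:nc) + 1 + dj]
  dzdx <- ((sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
             (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))) / (8 * dem$cell_size)
  dzdy <- ((sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
             (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))) / (8 * dem$cell_size)
  atan(sqrt(dzdx^2 + dzdy^2))
}

#' Compound topographic index (wetness index)
#'
#' `ln(a_s / tan(beta))` with specific catchment area proxied by
#' `(D8 accumulation + 1) * cell_size` and slope `beta` from the Horn 3x3
#' finite-difference operator, floored at 0.001 rad to avoid the log
#' singularity on flats. Higher in valleys and flats than on ridges. Computed
#' at native resolution; average to the scale ladder with [focal_stat()].
#'
#' @param dem Elevation `sdm_grid`.
#' @return An `sdm_grid`.
#' @export
cti <- function(dem) {
  if (all(is.na(dem$values))) stop("DEM is entirely nodata", call. = FALSE)
  fl <- d8_flow(dem)
  beta <- pmax(horn_slope(dem), 0.001)
  a_s <- (fl$accumulation + 1) * dem$cell_size
  out <- dem
  out$values <- log(a_s / tan(beta))
  out$values[is.na(dem$values)] <- NA_real_
  out
}
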