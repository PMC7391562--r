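# Circular moving-window engine. Every "scale" in the package is the radius
# (metres) of a disc of cells whose centers lie within that distance of the
# focal cell center; the same disc definition is shared by terrain metrics,
# landscape metrics and buffer logic.

#' Binary disc kernel for a given radius
#'
#' @param radius Window radius in metres.
#' @param cell_size Cell size in metres.
#' @return 0/1 matrix with odd dimensions; the center cell is always included
#'   (its distance is zero).
#' @export
disc_kernel <- function(radius, cell_size) {
  half <- floor(radius / cell_size)
  off <- (-half):half
  d2 <- outer(off^2, off^2, "+") * cell_size^2
  k <- (d2 <= radius^2) * 1
  storage.mode(k) <- "double"
  k
}

# 2-D "same" convolution of matrix x with a (symmetric) 0/1 or weight kernel.
# Direct summation for small problems (exact arithmetic); FFT for large ones.
# Both are deterministic.
conv2_same <- function(x, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  stopifnot(kr %% 2 == 1, kc %% 2 == 1)
  work <- as.numeric(sum(kernel != 0)) * length(x)
  if (work <= 4e6) conv2_direct(x, kernel) else conv2_fft(x, kernel)
}

conv2_direct <- function(x, kernel) {
  nr <- nrow(x); nc <- ncol(x)
  hr <- (nrow(kernel) - 1L) / 2L; hc <- (ncol(kernel) - 1L) / 2L
  out <- matrix(0, nr, nc)
  idx <- which(kernel != 0, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    di <- idx[k, 1] - hr - 1L; dj <- idx[k, 2] - hc - 1L
    w <- kernel[idx[k, 1], idx[k, 2]]
    # out[i, j] += w * x[i + di, j + dj] where indices stay in range
    if (1L - di > nr - di || 1L - dj > nc - dj) next
    i0 <- max(1L, 1L - di); i1 <- min(nr, nr - di)
    j0 <- max(1L, 1L - dj); j1 <- min(nc, nc - dj)
    if (i0 > i1 || j0 > j1) next
    i_out <- i0:i1; j_out <- j0:j1
    out[i_out, j_out] <- out[i_out, j_out] + w * x[i_out + di, j_out + dj]
  }
  out
}

conv2_fft <- function(x, kernel) {
  nr <- nrow(x); nc <- ncol(x)
  kr <- nrow(kernel); kc <- ncol(kernel)
  pr <- nr + kr - 1L; pc <- nc + kc - 1L
  px <- matrix(0, pr, pc); px[1:nr, 1:nc] <- x
  pk <- matrix(0, pr, pc); pk[1:kr, 1:kc] <- kernel
  conv <- Re(stats::fft(stats::fft(px) * stats::fft(pk), inverse = TRUE)) / (pr * pc)
  hr <- (kr - 1L) / 2L; hc <- (kc - 1L) / 2L
  conv[(hr + 1L):(hr + nr), (hc + 1L):(hc + nc)]
}

#' Focal statistic over a circular window
#'
#' Per-cell statistic of all valid cells whose centers fall within `radius`
#' of the focal cell center (the focal cell is included). Nodata neighbours
#' are excluded from the statistic; the output is nodata where the focal cell
#' is nodata or the window holds no valid cell. The standard deviation is the
#' population form (divisor n).
#'
#' @param grid Input `sdm_grid`.
#' @param radius Window radius, metres (>= cell_size / 2).
#' @param stat One of `"mean"`, `"sd"`, `"min"`, `"max"`.
#' @return An `sdm_grid` with the same geometry.
#' @examples
#' g <- sdm_grid(matrix(1, 5, 5), cell_size = 90)
#' focal_stat(g, radius = 135, stat = "mean")$values[3, 3]  # 1
#' @export
focal_stat <- function(grid, radius, stat = c("mean", "sd", "min", "max")) {
  stat <- match.arg(stat)
  cs <- grid$cell_size
  if (radius < cs / 2) stop("radius must be at least half a cell size", call. = FALSE)
  v <- grid$values
  valid <- !is.na(v)
  kern <- disc_kernel(radius, cs)
  out <- grid
  if (stat %in% c("mean", "sd")) {
    # center values first: the windowed SD is shift-invariant and centering
    # avoids cancellation error in E[x^2] - E[x]^2 for large-magnitude fields
    mu0 <- mean(v[valid])
    x0 <- ifelse(valid, v - mu0, 0)
    cnt <- round(conv2_same(valid * 1, kern))
    s1 <- conv2_same(x0, kern)
    m <- ifelse(cnt > 0, s1 / cnt, NA_real_)
    if (stat == "mean") {
      res <- m + mu0
    } else {
      s2 <- conv2_same(x0^2, kern)
      varp <- pmax(ifelse(cnt > 0, s2 / cnt, NA_real_) - m^2, 0)
      res <- sqrt(varp)
    }
  } else {
    res <- matrix(if (stat == "min") Inf else -Inf, nrow(v), ncol(v))
    x0 <- v
    x0[!valid] <- if (stat == "min") Inf else -Inf
    nr <- nrow(v); nc <- ncol(v)
    hr <- (nrow(kern) - 1L) / 2L
    idx <- which(kern != 0, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      di <- idx[k, 1] - hr - 1L; dj <- idx[k, 2] - hr - 1L
      i0 <- max(1L, 1L - di); i1 <- min(nr, nr - di)
      j0 <- max(1L, 1L - dj); j1 <- min(nc, nc - dj)
      if (i0 > i1 || j0 > j1) next
      i_out <- i0:i1; j_out <- j0:j1
      sub <- x0[i_out + di, j_out + dj, drop = FALSE]
      cur <- res[i_out, j_out, drop = FALSE]
      res[i_out, j_out] <- if (stat == "min") pmin(cur, sub) else pmax(cur, sub)
    }
    res[!is.finite(res)] <- NA_real_
  }
  res[!valid] <- NA_real_
  out$values <- res
  out
}

# Gaussian smoothing kernel truncated at `trunc` standard deviations,
# normalized to sum 1. sigma in cells.
gaussian_kernel <- function(sigma_cells, trunc = 3) {
  half <- max(1L, ceiling(sigma_cells * trunc))
  off <- (-half):half
  k <- exp(-outer(off^2, off^2, "+") / (2 * sigma_cells^2))
  k / sum(k)
}
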