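# FRAGSTATS-style landscape-pattern metrics over circular moving windows.
# Patch definition uses 8-neighbour connectivity by default; adjacency
# accounting for AI and edge metrics is rook (4-neighbour), single-count.
# Windows are clipped before metric computation and the window border itself
# contributes no edge.

#' Label patches (connected components of equal class)
#'
#' Run-based connected-component labeling with union-find. Nodata cells are
#' unlabeled (0). Labels are dense, numbered in order of first appearance
#' (row-major), so the labeling is deterministic.
#'
#' @param landcover Integer-coded `sdm_grid` or matrix; `NA` = nodata.
#' @param connectivity 4 or 8 (default 8, the FRAGSTATS patch rule).
#' @return List with `labels` (integer matrix, 0 = unlabeled), `patch_class`
#'   and `patch_cells` (per-label vectors).
#' @export
label_patches <- function(landcover, connectivity = 8) {
  v <- if (inherits(landcover, "sdm_grid")) landcover$values else landcover
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(v); nc <- ncol(v)
  parent <- integer(0)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  reach <- if (connectivity == 8) 1L else 0L
  run_start <- integer(0); run_end <- integer(0)
  run_class <- numeric(0); run_row <- integer(0)
  row_runs <- vector("list", nr)
  prev_runs <- integer(0)
  for (i in seq_len(nr)) {
    rowv <- v[i, ]
    ok <- which(!is.na(rowv))
    cur <- integer(0)
    if (length(ok)) {
      brk <- c(TRUE, diff(ok) > 1 | rowv[ok[-1]] != rowv[ok[-length(ok)]])
      starts <- ok[brk]
      ends <- ok[c(which(brk)[-1] - 1L, length(ok))]
      for (r in seq_along(starts)) {
        id <- length(parent) + 1L
        parent[id] <- id
        run_start[id] <- starts[r]; run_end[id] <- ends[r]
        run_class[id] <- rowv[starts[r]]; run_row[id] <- i
        cur <- c(cur, id)
        for (p in prev_runs) {
          if (run_class[p] == run_class[id] &&
              run_start[p] <= ends[r] + reach &&
              run_end[p] >= starts[r] - reach) {
            ra <- find(p); rb <- find(id)
            if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
          }
        }
      }
    }
    row_runs[[i]] <- cur
    prev_runs <- cur
  }
  labels <- matrix(0L, nr, nc)
  if (length(parent)) {
    roots <- vapply(seq_along(parent), find, integer(1))
    dense <- match(roots, unique(roots))
    for (i in seq_len(nr)) {
      for (id in row_runs[[i]]) {
        labels[i, run_start[id]:run_end[id]] <- dense[id]
      }
    }
    n_lab <- max(dense)
    patch_cells <- tabulate(labels[labels > 0], n_lab)
    patch_class <- numeric(n_lab)
    first <- match(seq_len(n_lab), dense)
    patch_class <- run_class[first]
  } else {
    patch_cells <- integer(0); patch_class <- numeric(0)
  }
  list(labels = labels, patch_class = patch_class, patch_cells = patch_cells)
}

# ---- single-window metrics -------------------------------------------------
# Each takes a clipped window: a matrix with NA outside the window/nodata.

#' Percentage of landscape occupied by a class
#'
#' @param window Clipped landcover matrix (`NA` outside the window).
#' @param class Class code.
#' @return Percent of valid window cells in `class`; `NA` for empty windows.
#' @export
pland <- function(window, class) {
  n <- sum(!is.na(window))
  if (n == 0) return(NA_real_)
  100 * sum(window == class, na.rm = TRUE) / n
}

#' Patch density (patches per 100 ha)
#'
#' Patches of all classes are relabeled inside the clipped window, then the
#' count is scaled by the window's valid area.
#'
#' @inheritParams pland
#' @param cell_size Cell size, metres.
#' @param connectivity Patch connectivity (default 8).
#' @return Patches per 100 hectares; `NA` for empty windows.
#' @export
patch_density <- function(window, cell_size, connectivity = 8) {
  n <- sum(!is.na(window))
  if (n == 0) return(NA_real_)
  lp <- label_patches(window, connectivity)
  n_patch <- length(lp$patch_cells)
  area_m2 <- n * cell_size^2
  n_patch / area_m2 * 1e6
}

max_like_adjacencies <- function(A) {
  n <- floor(sqrt(A))
  m <- A - n^2
  ifelse(A <= 0, 0,
         ifelse(m == 0, 2 * n * (n - 1),
                ifelse(m <= n, 2 * n * (n - 1) + 2 * m - 1,
                       2 * n * (n - 1) + 2 * m - 2)))
}

like_adjacencies <- function(window, class) {
  b <- !is.na(window) & window == class
  sum(b[, -ncol(window), drop = FALSE] & b[, -1, drop = FALSE]) +
    sum(b[-nrow(window), , drop = FALSE] & b[-1, , drop = FALSE])
}

#' Aggregation index (landscape level)
#'
#' For each class, the single-count rook like-adjacencies as a percentage of
#' the maximum possible for that class's area; the landscape value is the
#' area-weighted mean over classes present. Classes whose maximum is zero
#' (single-cell classes) contribute 0.
#'
#' @inheritParams pland
#' @return Percent in `[0, 100]`; `NA` for windows with fewer than 2 cells.
#' @export
aggregation_index <- function(window) {
  n <- sum(!is.na(window))
  if (n < 2) return(NA_real_)
  classes <- sort(unique(window[!is.na(window)]))
  ai_total <- 0
  for (cl in classes) {
    A <- sum(window == cl, na.rm = TRUE)
    mx <- max_like_adjacencies(A)
    ai_i <- if (mx > 0) 100 * like_adjacencies(window, cl) / mx else 0
    ai_total <- ai_total + ai_i * A / n
  }
  ai_total
}

#' Contrast-weighted edge density
#'
#' Sum over internal class-boundary segments of cell side length times the
#' contrast weight of the two classes, per hectare of window area. Boundaries
#' to nodata and the window border contribute no edge.
#'
#' @inheritParams patch_density
#' @param contrast Symmetric contrast matrix with `dimnames` naming class
#'   codes, entries in `[0, 1]`, zero diagonal (see [default_contrast()]).
#' @return Metres of weighted edge per hectare; `NA` for empty windows.
#' @export
cwed <- function(window, contrast, cell_size) {
  n <- sum(!is.na(window))
  if (n == 0) return(NA_real_)
  wsum <- 0
  lookup <- function(a, b) contrast[as.character(a), as.character(b)]
  nrw <- nrow(window); ncw <- ncol(window)
  a_h <- window[, -ncw, drop = FALSE]; b_h <- window[, -1, drop = FALSE]
  ok <- !is.na(a_h) & !is.na(b_h) & a_h != b_h
  if (any(ok)) wsum <- wsum + sum(mapply(lookup, a_h[ok], b_h[ok]))
  a_v <- window[-nrw, , drop = FALSE]; b_v <- window[-1, , drop = FALSE]
  ok <- !is.na(a_v) & !is.na(b_v) & a_v != b_v
  if (any(ok)) wsum <- wsum + sum(mapply(lookup, a_v[ok], b_v[ok]))
  area_ha <- n * cell_size^2 / 1e4
  wsum * cell_size / area_ha
}

#' Area-weighted mean patch size and radius of gyration
#'
#' Over patches of `class` clipped to the window: `area_am` is
#' `sum(a_j * a_j / sum(a_j))` in hectares; the radius of gyration of a patch
#' is the mean distance of its cell centers to the patch centroid, and
#' `gyrate_am` weights it by area share. Both are 0 when the class is absent
#' (FRAGSTATS convention); `NA` for empty windows.
#'
#' @inheritParams patch_density
#' @param class Class code.
#' @return Hectares (`area_am`) or metres (`gyrate_am`).
#' @export
area_am <- function(window, class, cell_size, connectivity = 8) {
  if (sum(!is.na(window)) == 0) return(NA_real_)
  lp <- label_patches(window, connectivity)
  keep <- which(lp$patch_class == class)
  if (!length(keep)) return(0)
  a <- lp$patch_cells[keep] * cell_size^2 / 1e4
  sum(a * a / sum(a))
}

#' @rdname area_am
#' @export
gyrate_am <- function(window, class, cell_size, connectivity = 8) {
  if (sum(!is.na(window)) == 0) return(NA_real_)
  lp <- label_patches(window, connectivity)
  keep <- which(lp$patch_class == class)
  if (!length(keep)) return(0)
  gyr <- numeric(length(keep))
  for (m in seq_along(keep)) {
    cells <- which(lp$labels == keep[m], arr.ind = TRUE)
    cy <- cells[, 1] * cell_size; cx <- cells[, 2] * cell_size
    gyr[m] <- mean(sqrt((cx - mean(cx))^2 + (cy - mean(cy))^2))
  }
  a <- lp$patch_cells[keep]
  sum(gyr * a / sum(a))
}

#' Default contrast matrix for ordered classes
#'
#' Contrast between classes `a` and `b` is `|rank(a) - rank(b)| / (K - 1)`
#' over the ordered class list: adjacent classes have low contrast, the two
#' extremes have contrast 1. Overridable wherever a contrast matrix is taken.
#'
#' @param classes Ordered vector of class codes.
#' @return Symmetric matrix with zero diagonal and dimnames = class codes.
#' @export
default_contrast <- function(classes) {
  k <- length(classes)
  ranks <- seq_len(k)
  w <- abs(outer(ranks, ranks, "-")) / max(1, k - 1)
  dimnames(w) <- list(as.character(classes), as.character(classes))
  w
}

# ---- moving-window metric grids -------------------------------------------

# AI, CWED and PLAND admit exact per-cell evaluation through convolutions
# with "both ends in the disc" pair kernels; PD, AREA_AM and GYR_AM need a
# per-window clip-and-relabel pass and are evaluated on a block lattice for
# larger grids.

pair_kernels <- function(radius, cell_size) {
  k <- disc_kernel(radius, cell_size)
  nr <- nrow(k)
  kh <- k[, -nr, drop = FALSE] * k[, -1, drop = FALSE]      # offset pairs (0,+1)
  kv <- k[-nr, , drop = FALSE] * k[-1, , drop = FALSE]      # offset pairs (+1,0)
  # re-center to odd dimensions by padding a zero column/row on the right/bottom
  kh2 <- cbind(kh, 0); kv2 <- rbind(kv, 0)
  list(disc = k, h = kh2, v = kv2)
}

#' Moving-window landscape metric grid
#'
#' Computes a landscape metric per cell over circular windows of `radius`.
#' `pland`, `ai` and `cwed` are evaluated exactly at every cell via
#' convolution; `pd`, `area_am` and `gyrate_am` relabel patches inside each
#' window and are evaluated on a coarser block lattice when the grid is
#' large (controlled by `lattice_step`; each block inherits the value at its
#' central cell, and the output records the step used as an attribute).
#'
#' @param landcover Integer-coded landcover `sdm_grid`.
#' @param metric One of `"pland"`, `"ai"`, `"cwed"`, `"pd"`, `"area_am"`,
#'   `"gyrate_am"`.
#' @param radius Window radius, metres.
#' @param class Class code (required for class-level metrics).
#' @param contrast Contrast matrix for `cwed`; defaults to
#'   [default_contrast()] over the classes present.
#' @param lattice_step Evaluation lattice step in cells for the patch-based
#'   metrics; default 1 for grids up to 4,096 cells, else scaled so the
#'   lattice stays near 64 x 64.
#' @param connectivity Patch connectivity for the patch-based metrics.
#' @return An `sdm_grid`.
#' @export
landscape_metric_grid <- function(landcover, metric, radius, class = NULL,
                                  contrast = NULL, lattice_step = NULL,
                                  connectivity = 8) {
  metric <- match.arg(metric, c("pland", "ai", "cwed", "pd", "area_am",
                                "gyrate_am"))
  v <- landcover$values
  cs <- landcover$cell_size
  valid <- !is.na(v)
  out <- landcover
  if (metric %in% c("pland", "ai", "cwed")) {
    pk <- pair_kernels(radius, cs)
    cnt_valid <- round(conv2_same(valid * 1, pk$disc))
    if (metric == "pland") {
      stopifnot(!is.null(class))
      cnt_c <- round(conv2_same((valid & v == class) * 1, pk$disc))
      res <- ifelse(cnt_valid > 0, 100 * cnt_c / cnt_valid, NA_real_)
    } else if (metric == "ai") {
      classes <- sort(unique(v[valid]))
      res <- matrix(0, nrow(v), ncol(v))
      for (cl in classes) {
        b <- (valid & v == cl) * 1
        A <- round(conv2_same(b, pk$disc))
        bh <- b[, -ncol(b), drop = FALSE] * b[, -1, drop = FALSE]
        bv <- b[-nrow(b), , drop = FALSE] * b[-1, , drop = FALSE]
        g <- round(conv2_same(cbind(bh, 0), pk$h) + conv2_same(rbind(bv, 0), pk$v))
        mx <- max_like_adjacencies(A)
        ai_i <- ifelse(mx > 0, 100 * g / mx, 0)
        res <- res + ai_i * ifelse(cnt_valid > 0, A / cnt_valid, 0)
      }
      res[cnt_valid < 2] <- NA_real_
    } else {
      if (is.null(contrast)) contrast <- default_contrast(sort(unique(v[valid])))
      wh <- matrix(0, nrow(v), ncol(v)); wv <- matrix(0, nrow(v), ncol(v))
      a_h <- v[, -ncol(v), drop = FALSE]; b_h <- v[, -1, drop = FALSE]
      okh <- !is.na(a_h) & !is.na(b_h) & a_h != b_h
      idx <- which(okh)
      if (length(idx)) {
        wh[, -ncol(v)][idx] <- contrast[cbind(as.character(a_h[idx]),
                                              as.character(b_h[idx]))]
      }
      a_v <- v[-nrow(v), , drop = FALSE]; b_v <- v[-1, , drop = FALSE]
      okv <- !is.na(a_v) & !is.na(b_v) & a_v != b_v
      idx <- which(okv)
      if (length(idx)) {
        wv[-nrow(v), ][idx] <- contrast[cbind(as.character(a_v[idx]),
                                              as.character(b_v[idx]))]
      }
      esum <- conv2_same(wh, pk$h) + conv2_same(wv, pk$v)
      area_ha <- cnt_valid * cs^2 / 1e4
      res <- ifelse(cnt_valid > 0, esum * cs / area_ha, NA_real_)
    }
    res[!valid] <- NA_real_
    out$values <- res
    attr(out, "lattice_step") <- 1L
    return(out)
  }
  # patch-based metrics: lattice evaluation with clip-and-relabel
  nr <- nrow(v); nc <- ncol(v)
  if (is.null(lattice_step)) {
    lattice_step <- if (nr * nc <= 4096) 1L else max(1L, ceiling(max(nr, nc) / 64))
  }
  half <- floor(radius / cs)
  kern <- disc_kernel(radius, cs)
  res <- matrix(NA_real_, nr, nc)
  ev_rows <- seq(1L + (lattice_step - 1L) %/% 2L, nr, by = lattice_step)
  ev_cols <- seq(1L + (lattice_step - 1L) %/% 2L, nc, by = lattice_step)
  for (i in ev_rows) {
    i_rng <- max(1L, i - half):min(nr, i + half)
    k_i <- i_rng - i + half + 1L
    for (j in ev_cols) {
      if (is.na(v[i, j])) next
      j_rng <- max(1L, j - half):min(nc, j + half)
      k_j <- j_rng - j + half + 1L
      w <- v[i_rng, j_rng, drop = FALSE]
      w[kern[k_i, k_j, drop = FALSE] == 0] <- NA
      val <- switch(metric,
        pd = patch_density(w, cs, connectivity),
        area_am = area_am(w, class, cs, connectivity),
        gyrate_am = gyrate_am(w, class, cs, connectivity))
      bi <- max(1L, i - lattice_step %/% 2L):min(nr, i + (lattice_step - 1L) %/% 2L)
      bj <- max(1L, j - lattice_step %/% 2L):min(nc, j + (lattice_step - 1L) %/% 2L)
      res[bi, bj] <- val
    }
  }
  res[!valid] <- NA_real_
  out$values <- res
  attr(out, "lattice_step") <- as.integer(lattice_step)
  out
}
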