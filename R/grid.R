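# Matrix-backed raster container. Row 1 is the northernmost row; `origin` is
# the (x, y) of the outer corner of the top-left cell (GeoTIFF convention).
# NA values mark nodata.

#' Create a raster grid
#'
#' `sdm_grid` is the raster container used throughout the package: a numeric
#' matrix plus a cell size in metres and the coordinate of the top-left outer
#' corner. All layers entering a model run must share geometry exactly;
#' arithmetic between grids with different geometry is refused.
#'
#' @param values Numeric matrix. `NA` marks nodata. Row 1 is the north edge.
#' @param cell_size Cell edge length in metres (> 0).
#' @param origin Length-2 numeric, `c(x, y)` of the outer top-left corner.
#' @param crs Free-text label for the projected CRS. Only metric, projected
#'   coordinates are supported; the label is carried through unchanged.
#' @return An object of class `sdm_grid`.
#' @examples
#' g <- sdm_grid(matrix(1:12, 3, 4), cell_size = 90)
#' g
#' @export
sdm_grid <- function(values, cell_size, origin = c(0, nrow(values) * cell_size),
                     crs = "local-metric") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("`cell_size` must be a single positive number (metres)", call. = FALSE)
  }
  if (length(origin) != 2L || !is.numeric(origin)) {
    stop("`origin` must be a length-2 numeric (x, y)", call. = FALSE)
  }
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), crs = crs),
    class = "sdm_grid"
  )
}

#' @export
print.sdm_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<sdm_grid> %d x %d cells, %.6g m cell size, origin (%.6g, %.6g)\n",
              nrow(v), ncol(v), x$cell_size, x$origin[1], x$origin[2]))
  cat(sprintf("  crs: %s | valid cells: %d/%d | range: [%s, %s]\n",
              x$crs, sum(!is.na(v)), length(v),
              format(suppressWarnings(min(v, na.rm = TRUE)), digits = 5),
              format(suppressWarnings(max(v, na.rm = TRUE)), digits = 5)))
  invisible(x)
}

#' @export
dim.sdm_grid <- function(x) dim(x$values)

#' Test whether two grids share geometry
#'
#' @param a,b `sdm_grid` objects.
#' @param tol Absolute tolerance on cell size and origin, metres.
#' @return `TRUE` or `FALSE`.
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$cell_size - b$cell_size) < tol &&
    all(abs(a$origin - b$origin) < tol)
}

check_same_geometry <- function(a, b, what = "grids") {
  if (!same_geometry(a, b)) {
    stop(sprintf("%s do not share geometry (shape/cell size/origin)", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
Ops.sdm_grid <- function(e1, e2) {
  if (missing(e2)) {
    e1$values <- get(.Generic)(e1$values)
    return(e1)
  }
  if (inherits(e1, "sdm_grid") && inherits(e2, "sdm_grid")) {
    check_same_geometry(e1, e2)
    out <- e1
    out$values <- get(.Generic)(e1$values, e2$values)
    return(out)
  }
  out <- if (inherits(e1, "sdm_grid")) e1 else e2
  v1 <- if (inherits(e1, "sdm_grid")) e1$values else e1
  v2 <- if (inherits(e2, "sdm_grid")) e2$values else e2
  res <- get(.Generic)(v1, v2)
  if (is.logical(res)) res <- res * 1
  out$values <- res
  out
}

#' Coordinates of cell centers
#'
#' @param grid An `sdm_grid`.
#' @return List with `x` (per column) and `y` (per row) center coordinates.
#' @export
cell_centers <- function(grid) {
  cs <- grid$cell_size
  list(
    x = grid$origin[1] + (seq_len(ncol(grid$values)) - 0.5) * cs,
    y = grid$origin[2] - (seq_len(nrow(grid$values)) - 0.5) * cs
  )
}

#' Convert a grid to a tibble of cell centers
#'
#' @param x An `sdm_grid`.
#' @param ... Unused.
#' @param drop_na Drop nodata cells (default `TRUE`).
#' @return Tibble with columns `x`, `y`, `value`.
#' @method as_tibble sdm_grid
#' @export
as_tibble.sdm_grid <- function(x, ..., drop_na = TRUE) {
  cc <- cell_centers(x)
  out <- tibble::tibble(
    x = rep(cc$x, each = nrow(x$values)),
    y = rep(cc$y, times = ncol(x$values)),
    value = as.vector(x$values)
  )
  if (drop_na) out <- out[!is.na(out$value), ]
  out
}

#' Summary statistics over valid cells
#'
#' @param object An `sdm_grid`.
#' @param ... Unused.
#' @export
summary.sdm_grid <- function(object, ...) {
  v <- object$values[!is.na(object$values)]
  c(n_valid = length(v), mean = mean(v), sd = stats::sd(v),
    min = min(v), max = max(v))
}

# ---- ESRI ASCII grid IO ----------------------------------------------------

#' Read a raster from an ESRI ASCII grid file
#'
#' Supports `xllcorner`/`yllcorner` and `xllcenter`/`yllcenter` headers and an
#' optional `nodata_value`. The file's lower-left reference is converted to
#' the package's top-left origin convention.
#'
#' @param path Path to a `.asc` file.
#' @param crs CRS label to attach (the ASCII format carries none). Must denote
#'   a projected, metric system.
#' @return An `sdm_grid`.
#' @export
read_grid <- function(path, crs = "local-metric") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 7L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2L && grepl("^[a-zA-Z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("not an ESRI ASCII grid (missing ncols/nrows/cellsize): ", path,
         call. = FALSE)
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  vals <- scan(path, skip = n_hdr, quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop(sprintf("payload size mismatch: expected %d values, got %d",
                 nr * nc, length(vals)), call. = FALSE)
  }
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA_real_
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cs / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cs / 2
  if (is.na(xll) || is.na(yll)) { xll <- 0; yll <- 0 }
  sdm_grid(m, cell_size = cs, origin = c(xll, yll + nr * cs), crs = crs)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' @param grid An `sdm_grid`.
#' @param path Output path.
#' @param nodata Sentinel written for `NA` cells.
#' @param digits Significant digits for the payload.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, nodata = -9999, digits = 10) {
  stopifnot(inherits(grid, "sdm_grid"))
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  con <- file(path, "w")
  on.exit(close(con))
  yll <- grid$origin[2] - nr * grid$cell_size
  writeLines(c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("nodata_value %.10g", nodata)
  ), con)
  v[is.na(v)] <- nodata
  for (i in seq_len(nr)) {
    writeLines(paste(formatC(v[i, ], format = "g", digits = digits),
                     collapse = " "), con)
  }
  invisible(path)
}

# ---- occurrences -----------------------------------------------------------

#' Load occurrence points from a CSV file
#'
#' Reads a CSV with at least `x` and `y` columns (optionally `source`), drops
#' rows with missing or non-numeric coordinates, collapses duplicate
#' coordinates, and drops points outside the reference grid extent. Each
#' filtering step reports its count.
#'
#' @param path CSV path with header `x,y[,source]`.
#' @param grid Reference `sdm_grid`; points outside its extent are dropped.
#' @param dataset_tag Optional label (e.g. `"RD"`) stored as an attribute.
#' @param quiet Suppress the filter-count messages.
#' @return Tibble with columns `x`, `y`, `source`.
#' @export
load_occurrences <- function(path, grid, dataset_tag = NULL, quiet = FALSE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(raw))) {
    stop("occurrence CSV must have x and y columns", call. = FALSE)
  }
  if (is.null(raw$source)) raw$source <- "unknown"
  n0 <- nrow(raw)
  xs <- suppressWarnings(as.numeric(raw$x))
  ys <- suppressWarnings(as.numeric(raw$y))
  ok <- is.finite(xs) & is.finite(ys)
  n_missing <- sum(!ok)
  occ <- tibble::tibble(x = xs[ok], y = ys[ok], source = raw$source[ok])
  dup <- duplicated(occ[, c("x", "y")])
  n_dup <- sum(dup)
  occ <- occ[!dup, ]
  inside <- points_in_extent(occ$x, occ$y, grid)
  n_out <- sum(!inside)
  occ <- occ[inside, ]
  if (!quiet) {
    message(sprintf(
      "loaded %d rows: dropped %d missing-coordinate, %d duplicate, %d out-of-extent; retained %d",
      n0, n_missing, n_dup, n_out, nrow(occ)))
  }
  if (nrow(occ) == 0L) stop("no valid occurrence points after filtering",
                            call. = FALSE)
  if (!is.null(dataset_tag)) attr(occ, "dataset_tag") <- dataset_tag
  occ
}

points_in_extent <- function(x, y, grid) {
  cs <- grid$cell_size
  xmin <- grid$origin[1]; xmax <- xmin + ncol(grid$values) * cs
  ymax <- grid$origin[2]; ymin <- ymax - nrow(grid$values) * cs
  x >= xmin & x <= xmax & y >= ymin & y <= ymax
}

#' Map point coordinates to cell row/column indices
#'
#' @param x,y Coordinate vectors (metres).
#' @param grid Reference `sdm_grid`.
#' @return Tibble with `row`, `col`, and the flat `cell` index
#'   (column-major, matching R matrix indexing).
#' @export
points_to_cells <- function(x, y, grid) {
  cs <- grid$cell_size
  col <- pmin(pmax(floor((x - grid$origin[1]) / cs) + 1L, 1L), ncol(grid$values))
  row <- pmin(pmax(floor((grid$origin[2] - y) / cs) + 1L, 1L), nrow(grid$values))
  tibble::tibble(row = as.integer(row), col = as.integer(col),
                 cell = as.integer((col - 1L) * nrow(grid$values) + row))
}

#' Binary mask of cells within a buffer of occurrence points
#'
#' A cell is 1 iff its center lies within `radius` of at least one point.
#' Nodata cells of the reference grid stay 0. Used to delimit the background
#' (pseudo-absence) sampling region around occurrences.
#'
#' @param occ Tibble with `x`, `y` columns.
#' @param grid Reference `sdm_grid` (its `NA` cells are excluded).
#' @param radius Buffer radius, metres (> 0).
#' @return An `sdm_grid` of 0/1 values.
#' @export
buffer_mask <- function(occ, grid, radius) {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0", call. = FALSE)
  v <- grid$values
  cs <- grid$cell_size
  cc <- cell_centers(grid)
  pc <- points_to_cells(occ$x, occ$y, grid)
  # fast path: points on cell centers reduce the buffer to a disc convolution
  on_center <- all(abs(occ$x - cc$x[pc$col]) < 1e-6 * cs) &&
    all(abs(occ$y - cc$y[pc$row]) < 1e-6 * cs)
  if (on_center) {
    cnt <- matrix(0, nrow(v), ncol(v))
    cnt[pc$cell] <- 1
    hit <- conv2_same(cnt, disc_kernel(radius, cs))
    mask <- (hit > 0.5) * 1
    mask[is.na(v)] <- 0
    out <- grid
    out$values <- mask
    return(out)
  }
  mask <- matrix(0, nrow(v), ncol(v))
  half <- ceiling(radius / cs) + 1L
  for (k in seq_len(nrow(occ))) {
    px <- occ$x[k]; py <- occ$y[k]
    jc <- floor((px - grid$origin[1]) / cs) + 1
    ic <- floor((grid$origin[2] - py) / cs) + 1
    js <- max(1L, jc - half):min(ncol(v), jc + half)
    is <- max(1L, ic - half):min(nrow(v), ic + half)
    if (!length(js) || !length(is)) next
    dx2 <- (cc$x[js] - px)^2
    dy2 <- (cc$y[is] - py)^2
    hit <- outer(dy2, dx2, "+") <= radius^2
    mask[is, js][hit] <- 1
  }
  mask[is.na(v)] <- 0
  out <- grid
  out$values <- mask
  out
}
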