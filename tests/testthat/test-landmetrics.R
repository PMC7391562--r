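# Patch labeling and FRAGSTATS-style window metrics against independent
# oracles.

# independent labeling oracle: connected components via igraph on the cell
# adjacency graph
igraph_label <- function(v, connectivity = 8) {
  nr <- nrow(v); nc <- ncol(v)
  id <- function(i, j) (j - 1L) * nr + i
  from <- integer(0); to <- integer(0)
  offs <- if (connectivity == 8) {
    list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  } else list(c(0, 1), c(1, 0))
  for (o in offs) {
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      a <- i + o[1]; b <- j + o[2]
      if (a >= 1 && a <= nr && b >= 1 && b <= nc &&
          !is.na(v[i, j]) && !is.na(v[a, b]) && v[i, j] == v[a, b]) {
        from <- c(from, id(i, j)); to <- c(to, id(a, b))
      }
    }
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nr * nc - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab <- matrix(comp[seq_len(nr * nc)], nr, nc)
  lab[is.na(v)] <- 0L
  lab
}

same_partition <- function(a, b) {
  ok <- a > 0
  # bijection between the two labelings: each pair (a, b) is unique and the
  # label counts agree
  length(unique(paste(a[ok], b[ok]))) == length(unique(a[ok])) &&
    length(unique(a[ok])) == length(unique(b[ok]))
}

test_that("patch labeling matches an igraph components oracle", {
  set.seed(31)
  for (rep in 1:5) {
    v <- matrix(sample(1:3, 100, replace = TRUE), 10, 10)
    v[sample(100, 8)] <- NA
    for (conn in c(4, 8)) {
      lp <- label_patches(v, conn)
      expect_true(same_partition(lp$labels, igraph_label(v, conn)))
      expect_equal(sum(lp$patch_cells), sum(!is.na(v)))
      # every labelled cell's class equals its patch's class
      for (k in seq_along(lp$patch_class)) {
        expect_true(all(v[lp$labels == k] == lp$patch_class[k]))
      }
    }
  }
})

test_that("labeling handles uniform and checkerboard extremes", {
  u <- matrix(7, 6, 6)
  expect_equal(length(label_patches(u, 8)$patch_cells), 1)
  cb <- outer(1:6, 1:6, function(i, j) (i + j) %% 2 + 1)
  expect_equal(length(label_patches(cb, 4)$patch_cells), 36)
  expect_equal(length(label_patches(cb, 8)$patch_cells), 2)
})

test_that("PLAND counts and sums to 100 over classes", {
  w <- matrix(c(1, 1, 1, 2, 2, 2, 2, 2, 2, 3, 3, 3), 3, 4)
  expect_equal(pland(w, 1), 25)
  expect_equal(pland(w, 9), 0)
  expect_equal(sum(sapply(1:3, function(cl) pland(w, cl))), 100)
  expect_equal(pland(matrix(5, 2, 2), 5), 100)
  expect_true(is.na(pland(matrix(NA_real_, 2, 2), 1)))
})

test_that("patch density has its closed forms and splits increase it", {
  w <- matrix(1, 10, 10)
  # one patch: PD = 1e6 / area_m2
  expect_equal(patch_density(w, 100), 1e6 / (100 * 100 * 100))
  # 100 ha window (10x10 cells at 100 m) tiled into exactly 30 patches:
  # each row holds 3 runs, classes alternating between rows so rows never merge
  even <- c(rep(1, 4), rep(2, 3), rep(3, 3))
  odd <- c(rep(4, 4), rep(5, 3), rep(6, 3))
  v <- t(sapply(1:10, function(i) if (i %% 2) odd else even))
  expect_equal(length(label_patches(v, 8)$patch_cells), 30)
  expect_equal(patch_density(v, 100), 30)
  # removing a bridge cell splits one patch into two: PD strictly increases
  a <- matrix(1, 1, 5)
  b <- a; b[1, 3] <- NA
  expect_gt(patch_density(b, 100), patch_density(a, 100))
})

test_that("aggregation index matches hand adjacency counts", {
  expect_equal(aggregation_index(matrix(4, 5, 5)), 100)
  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  expect_equal(aggregation_index(cb), 0)
  # 2x2 block of A in a 4x4 of B: g_AA = 4, A_area = 4 -> max 4, AI_A = 100;
  # B: 12 cells, g_BB = 10 like edges, max for 12 = 2*3*2+2*3-2... use formula
  w <- matrix("B", 4, 4); w[1:2, 1:2] <- "A"
  wn <- matrix(match(w, c("A", "B")), 4, 4)
  gBB <- scalesdm:::like_adjacencies(wn, 2)
  maxB <- scalesdm:::max_like_adjacencies(12)
  expect_equal(aggregation_index(wn),
               100 * (4 / 16) + (100 * gBB / maxB) * (12 / 16))
  expect_true(is.na(aggregation_index(matrix(c(1, NA), 1, 2)[, 2, drop = FALSE])))
})

test_that("AI is invariant under class relabeling", {
  set.seed(13)
  v <- matrix(sample(1:4, 144, replace = TRUE), 12, 12)
  perm <- c(3, 1, 4, 2)
  v2 <- matrix(perm[v], 12, 12)
  expect_equal(aggregation_index(v), aggregation_index(v2), tolerance = 1e-12)
})

test_that("CWED equals hand edge counts, is linear and symmetric in weights", {
  # 6x6 window split into two 6x3 halves: boundary of 6 cell sides
  w <- cbind(matrix(1, 6, 3), matrix(2, 6, 3))
  cm <- default_contrast(1:2)  # contrast 1 between the two classes
  expect_equal(cwed(w, cm, 90), 6 * 90 / (36 * 8100 / 1e4))
  expect_equal(cwed(matrix(1, 4, 4), cm, 90), 0)
  expect_equal(cwed(w, cm * 0.5, 90), 0.5 * cwed(w, cm, 90))
  # symmetry of the contrast lookup: flipped window gives the same value
  expect_equal(cwed(w[, 6:1], cm, 90), cwed(w, cm, 90))
})

test_that("area-weighted patch metrics follow FRAGSTATS conventions", {
  cs <- 90
  one <- matrix(c(1, NA, NA, NA), 2, 2)
  expect_equal(area_am(one, 1, cs), cs^2 / 1e4)
  expect_equal(gyrate_am(one, 1, cs), 0)
  # two-cell patch: centers 90 m apart -> gyration 45 m
  two <- matrix(c(1, 1, NA, NA), 1, 4)
  expect_equal(gyrate_am(two, 1, cs), 45)
  # absent class -> 0; empty window -> NA
  expect_equal(area_am(two, 9, cs), 0)
  expect_true(is.na(area_am(matrix(NA_real_, 2, 2), 1, cs)))
  # one patch only: AREA_AM equals that patch's area exactly
  blob <- matrix(c(1, 1, 1, NA, NA, 1), 2, 3)
  expect_equal(area_am(blob, 1, cs), 4 * cs^2 / 1e4)
  # two patches: area-weighted mean = sum a_j^2 / sum a_j
  vp <- matrix(c(1, 1, NA, 1), 1, 4)
  a <- c(2, 1) * cs^2 / 1e4
  expect_equal(area_am(vp, 1, cs), sum(a^2) / sum(a))
})

test_that("moving-window metric grids equal brute-force window recomputation", {
  set.seed(41)
  v <- matrix(sample(1:3, 20 * 20, replace = TRUE), 20, 20)
  v[sample(400, 12)] <- NA
  g <- sdm_grid(v, cell_size = 90)
  radius <- 2.5 * 90
  cm <- default_contrast(1:3)
  ai_g <- landscape_metric_grid(g, "ai", radius)
  cw_g <- landscape_metric_grid(g, "cwed", radius, contrast = cm)
  pl_g <- landscape_metric_grid(g, "pland", radius, class = 2)
  pd_g <- landscape_metric_grid(g, "pd", radius)
  aa_g <- landscape_metric_grid(g, "area_am", radius, class = 2)
  gy_g <- landscape_metric_grid(g, "gyrate_am", radius, class = 2)
  cells <- cbind(sample(4:17, 20, replace = TRUE), sample(4:17, 20, replace = TRUE))
  for (k in seq_len(nrow(cells))) {
    i <- cells[k, 1]; j <- cells[k, 2]
    if (is.na(v[i, j])) next
    w <- clip_window(v, i, j, radius, 90)
    expect_equal(ai_g$values[i, j], aggregation_index(w), tolerance = 1e-9)
    expect_equal(cw_g$values[i, j], cwed(w, cm, 90), tolerance = 1e-9)
    expect_equal(pl_g$values[i, j], pland(w, 2), tolerance = 1e-9)
    expect_equal(pd_g$values[i, j], patch_density(w, 90), tolerance = 1e-9)
    expect_equal(aa_g$values[i, j], area_am(w, 2, 90), tolerance = 1e-9)
    expect_equal(gy_g$values[i, j], gyrate_am(w, 2, 90), tolerance = 1e-9)
  }
})

test_that("PLAND window grids sum to 100 over classes", {
  set.seed(43)
  v <- matrix(sample(1:4, 256, replace = TRUE), 16, 16)
  g <- sdm_grid(v, cell_size = 90)
  tot <- Reduce(`+`, lapply(1:4, function(cl) {
    landscape_metric_grid(g, "pland", 200, class = cl)$values
  }))
  expect_equal(tot, matrix(100, 16, 16), tolerance = 1e-9)
})

test_that("default contrast matrix is symmetric, zero-diagonal, rank-scaled", {
  cm <- default_contrast(c(3, 4, 5, 8, 10))
  expect_equal(cm, t(cm))
  expect_true(all(diag(cm) == 0))
  expect_equal(cm["3", "10"], 1)
  expect_equal(cm["3", "4"], 0.25)
})
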