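# Model evaluation: presence-background AUC (Mann-Whitney form with half
# credit for ties), train-test AUC difference as an overfitting proxy, the
# maximum training sensitivity plus specificity (MTSS) threshold with its
# omission rate, Pearson correlation matrices for collinearity screening,
# and k-fold cross-validation with variable jackknife.

#' Presence-background AUC
#'
#' The Mann-Whitney rank statistic: the probability that a presence scores
#' above a background point, with ties credited one half.
#'
#' @param presence_scores,background_scores Numeric score vectors (both
#'   non-empty).
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(0.9, 0.4), c(0.5, 0.3, 0.1))  # 0.75
#' @export
auc <- function(presence_scores, background_scores) {
  m <- length(presence_scores); n <- length(background_scores)
  if (m == 0 || n == 0) stop("both score sets must be non-empty", call. = FALSE)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Maximum training sensitivity plus specificity threshold
#'
#' Scans every observed score as a candidate threshold and returns the one
#' maximizing sensitivity (presences scoring at or above it) plus
#' specificity (background scoring below it), background serving as
#' pseudo-absence. Ties are broken toward the lowest threshold.
#'
#' @param presence_scores,background_scores Training score vectors.
#' @return The MTSS threshold.
#' @export
mtss_threshold <- function(presence_scores, background_scores) {
  stopifnot(length(presence_scores) > 0, length(background_scores) > 0)
  cand <- sort(unique(c(presence_scores, background_scores)))
  ps <- sort(presence_scores); bs <- sort(background_scores)
  # counts below each candidate via sorted search: sens + spec per threshold
  sens <- 1 - findInterval(cand, ps, left.open = TRUE) / length(ps)
  spec <- findInterval(cand, bs, left.open = TRUE) / length(bs)
  v <- sens + spec
  cand[which(v > max(v) - 1e-12)[1]]  # lowest threshold among ties
}

#' Omission rate at a threshold
#'
#' Fraction of presences scoring strictly below the threshold.
#'
#' @param presence_scores Score vector (typically the test partition).
#' @param threshold Score threshold (see [mtss_threshold()]).
#' @return Rate in `[0, 1]`.
#' @export
omission <- function(presence_scores, threshold) {
  mean(presence_scores < threshold)
}

#' Evaluate a fitted model on its design
#'
#' Computes training and test AUC against the background, their difference
#' (`auc_diff = auc_train - auc_test`, the overfitting proxy; negative when
#' the test partition discriminates better), the MTSS threshold from the
#' training partition, and omission rates of both partitions at that
#' threshold.
#'
#' @param model A `maxent_model`.
#' @param design The `sdm_design` the model was fitted on.
#' @return One-row tibble (class `eval_report`).
#' @export
eval_report <- function(model, design) {
  sp <- maxent_scores(model, design$x_presence[, model$layers, drop = FALSE],
                      "logistic")
  sb <- maxent_scores(model, design$x_background[, model$layers, drop = FALSE],
                      "logistic")
  tr <- design$train
  auc_train <- auc(sp[tr], sb)
  auc_test <- if (any(!tr)) auc(sp[!tr], sb) else NA_real_
  thr <- mtss_threshold(sp[tr], sb)
  tibble::tibble(
    auc_train = auc_train, auc_test = auc_test,
    auc_diff = auc_train - auc_test,
    mtss = thr,
    omission_train = omission(sp[tr], thr),
    omission_test = if (any(!tr)) omission(sp[!tr], thr) else NA_real_,
    n_presence_train = sum(tr), n_presence_test = sum(!tr)
  )
}

#' Pairwise Pearson correlations between predictor layers
#'
#' Computed over the cells valid in every layer, subsampled to at most
#' `subsample` cells (seeded) on large grids. A constant layer has no
#' defined correlation: its entries are `NA`, reported with a message, and
#' treated as zero by [collinearity_filter()].
#'
#' @param predictors Named list of `sdm_grid` layers (>= 2).
#' @param subsample Maximum number of cells used (default 10,000).
#' @param seed Seed for the cell subsample.
#' @param quiet Suppress the constant-layer message.
#' @return Symmetric correlation matrix with layer names.
#' @export
pearson_matrix <- function(predictors, subsample = 10000, seed = 1,
                           quiet = FALSE) {
  stopifnot(length(predictors) >= 2)
  ref <- predictors[[1]]
  for (p in predictors) check_same_geometry(ref, p, "predictor layers")
  ok <- Reduce(`&`, lapply(predictors, function(g) !is.na(g$values)))
  cells <- which(ok)
  if (!length(cells)) stop("no overlapping valid cells", call. = FALSE)
  if (length(cells) > subsample) {
    set.seed(seed)
    cells <- sample(cells, subsample)
  }
  x <- vapply(predictors, function(g) g$values[cells], numeric(length(cells)))
  const <- apply(x, 2, function(col) stats::sd(col) == 0)
  r <- suppressWarnings(stats::cor(x))
  diag(r) <- 1
  if (any(const) && !quiet) {
    message("constant layer(s), correlation undefined (treated as 0 when filtering): ",
            paste(colnames(x)[const], collapse = ", "))
  }
  r
}

#' k-fold cross-validation with variable jackknife
#'
#' Presences are partitioned into `k` folds (seeded); for each fold the
#' model is refitted on the remaining presences against the design's fixed
#' background and evaluated on the held-out fold. Reported metrics are fold
#' means. The jackknife refits the model withholding each layer in turn
#' (on the full presence set) and reports the test-AUC drop; it is reported
#' for interpretation and plays no role in ranking.
#'
#' @param design An `sdm_design`.
#' @param layers Layers of the model (default: all design layers).
#' @param k Number of folds (>= 2, and at most the presence count).
#' @param seed Seed for the fold assignment.
#' @param jackknife Also compute the leave-one-variable-out AUC drops.
#' @param ... Passed to [fit_maxent()].
#' @return List with `summary` (one-row tibble of fold-mean metrics),
#'   `folds` (per-fold tibble) and `jackknife` (tibble or `NULL`).
#' @export
kfold_cv <- function(design, layers = NULL, k = 10, seed = 1,
                     jackknife = FALSE, ...) {
  if (is.null(layers)) layers <- colnames(design$x_presence)
  n <- length(design$presence_cells)
  if (k < 2 || k > n) stop("k must be in [2, n_presence]", call. = FALSE)
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  rows <- vector("list", k)
  d <- design
  for (f in seq_len(k)) {
    d$train <- fold != f
    if (!any(!d$train)) stop("fold with zero presences", call. = FALSE)
    m <- fit_maxent(d, layers = layers, ...)
    rows[[f]] <- dplyr::mutate(eval_report(m, d), fold = f)
  }
  folds <- dplyr::bind_rows(rows)
  summ <- dplyr::summarise(folds, dplyr::across(
    c("auc_train", "auc_test", "auc_diff", "mtss",
      "omission_train", "omission_test"), mean))
  summ$k <- k
  jk <- NULL
  if (jackknife && length(layers) > 1) {
    full <- fit_maxent(design, layers = layers, ...)
    full_auc <- eval_report(full, design)$auc_test
    jk <- purrr::map_dfr(layers, function(nm) {
      m <- fit_maxent(design, layers = setdiff(layers, nm), ...)
      tibble::tibble(layer = nm,
                     auc_without = eval_report(m, design)$auc_test,
                     auc_drop = full_auc - eval_report(m, design)$auc_test)
    })
  }
  list(summary = summ, folds = folds, jackknife = jk)
}
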