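# The selection framework: univariate scale-of-effect optimization per
# variable, collinearity filtering at |r| >= 0.7, category-constrained
# enumeration of five-predictor candidate models, retention of the top ten
# by test AUC, and the multi-scale versus single-scale comparison.
#
# Layer naming convention throughout: "{VAR}_{scale}" (e.g. "ELEV_2400",
# "PLAND_Gr_14400"); the scale is the trailing integer.

#' Compose and parse layer names
#'
#' @param variable Base variable name (may itself contain underscores).
#' @param scale Window radius in metres.
#' @return `layer_name()`: the composed name. `layer_variable()` /
#'   `layer_scale()`: the parsed parts.
#' @export
layer_name <- function(variable, scale) paste0(variable, "_", scale)

#' @rdname layer_name
#' @param layer Composed layer name.
#' @export
layer_variable <- function(layer) sub("_[0-9]+$", "", layer)

#' @rdname layer_name
#' @export
layer_scale <- function(layer) as.numeric(sub("^.*_([0-9]+)$", "\\1", layer))

#' Enumerate the univariate fit grid
#'
#' One single-predictor fit specification per (variable, scale) pair; the
#' total is `length(variables) * length(ladder)`.
#'
#' @param variables Character vector of base variable names.
#' @param ladder Numeric vector of window radii, metres.
#' @return Tibble with `variable`, `scale`, `layer`.
#' @export
univariate_plan <- function(variables, ladder) {
  tidyr::crossing(variable = variables, scale = ladder) |>
    dplyr::mutate(layer = layer_name(.data$variable, .data$scale))
}

#' Univariate scale optimization
#'
#' Fits one single-predictor model per (variable, scale) against the shared
#' background of `design` and selects, per variable, the scale with the
#' highest test AUC; ties go to the smaller `auc_diff`, then to the smaller
#' scale. The design must contain a `"{variable}_{scale}"` layer for every
#' pair.
#'
#' @param design An `sdm_design` holding every `variable x scale` layer.
#' @param variables Base variable names.
#' @param ladder Window radii, metres.
#' @param ... Passed to [fit_maxent()].
#' @return Tibble (class `univariate_scaling`) with one row per fit:
#'   `variable`, `scale`, `layer`, `auc_train`, `auc_test`, `auc_diff`,
#'   `best` flag.
#' @export
univariate_scaling <- function(design, variables, ladder, ...) {
  plan <- univariate_plan(variables, ladder)
  missing_l <- setdiff(plan$layer, colnames(design$x_presence))
  if (length(missing_l)) {
    stop("design lacks layers: ", paste(missing_l, collapse = ", "),
         call. = FALSE)
  }
  res <- purrr::pmap_dfr(plan, function(variable, scale, layer) {
    m <- fit_maxent(design, layers = layer, ...)
    ev <- eval_report(m, design)
    tibble::tibble(variable = variable, scale = scale, layer = layer,
                   auc_train = ev$auc_train, auc_test = ev$auc_test,
                   auc_diff = ev$auc_diff)
  })
  res <- res |>
    dplyr::group_by(.data$variable) |>
    dplyr::arrange(dplyr::desc(.data$auc_test), .data$auc_diff, .data$scale,
                   .by_group = TRUE) |>
    dplyr::mutate(best = dplyr::row_number() == 1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$variable, .data$scale)
  class(res) <- c("univariate_scaling", class(res))
  res
}

#' Best scales from a univariate scaling table
#'
#' @param scaling A `univariate_scaling` tibble.
#' @return Tibble with one row per variable: `variable`, `scale`, `layer`,
#'   `auc_test`, `auc_diff`.
#' @export
best_scales <- function(scaling) {
  scaling |>
    dplyr::filter(.data$best) |>
    dplyr::select("variable", "scale", "layer", "auc_test", "auc_diff")
}

#' Collinearity filter at a correlation threshold
#'
#' Processes variable pairs with `|r| >= threshold` in decreasing `|r|`
#' (alphabetical pair order breaks exact ties) and drops the member with the
#' lower AUC -- unless one of the pair was already dropped, in which case
#' the pair is skipped. AUC ties drop the alphabetically later variable.
#'
#' @param best Tibble from [best_scales()] (`variable`, `layer`, `auc_test`).
#' @param corr Correlation matrix over the best-scale layers (see
#'   [pearson_matrix()]); `NA` entries are treated as zero correlation.
#' @param threshold Absolute-correlation threshold (default 0.7).
#' @return `best` with a `retained` logical column.
#' @export
collinearity_filter <- function(best, corr, threshold = 0.7) {
  stopifnot(all(best$layer %in% rownames(corr)))
  r <- abs(corr[best$layer, best$layer, drop = FALSE])
  r[is.na(r)] <- 0
  pairs <- which(upper.tri(r) & r >= threshold, arr.ind = TRUE)
  ord <- order(-r[pairs], rownames(r)[pairs[, 1]], colnames(r)[pairs[, 2]])
  pairs <- pairs[ord, , drop = FALSE]
  dropped <- rep(FALSE, nrow(best))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (dropped[i] || dropped[j]) next
    ai <- best$auc_test[i]; aj <- best$auc_test[j]
    drop_idx <- if (ai > aj) j else if (aj > ai) i
      else if (best$layer[i] <= best$layer[j]) j else i  # tie: keep earlier name
    dropped[drop_idx] <- TRUE
  }
  dplyr::mutate(best, retained = !dropped)
}

#' Enumerate category-constrained candidate models
#'
#' Full Cartesian product over the retained variables of each category: one
#' predictor per category, five categories, so the candidate count is the
#' product of the per-category sizes.
#'
#' @param retained_by_category Named list, one character vector of layer
#'   names per category; every category must be non-empty.
#' @return Tibble with `model_id` and one column per category.
#' @export
enumerate_candidates <- function(retained_by_category) {
  sizes <- lengths(retained_by_category)
  if (any(sizes == 0)) {
    stop("empty category: ",
         paste(names(retained_by_category)[sizes == 0], collapse = ", "),
         call. = FALSE)
  }
  grid <- do.call(tidyr::crossing, retained_by_category)
  grid <- dplyr::arrange(grid, dplyr::across(dplyr::everything()))
  dplyr::mutate(grid, model_id = paste0("M", sprintf("%03d", dplyr::row_number())),
                .before = 1)
}

candidate_layers <- function(candidates) {
  cols <- setdiff(names(candidates), c("model_id", "rank", "auc_train",
                                       "auc_test", "auc_diff"))
  lapply(seq_len(nrow(candidates)), function(i) {
    unlist(candidates[i, cols], use.names = FALSE)
  })
}

#' Evaluate, rank and retain candidate models
#'
#' Fits every candidate on the shared design (same background sample, so AUC
#' differences reflect the predictors), ranks by test AUC (ties: lower
#' `auc_diff`, then `model_id`), and re-evaluates the `top_k` best by k-fold
#' cross-validation with a variable jackknife.
#'
#' @param candidates Tibble from [enumerate_candidates()].
#' @param design An `sdm_design` containing every candidate layer.
#' @param top_k Models to retain (default 10; all if fewer candidates).
#' @param k Folds for the cross-validation of retained models.
#' @param cv Set `FALSE` to skip the fold re-evaluation (ranking only).
#' @param seed Seed for the fold assignment.
#' @param ... Passed to [fit_maxent()].
#' @return List with `ranked` (all candidates with split metrics and rank),
#'   `top` (retained subset with `cv_auc_test`, `cv_auc_diff` columns), and
#'   `jackknife` (per retained model).
#' @export
rank_and_retain <- function(candidates, design, top_k = 10, k = 10,
                            cv = TRUE, seed = 1, ...) {
  lays <- candidate_layers(candidates)
  evals <- purrr::map_dfr(lays, function(ll) {
    m <- fit_maxent(design, layers = ll, ...)
    ev <- eval_report(m, design)
    ev[, c("auc_train", "auc_test", "auc_diff")]
  })
  ranked <- dplyr::bind_cols(candidates, evals) |>
    dplyr::arrange(dplyr::desc(.data$auc_test), .data$auc_diff, .data$model_id) |>
    dplyr::mutate(rank = dplyr::row_number())
  top <- utils::head(ranked, top_k)
  jk <- NULL
  if (cv) {
    top_lays <- candidate_layers(top)
    cvs <- purrr::map(top_lays, function(ll) {
      kfold_cv(design, layers = ll, k = k, seed = seed, jackknife = TRUE, ...)
    })
    top$cv_auc_test <- vapply(cvs, function(z) z$summary$auc_test, numeric(1))
    top$cv_auc_diff <- vapply(cvs, function(z) z$summary$auc_diff, numeric(1))
    jk <- purrr::map2_dfr(cvs, top$model_id, function(z, id) {
      if (is.null(z$jackknife)) return(NULL)
      dplyr::mutate(z$jackknife, model_id = id)
    })
  }
  list(ranked = ranked, top = top, jackknife = jk)
}

#' Multi-scale versus single-scale comparison
#'
#' For each retained model, evaluates the same variable set with every
#' predictor forced to each single ladder scale, alongside the multi-scale
#' original: `k` models yield `k * (length(ladder) + 1)` evaluations. The
#' summary row gives the per-scale column averages (the mean over models).
#'
#' @param top Tibble of retained candidates (category columns hold layer
#'   names at the optimized scales).
#' @param design Design containing every variable at every ladder scale.
#' @param ladder Window radii, metres.
#' @param ... Passed to [fit_maxent()].
#' @return Tibble with `model_id`, `scale` (`"multi"` or the radius),
#'   `auc_test`, `auc_diff`, and a `best` flag per model.
#' @export
single_vs_multiscale <- function(top, design, ladder, ...) {
  lays <- candidate_layers(top)
  rows <- purrr::map2_dfr(lays, top$model_id, function(ll, id) {
    vars <- layer_variable(ll)
    sets <- c(list(multi = ll),
              stats::setNames(lapply(ladder, function(s) layer_name(vars, s)),
                              as.character(ladder)))
    purrr::imap_dfr(sets, function(layers, scale_lab) {
      missing_l <- setdiff(layers, colnames(design$x_presence))
      if (length(missing_l)) {
        stop("design lacks layers: ", paste(missing_l, collapse = ", "),
             call. = FALSE)
      }
      m <- fit_maxent(design, layers = layers, ...)
      ev <- eval_report(m, design)
      tibble::tibble(model_id = id, scale = scale_lab,
                     auc_test = ev$auc_test, auc_diff = ev$auc_diff)
    })
  })
  rows |>
    dplyr::group_by(.data$model_id) |>
    dplyr::mutate(best = .data$auc_test == max(.data$auc_test)) |>
    dplyr::ungroup()
}

#' Column averages of a scale-comparison table
#'
#' @param comparison Output of [single_vs_multiscale()].
#' @return Tibble with one row per scale: mean `auc_test` and `auc_diff`
#'   over models.
#' @export
scale_comparison_summary <- function(comparison) {
  comparison |>
    dplyr::group_by(.data$scale) |>
    dplyr::summarise(auc_test = mean(.data$auc_test),
                     auc_diff = mean(.data$auc_diff), .groups = "drop")
}
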