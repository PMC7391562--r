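# Presence-background maximum-entropy model with linear + quadratic features
# and L1 regularization, fitted by deterministic full-batch proximal
# gradient (FISTA with adaptive restart). The raw output is the Gibbs
# distribution over the background; the logistic output uses the entropy
# constant c = exp(H) so that an uninformative model scores 0.5 everywhere.

#' Build a presence-background sample design
#'
#' Samples background (pseudo-absence) cells from the cells of `mask` that
#' are valid in every predictor layer: uniformly without replacement by
#' default, or -- when a bias surface is supplied -- with replacement with
#' probability proportional to the surface, so the background represents the
#' survey-effort distribution (the standard MaxEnt bias-file semantics used
#' for Gaussian-kernel corrections). Presences are
#' randomly split into train and test partitions. The design stores raw
#' predictor values for every layer, so models on any subset of layers can
#' be fitted against the same background sample.
#'
#' @param occ Occurrence tibble (`x`, `y`).
#' @param predictors Named list of `sdm_grid` layers (names are layer ids,
#'   conventionally `"{VAR}_{scale}"`).
#' @param mask Binary `sdm_grid` delimiting the background region (see
#'   [buffer_mask()]).
#' @param n_background Background points requested (default 20,000). If the
#'   eligible pool is smaller the entire pool is used, with a warning.
#' @param bias Optional `sdm_grid` of positive sampling weights.
#' @param split Train fraction for presences (default 0.75).
#' @param seed Integer seed for background sampling and the split.
#' @return An object of class `sdm_design`.
#' @export
build_design <- function(occ, predictors, mask, n_background = 20000,
                         bias = NULL, split = 0.75, seed = 1) {
  stopifnot(length(predictors) >= 1, split > 0, split < 1)
  ref <- predictors[[1]]
  for (p in predictors) check_same_geometry(ref, p, "predictor layers")
  check_same_geometry(ref, mask, "mask and predictors")
  valid <- mask$values == 1 & !is.na(mask$values)
  for (p in predictors) valid <- valid & !is.na(p$values)
  pool <- which(valid)
  if (!length(pool)) stop("background pool is empty", call. = FALSE)
  set.seed(seed)
  if (!is.null(bias)) {
    # bias-file semantics: the background is a sample from the survey-effort
    # distribution, drawn with replacement so the weighting holds regardless
    # of pool size
    w <- bias$values[pool]
    if (any(is.na(w) | w < 0)) stop("bias surface must be non-negative on the pool",
                                    call. = FALSE)
    bg <- sample(pool, n_background, replace = TRUE, prob = w)
  } else if (length(pool) <= n_background) {
    if (length(pool) < n_background) {
      warning(sprintf("background pool (%d) smaller than requested %d; using all",
                      length(pool), n_background), call. = FALSE)
    }
    bg <- pool
  } else {
    bg <- sample(pool, n_background)
  }
  pc <- points_to_cells(occ$x, occ$y, ref)
  if (nrow(pc) < 2) stop("need at least 2 presences", call. = FALSE)
  if (nrow(pc) < 20) {
    warning("fewer than 20 presences; estimates will be unstable", call. = FALSE)
  }
  # keep both partitions non-empty whenever there are >= 2 presences
  n_train <- min(max(1L, round(split * nrow(pc))), nrow(pc) - 1L)
  train <- rep(FALSE, nrow(pc))
  train[sample.int(nrow(pc), n_train)] <- TRUE
  extract <- function(cells) {
    m <- vapply(predictors, function(p) p$values[cells], numeric(length(cells)))
    if (is.null(dim(m))) m <- matrix(m, nrow = length(cells))
    colnames(m) <- names(predictors)
    m
  }
  x_pres <- extract(pc$cell)
  if (any(!is.finite(x_pres))) {
    stop("presence cells carry nodata in a predictor; mask them upstream",
         call. = FALSE)
  }
  structure(
    list(x_presence = x_pres, x_background = extract(bg),
         presence_cells = pc$cell, background_cells = bg, train = train,
         grid = ref[c("cell_size", "origin", "crs")],
         n_background_requested = n_background, split = split, seed = seed,
         biased = !is.null(bias)),
    class = "sdm_design"
  )
}

#' @export
print.sdm_design <- function(x, ...) {
  cat(sprintf("<sdm_design> %d presences (%d train / %d test), %d background, %d layers\n",
              length(x$presence_cells), sum(x$train), sum(!x$train),
              length(x$background_cells), ncol(x$x_presence)))
  invisible(x)
}

# Phillips & Dudik default per-feature-class regularization for the
# linear+quadratic feature set, interpolated on presence count.
lq_beta <- function(n_presence) {
  bp <- c(0, 10, 17, 30, 100)
  bt <- c(1.3, 0.8, 0.5, 0.25, 0.05)
  stats::approx(bp, bt, xout = n_presence, rule = 2)$y
}

build_feature_spec <- function(x_ref, x_pres, features, reg_multiplier) {
  p <- ncol(x_ref)
  rng <- apply(x_ref, 2, range)
  vars <- colnames(x_ref)
  feat_names <- character(0); feat_var <- character(0); feat_kind <- character(0)
  if ("linear" %in% features) {
    feat_names <- c(feat_names, vars)
    feat_var <- c(feat_var, vars); feat_kind <- c(feat_kind, rep("linear", p))
  }
  if ("quadratic" %in% features) {
    feat_names <- c(feat_names, paste0(vars, "^2"))
    feat_var <- c(feat_var, vars); feat_kind <- c(feat_kind, rep("quadratic", p))
  }
  spec <- list(min = rng[1, ], max = rng[2, ], feat_names = feat_names,
               feat_var = feat_var, feat_kind = feat_kind)
  m <- nrow(x_pres)
  fp <- expand_features(x_pres, spec)
  beta0 <- lq_beta(m) * reg_multiplier
  sd_floor <- 1 / sqrt(m)
  spec$beta <- beta0 * pmax(apply(fp, 2, stats::sd), sd_floor) / sqrt(m)
  spec
}

expand_features <- function(x, spec) {
  rngd <- spec$max - spec$min
  z <- sweep(x, 2, spec$min)
  z <- sweep(z, 2, ifelse(rngd > 0, rngd, 1), "/")
  z <- pmin(pmax(z, 0), 1)
  out <- matrix(0, nrow(x), length(spec$feat_names))
  colnames(out) <- spec$feat_names
  for (k in seq_along(spec$feat_names)) {
    col <- z[, spec$feat_var[k]]
    out[, k] <- if (spec$feat_kind[k] == "quadratic") col^2 else col
  }
  out
}

logsumexp <- function(v) { mx <- max(v); mx + log(sum(exp(v - mx))) }

maxent_objective <- function(lam, fbar, Fb, beta) {
  -sum(lam * fbar) + logsumexp(as.vector(Fb %*% lam)) + sum(beta * abs(lam))
}

#' Fit a maximum-entropy model
#'
#' Maximizes the penalized presence log-likelihood
#' `mean_presence(lambda . f) - log Z(lambda) - sum_j beta_j |lambda_j|`
#' where `Z` normalizes the Gibbs distribution `q(x) = exp(lambda . f(x))/Z`
#' over the background (presences are appended to the background for
#' normalization, the MaxEnt "add samples to background" rule). Features are
#' the predictors rescaled to `[0, 1]` by background min/max, plus their
#' squares. Per-feature L1 weights follow the published default
#' regularization for the linear+quadratic feature class, interpolated on
#' presence count and scaled by `reg_multiplier`. The optimizer is
#' deterministic; convergence is declared when the objective changes by less
#' than `tol`.
#'
#' @param design An `sdm_design`.
#' @param layers Character vector of layer names to use (default: all layers
#'   in the design).
#' @param features Feature classes, subset of `c("linear", "quadratic")`.
#' @param reg_multiplier Multiplier on the default regularization (1 = the
#'   published defaults).
#' @param max_iter Iteration cap (default 5,000).
#' @param tol Absolute objective-change tolerance.
#' @param train_only Fit on the training presence partition only (default);
#'   set `FALSE` to use all presences.
#' @return Object of class `maxent_model` with elements `lambdas`, `logZ`,
#'   `entropy`, `spec`, `converged`, `iterations`, `objective`.
#' @export
fit_maxent <- function(design, layers = NULL,
                       features = c("linear", "quadratic"),
                       reg_multiplier = 1, max_iter = 5000, tol = 1e-6,
                       train_only = TRUE) {
  stopifnot(inherits(design, "sdm_design"))
  if (is.null(layers)) layers <- colnames(design$x_presence)
  missing_l <- setdiff(layers, colnames(design$x_presence))
  if (length(missing_l)) {
    stop("layers not in design: ", paste(missing_l, collapse = ", "),
         call. = FALSE)
  }
  xp_all <- design$x_presence[, layers, drop = FALSE]
  xp <- if (train_only) xp_all[design$train, , drop = FALSE] else xp_all
  xb <- design$x_background[, layers, drop = FALSE]
  if (any(!is.finite(xp)) || any(!is.finite(xb))) {
    stop("non-finite predictor values in design", call. = FALSE)
  }
  x_ref <- rbind(xb, xp)          # background with samples added
  spec <- build_feature_spec(x_ref, xp, features, reg_multiplier)
  if (length(spec$feat_names) < 2) stop("need at least 2 features", call. = FALSE)
  Fp <- expand_features(xp, spec)
  Fb <- expand_features(x_ref, spec)
  fbar <- colMeans(Fp)
  beta <- spec$beta
  p <- length(fbar)

  smooth_val <- function(lam) {
    -sum(lam * fbar) + logsumexp(as.vector(Fb %*% lam))
  }
  smooth_grad <- function(lam) {
    e <- as.vector(Fb %*% lam)
    w <- exp(e - max(e)); w <- w / sum(w)
    as.vector(crossprod(Fb, w)) - fbar
  }
  soft <- function(v, t) sign(v) * pmax(abs(v) - t, 0)

  lam <- rep(0, p); ylam <- lam; tk <- 1
  step <- 1
  obj_old <- maxent_objective(lam, fbar, Fb, beta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (any(!is.finite(ylam))) { ylam <- lam; tk <- 1 }
    gy <- smooth_grad(ylam)
    fy <- smooth_val(ylam)
    if (!is.finite(fy) || any(!is.finite(gy))) { ylam <- lam; tk <- 1
      gy <- smooth_grad(ylam); fy <- smooth_val(ylam) }
    repeat {
      cand <- soft(ylam - step * gy, step * beta)
      dv <- cand - ylam
      sv <- smooth_val(cand)
      if (is.finite(sv) &&
          sv <= fy + sum(gy * dv) + sum(dv^2) / (2 * step) + 1e-12) break
      step <- step / 2
      if (step < 1e-12) break
    }
    lam_new <- cand
    obj_new <- maxent_objective(lam_new, fbar, Fb, beta)
    if (!is.finite(obj_new) || obj_new > obj_old) {   # adaptive restart
      ylam <- lam; tk <- 1
      obj_new <- obj_old; lam_new <- lam
      step <- step / 2
      if (step < 1e-12) { converged <- TRUE; break }
    } else {
      t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
      ylam <- lam_new + ((tk - 1) / t_new) * (lam_new - lam)
      tk <- t_new
      if (abs(obj_old - obj_new) < tol && iter > 1) {
        lam <- lam_new; obj_old <- obj_new
        converged <- TRUE
        break
      }
      lam <- lam_new; obj_old <- obj_new
      step <- min(step * 1.5, 1e3)
    }
  }
  e <- as.vector(Fb %*% lam)
  logZ <- logsumexp(e)
  praw <- exp(e - logZ)
  entropy <- -sum(praw * log(pmax(praw, 1e-300)))
  structure(
    list(lambdas = stats::setNames(lam, spec$feat_names), spec = spec,
         layers = layers, logZ = logZ, entropy = entropy,
         converged = converged, iterations = iter, objective = -obj_old,
         n_presence = nrow(xp), n_background = nrow(xb),
         reg_multiplier = reg_multiplier),
    class = "maxent_model"
  )
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> %d features on %d layers | H = %.4f | %s in %d iters\n",
              length(x$lambdas), length(x$layers), x$entropy,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  nz <- x$lambdas[x$lambdas != 0]
  if (length(nz)) {
    cat("  non-zero coefficients:\n")
    for (nm in names(nz)) cat(sprintf("    %-24s %+.5f\n", nm, nz[nm]))
  }
  invisible(x)
}

# score matrix rows of raw predictor values
maxent_scores <- function(model, x, type) {
  Fm <- expand_features(x[, model$layers, drop = FALSE], model$spec)
  e <- as.vector(Fm %*% model$lambdas)
  q <- exp(e - model$logZ)
  if (type == "raw") return(q)
  cq <- exp(model$entropy) * q
  cq / (1 + cq)
}

#' Predict from a fitted maximum-entropy model
#'
#' `type = "raw"` returns the Gibbs density `q` (summing to 1 over the
#' training background); `type = "logistic"` returns
#' `c q / (1 + c q)` with `c = exp(H)`, `H` the entropy of the fitted raw
#' distribution, so a model indistinguishable from background scores 0.5.
#'
#' @param object A `maxent_model`.
#' @param newdata Named list of `sdm_grid` layers covering the model's
#'   layers, or a matrix/data frame of raw predictor values.
#' @param type `"logistic"` (default) or `"raw"`.
#' @param ... Unused.
#' @return An `sdm_grid` when `newdata` is a grid list, else a numeric
#'   vector. Cells with nodata in any model layer are nodata.
#' @export
predict.maxent_model <- function(object, newdata, type = c("logistic", "raw"),
                                 ...) {
  type <- match.arg(type)
  if (is.list(newdata) && inherits(newdata[[1]], "sdm_grid")) {
    ref <- newdata[[object$layers[1]]]
    v <- lapply(object$layers, function(nm) {
      g <- newdata[[nm]]
      if (is.null(g)) stop("newdata is missing layer ", nm, call. = FALSE)
      check_same_geometry(ref, g, "prediction layers")
      g$values
    })
    ok <- Reduce(`&`, lapply(v, function(m) !is.na(m)))
    x <- do.call(cbind, lapply(v, function(m) m[ok]))
    colnames(x) <- object$layers
    out <- ref
    res <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
    res[ok] <- maxent_scores(object, x, type)
    out$values <- res
    return(out)
  }
  x <- as.matrix(newdata)
  maxent_scores(object, x, type)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted maximum-entropy model
#'
#' @param x A `maxent_model`.
#' @param ... Unused.
#' @return Tibble with one row per feature: `feature`, `layer`, `kind`,
#'   `estimate`, `penalty`.
#' @method tidy maxent_model
#' @export
tidy.maxent_model <- function(x, ...) {
  tibble::tibble(feature = x$spec$feat_names, layer = x$spec$feat_var,
                 kind = x$spec$feat_kind,
                 estimate = unname(x$lambdas), penalty = unname(x$spec$beta))
}

#' @rdname tidy.maxent_model
#' @return `glance()`: one-row tibble with fit-level summaries.
#' @method glance maxent_model
#' @export
glance.maxent_model <- function(x, ...) {
  tibble::tibble(n_presence = x$n_presence, n_background = x$n_background,
                 n_features = length(x$lambdas),
                 entropy = x$entropy, objective = x$objective,
                 iterations = x$iterations, converged = x$converged)
}

#' Serialize a fitted model to JSON
#'
#' @param model A `maxent_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maxent <- function(model, path) {
  jsonlite::write_json(
    list(layers = model$layers,
         lambdas = as.list(model$lambdas),
         feature_min = as.list(model$spec$min),
         feature_max = as.list(model$spec$max),
         beta = as.list(stats::setNames(model$spec$beta, model$spec$feat_names)),
         logZ = model$logZ, entropy = model$entropy,
         converged = model$converged, iterations = model$iterations,
         n_presence = model$n_presence, n_background = model$n_background),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
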