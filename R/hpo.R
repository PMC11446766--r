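# Hyperparameter optimization layer: published search spaces, the
# exhaustive grid-search baseline, and IBAS-driven hyperparameter
# evolution with cross-validated fitness.  Classifiers are consumed
# through a uniform fit / predict-probability adapter (glmnet, e1071,
# xgboost); their internals are out of scope here.

#' Hyperparameter search space for a model family
#'
#' The published optimization ranges: logistic regression - inverse
#' regularization strength \[0.01, 100\] step 10 and penalty in \{L1, L2\};
#' SVM (RBF) - cost and gamma both \[0.01, 100\] step 10; XGBoost -
#' learning rate \[0.01, 1\] step 0.1, maximum depth \[1, 20\] step 0.5
#' (rounded to integers), boosting rounds \[1, 100\] step 10.
#'
#' @param model_kind `"lr"`, `"svm"` or `"xgb"`.
#' @return object of class `hpo_space`: list with `model_kind` and
#'   `specs`, each spec a list (name, kind, low, high, step or levels).
#' @export
hpo_space <- function(model_kind = c("xgb", "lr", "svm")) {
  model_kind <- match.arg(model_kind)
  cont <- function(name, low, high, step) list(name = name, kind = "continuous", low = low, high = high, step = step)
  intg <- function(name, low, high, step) list(name = name, kind = "integer", low = low, high = high, step = step)
  catg <- function(name, levels) list(name = name, kind = "categorical", levels = levels)
  specs <- switch(model_kind,
    lr = list(cont("reg_c", 0.01, 100, 10), catg("penalty", c("l1", "l2"))),
    svm = list(cont("cost", 0.01, 100, 10), cont("gamma", 0.01, 100, 10)),
    xgb = list(cont("learning_rate", 0.01, 1, 0.1),
               intg("max_depth", 1, 20, 0.5),
               intg("nrounds", 1, 100, 10)))
  structure(list(model_kind = model_kind, specs = specs), class = "hpo_space")
}

#' Decode a unit-cube position into a hyperparameter assignment
#'
#' Continuous dimensions are scaled affinely into their range; integer
#' dimensions are scaled then rounded half-up; binary categorical
#' dimensions are thresholded at 0.5 (below 0.5 = first level).
#'
#' @param u numeric vector in \[0, 1\], one entry per spec.
#' @param space an [hpo_space()].
#' @return named list assignment, always in range.
#' @export
decode_position <- function(u, space) {
  specs <- space$specs
  if (length(u) < length(specs)) stopf("position has %d entries, space needs %d", length(u), length(specs))
  out <- list()
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    out[[s$name]] <- switch(s$kind,
      continuous = s$low + u[i] * (s$high - s$low),
      integer = min(max(round_half_up(s$low + u[i] * (s$high - s$low)), s$low), s$high),
      categorical = if (u[i] < 0.5) s$levels[1] else s$levels[2])
  }
  out
}

# per-spec grid values as printed: both endpoints included, the last
# point clipped to the upper bound; integer specs rounded, duplicates
# dropped
.grid_values <- function(s) {
  if (s$kind == "categorical") return(s$levels)
  k <- ceiling((s$high - s$low) / s$step - 1e-9)
  vals <- pmin(s$low + s$step * (0:k), s$high)
  if (s$kind == "integer") vals <- unique(pmin(pmax(round_half_up(vals), s$low), s$high))
  vals
}

# ---- classifier adapters ---------------------------------------------------

# fit + predicted positive-class probability, uniform across families
.fit_predict <- function(model_kind, assignment, X_train, y_train, X_val, seed = 1L) {
  switch(model_kind,
    lr = {
      alpha <- if (assignment$penalty == "l1") 1 else 0
      lam <- 1 / (assignment$reg_c * nrow(X_train))
      if (ncol(X_train) >= 2) {
        fit <- glmnet::glmnet(X_train, y_train, family = "binomial",
                              alpha = alpha, lambda = lam, standardize = FALSE)
        as.numeric(stats::predict(fit, X_val, type = "response"))
      } else {
        # the elastic-net solver needs >= 2 columns; a single-feature
        # model is fitted unpenalized (boundary fits are fine here: only
        # the score ranking feeds the fitness)
        df <- data.frame(x = X_train[, 1], y = y_train)
        fit <- suppressWarnings(stats::glm(y ~ x, data = df, family = stats::binomial()))
        as.numeric(stats::predict(fit, data.frame(x = X_val[, 1]), type = "response"))
      }
    },
    svm = with_seed(seed, {   # Platt scaling uses internal CV -> pin the RNG
      fit <- e1071::svm(X_train, factor(y_train, levels = c(0, 1)),
                        cost = assignment$cost, gamma = assignment$gamma,
                        kernel = "radial", probability = TRUE, scale = FALSE)
      pr <- stats::predict(fit, X_val, probability = TRUE)
      as.numeric(attr(pr, "probabilities")[, "1"])
    }),
    xgb = {
      dtr <- xgboost::xgb.DMatrix(X_train, label = y_train, nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = assignment$learning_rate,
                      max_depth = assignment$max_depth, nthread = 1,
                      tree_method = "exact"),
        data = dtr, nrounds = assignment$nrounds, verbose = 0)
      as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(X_val, nthread = 1)))
    },
    stopf("unknown model kind '%s'", model_kind))
}

.metric_fun <- function(metric) {
  switch(metric,
    roc_auc = function(y, s) roc_auc(y, s),
    acc = function(y, s) confusion_metrics(y, s, 0.5)$ACC,
    f1 = function(y, s) confusion_metrics(y, s, 0.5)$F1,
    stopf("unknown metric '%s' (use roc_auc, acc or f1)", metric))
}

# Precompute stratified folds and per-fold z-score-normalized matrices so
# repeated fitness evaluations share the split work.  Normalization
# parameters are fitted on the training folds only and applied to the
# held-out fold.
.cv_context <- function(X, y, k, seed) {
  X <- as.matrix(X); y <- as.integer(y)
  folds <- stratified_kfold(y, k, seed)
  prep <- lapply(seq_len(k), function(f) {
    tr <- folds != f
    if (length(unique(y[!tr])) < 2 || length(unique(y[tr])) < 2)
      stopf("fold %d is missing a class", f)
    mu <- colMeans(X[tr, , drop = FALSE])
    sg <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sg[sg == 0] <- 1
    list(X_train = scale(X[tr, , drop = FALSE], mu, sg),
         y_train = y[tr],
         X_val = scale(X[!tr, , drop = FALSE], mu, sg),
         y_val = y[!tr])
  })
  list(folds = prep, k = k, seed = seed)
}

.cv_fitness_ctx <- function(assignment, ctx, model_kind, metric_fn, feature_keep = NULL) {
  vals <- vapply(ctx$folds, function(f) {
    Xtr <- f$X_train; Xva <- f$X_val
    if (!is.null(feature_keep)) {
      Xtr <- Xtr[, feature_keep, drop = FALSE]
      Xva <- Xva[, feature_keep, drop = FALSE]
    }
    scores <- .fit_predict(model_kind, assignment, Xtr, f$y_train, Xva, seed = ctx$seed)
    metric_fn(f$y_val, scores)
  }, numeric(1))
  mean(vals)
}

#' Cross-validated fitness of a hyperparameter assignment
#'
#' Stratified k-fold (deterministic given `seed`); per fold, z-score
#' normalization is fitted on the training folds and applied to the
#' held-out fold, the designated classifier is trained with `assignment`,
#' and the held-out fold is scored.  Returns the mean metric across
#' folds, in \[0, 1\].
#'
#' @param assignment named list of hyperparameters (see [hpo_space()]).
#' @param X predictor matrix; `y` binary outcome.
#' @param y binary outcome vector.
#' @param model_kind `"lr"`, `"svm"` or `"xgb"`.
#' @param k folds (default 5).
#' @param metric `"roc_auc"` (default), `"acc"` or `"f1"`.
#' @param seed integer seed for the fold assignment.
#' @return mean cross-validated metric.
#' @export
cv_fitness <- function(assignment, X, y, model_kind, k = 5L,
                       metric = "roc_auc", seed = 1L) {
  ctx <- .cv_context(X, y, k, seed)
  .cv_fitness_ctx(assignment, ctx, model_kind, .metric_fun(metric))
}

.assignment_df <- function(assignments, fitness) {
  hist <- do.call(rbind, lapply(assignments, function(a) as.data.frame(a, stringsAsFactors = FALSE)))
  hist$fitness <- fitness
  hist
}

#' Exhaustive grid search over a hyperparameter space
#'
#' Enumerates the Cartesian grid defined by each spec's range and step
#' (endpoints included, final point clipped to the upper bound, integer
#' grids deduplicated after rounding), evaluates [cv_fitness()] for every
#' combination, and returns the argmax; ties are broken by enumeration
#' order.
#'
#' @inheritParams cv_fitness
#' @param space an [hpo_space()].
#' @return object of class `hpo_result`: `best_assignment`,
#'   `best_fitness`, `history` (one row per evaluation), `evaluations`,
#'   `method = "grid"`.
#' @export
grid_search <- function(space, X, y, k = 5L, metric = "roc_auc", seed = 1L) {
  stopifnot(inherits(space, "hpo_space"))
  vals <- lapply(space$specs, .grid_values)
  names(vals) <- vapply(space$specs, `[[`, "", "name")
  grid <- expand.grid(vals, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0) stopf("empty grid")
  ctx <- .cv_context(X, y, k, seed)
  mfun <- .metric_fun(metric)
  assignments <- lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, , drop = FALSE]))
  fitness <- vapply(assignments, .cv_fitness_ctx, numeric(1),
                    ctx = ctx, model_kind = space$model_kind, metric_fn = mfun)
  best <- which.max(fitness)
  structure(list(best_assignment = assignments[[best]], best_fitness = fitness[best],
                 history = .assignment_df(assignments, fitness),
                 evaluations = length(fitness), method = "grid"),
            class = "hpo_result")
}

#' Evolve hyperparameters with IBAS
#'
#' Runs the IBAS optimizer over the unit cube (one dimension per
#' hyperparameter, plus one binary mask dimension per feature when
#' `feature_mask = TRUE`) with objective `-cv_fitness(decode(u))`.  Stops
#' early when the best fitness improves by less than `plateau_tol` over
#' `plateau_patience` consecutive iterations.  Because every objective
#' call is a k-fold model fit, the random-walk refinement is applied once
#' at termination with a reduced evaluation cap rather than every
#' iteration.
#'
#' The feature-mask encoding (a per-feature dimension thresholded at 0.5,
#' features below threshold dropped; all-dropped proposals fall back to
#' the full feature set) is this package's interpretation of joint
#' hyperparameter optimization and feature selection; it is an extension,
#' off by default.
#'
#' @inheritParams grid_search
#' @param cfg an [optimizer_config()]; sensible reduced defaults are
#'   population 10, 30 iterations.
#' @param feature_mask logical; append per-feature selection dimensions.
#' @return `hpo_result` with `method = "ibas"`; when `feature_mask` is on,
#'   also `selected_features`.
#' @export
evolve_hyperparameters <- function(space, X, y,
                                   cfg = optimizer_config(population_size = 10L,
                                                          iterations = 30L,
                                                          walk_mode = "final",
                                                          walk_step_init = 0.25,
                                                          walk_step_threshold = 0.01,
                                                          walk_max_evals = 60L,
                                                          plateau_patience = 20L),
                                   k = 5L, metric = "roc_auc",
                                   feature_mask = FALSE) {
  stopifnot(inherits(space, "hpo_space"))
  X <- as.matrix(X)
  ctx <- .cv_context(X, y, k, cfg$seed)
  mfun <- .metric_fun(metric)
  nhp <- length(space$specs)
  dims <- nhp + if (feature_mask) ncol(X) else 0L
  hist_env <- new.env(parent = emptyenv())
  hist_env$assignments <- list(); hist_env$fitness <- numeric(0)
  objective <- function(U) {
    vapply(seq_len(nrow(U)), function(i) {
      u <- U[i, ]
      a <- decode_position(u[seq_len(nhp)], space)
      keep <- if (feature_mask) {
        kp <- which(u[(nhp + 1):dims] >= 0.5)
        if (length(kp) == 0) seq_len(ncol(X)) else kp
      } else NULL
      f <- .cv_fitness_ctx(a, ctx, space$model_kind, mfun, feature_keep = keep)
      hist_env$assignments[[length(hist_env$assignments) + 1L]] <- a
      hist_env$fitness <- c(hist_env$fitness, f)
      -f
    }, numeric(1))
  }
  res <- run_optimizer(objective, search_space(0, 1, dims), cfg, variant = "IBAS")
  if (length(hist_env$fitness) == 0) stopf("no successful fitness evaluations")
  u_best <- res$best$position
  best_assignment <- decode_position(u_best[seq_len(nhp)], space)
  out <- list(best_assignment = best_assignment, best_fitness = -res$best$fitness,
              history = .assignment_df(hist_env$assignments, hist_env$fitness),
              evaluations = length(hist_env$fitness), method = "ibas",
              trace = -res$trace, optimizer = res)
  if (feature_mask) {
    kp <- which(u_best[(nhp + 1):dims] >= 0.5)
    out$selected_features <- if (length(kp) == 0) colnames(X) else colnames(X)[kp]
  }
  structure(out, class = "hpo_result")
}

#' @export
print.hpo_result <- function(x, ...) {
  cat(sprintf("%s search: best fitness %.4f over %d evaluations\n",
              x$method, x$best_fitness, x$evaluations))
  cat("best assignment:\n")
  for (nm in names(x$best_assignment))
    cat(sprintf("  %s = %s\n", nm, format(x$best_assignment[[nm]], digits = 5)))
  invisible(x)
}
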