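# Headless one-step analysis pipeline: leakage-safe data cleaning,
# stratified train/test split, IBAS hyperparameter evolution on the
# training portion, final refit, evaluation panels and risk reports.

#' Pipeline configuration
#'
#' @param population_size,iteration_count IBAS budget for the
#'   hyperparameter evolution stage.
#' @param test_set_proportion held-out fraction in (0, 1) (default 0.2).
#' @param cv_folds folds for the fitness cross-validation (>= 2).
#' @param seed master seed; every stochastic stage derives from it.
#' @param model_kind `"xgb"`, `"lr"` or `"svm"`.
#' @param metric fitness metric (`"roc_auc"`, `"acc"`, `"f1"`).
#' @param impute,winsorize,normalize,balance cleaning switches: median /
#'   mode imputation, outlier winsorization at median +/- 3 IQR/1.349,
#'   z-score normalization, random minority oversampling (training rows
#'   only).
#' @param normalization_scope `"train_only"` (default; parameters fitted
#'   on training rows) or `"global"` (parameters fitted on all rows,
#'   reproducing pipelines that normalize before splitting - leaks test
#'   statistics and exists only for compatibility).
#' @param feature_selection logical; enable the IBAS feature-mask
#'   extension.
#' @param risk_threshold probability at or above which a subject is
#'   banded "high" (default 0.5).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(population_size = 10L, iteration_count = 30L,
                            test_set_proportion = 0.2, cv_folds = 5L, seed = 1L,
                            model_kind = "xgb", metric = "roc_auc",
                            impute = TRUE, winsorize = TRUE, normalize = TRUE,
                            balance = FALSE,
                            normalization_scope = c("train_only", "global"),
                            feature_selection = FALSE, risk_threshold = 0.5) {
  structure(list(population_size = as.integer(population_size),
                 iteration_count = as.integer(iteration_count),
                 test_set_proportion = test_set_proportion,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed),
                 model_kind = model_kind, metric = metric,
                 impute = impute, winsorize = winsorize, normalize = normalize,
                 balance = balance,
                 normalization_scope = match.arg(normalization_scope),
                 feature_selection = feature_selection,
                 risk_threshold = risk_threshold),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Every violated invariant yields a named diagnostic message; a valid
#' configuration returns an empty character vector.
#'
#' @param cfg a [pipeline_config()].
#' @return character vector of diagnostics (empty = valid).
#' @export
validate_config <- function(cfg) {
  d <- character(0)
  chk <- function(ok, msg) if (!ok) d <<- c(d, msg)
  chk(cfg$population_size >= 1, "population_size: must be >= 1")
  chk(cfg$iteration_count >= 1, "iteration_count: must be >= 1")
  chk(is.numeric(cfg$test_set_proportion) &&
        cfg$test_set_proportion > 0 && cfg$test_set_proportion < 1,
      "test_set_proportion: must be in (0, 1)")
  chk(cfg$cv_folds >= 2, "cv_folds: must be >= 2")
  chk(cfg$model_kind %in% c("xgb", "lr", "svm"),
      "model_kind: must be one of xgb, lr, svm")
  chk(cfg$metric %in% c("roc_auc", "acc", "f1"),
      "metric: must be one of roc_auc, acc, f1")
  chk(is.numeric(cfg$risk_threshold) && cfg$risk_threshold > 0 && cfg$risk_threshold < 1,
      "risk_threshold: must be in (0, 1)")
  d
}

# column-wise cleaning parameters fitted on the fitting rows only
.fit_cleaning <- function(df, fit_rows, cfg) {
  pred <- setdiff(names(df), "outcome")
  params <- list()
  for (nm in pred) {
    x <- df[[nm]][fit_rows]
    # type decided from the fitting rows only: held-out values must not
    # influence any fitted artifact
    binary <- length(unique(stats::na.omit(x))) <= 2
    if (binary) {
      tb <- table(stats::na.omit(x))
      params[[nm]] <- list(binary = TRUE,
                           mode = as.numeric(names(tb)[which.max(tb)]))
    } else {
      med <- stats::median(x, na.rm = TRUE)
      iqr <- stats::IQR(x, na.rm = TRUE)
      halfwidth <- 3 * iqr / 1.349          # 3 robust SDs
      # normalization moments measured after imputation + winsorization
      xi <- ifelse(is.na(x), med, x)
      if (cfg$winsorize) xi <- pmin(pmax(xi, med - halfwidth), med + halfwidth)
      params[[nm]] <- list(binary = FALSE, median = med,
                           win_lo = med - halfwidth, win_hi = med + halfwidth,
                           mean = mean(xi), sd = ifelse(stats::sd(xi) > 0, stats::sd(xi), 1))
    }
  }
  params
}

.apply_cleaning <- function(df, params, cfg, log_env = NULL) {
  note <- function(what, n) if (!is.null(log_env) && n > 0)
    log_env$log <- rbind(log_env$log, data.frame(action = what, cells = n))
  for (nm in names(params)) {
    p <- params[[nm]]
    x <- df[[nm]]
    na <- is.na(x)
    if (cfg$impute && any(na)) {
      x[na] <- if (p$binary) p$mode else p$median
      note(paste0("impute:", nm), sum(na))
    }
    if (!p$binary) {
      if (cfg$winsorize) {
        out <- x < p$win_lo | x > p$win_hi
        x <- pmin(pmax(x, p$win_lo), p$win_hi)
        note(paste0("winsorize:", nm), sum(out, na.rm = TRUE))
      }
      if (cfg$normalize) x <- (x - p$mean) / p$sd
    }
    df[[nm]] <- x
  }
  df
}

#' Clean a cohort table
#'
#' Missing continuous cells are imputed with the fitting-rows median and
#' binary cells with the mode; outliers are winsorized at median +/- 3
#' IQR/1.349; continuous columns are z-score normalized.  All parameters
#' are fitted on `fit_rows` (default: all rows) and applied to the whole
#' table, so a training-only fit never sees held-out values.  Optional
#' random oversampling of the minority class duplicates fitting rows
#' only.
#'
#' @param table cohort data.frame with `outcome`.
#' @param cfg a [pipeline_config()].
#' @param fit_rows logical or integer index of rows used to fit cleaning
#'   parameters.
#' @return list with `table` (cleaned), `params` (fitted parameters),
#'   `oversampled_rows` (indices appended by balancing, training scope),
#'   and `log` (action counts).
#' @export
clean_cohort <- function(table, cfg = pipeline_config(), fit_rows = seq_len(nrow(table))) {
  df <- as.data.frame(table)
  if (is.logical(fit_rows)) fit_rows <- which(fit_rows)
  pred <- setdiff(names(df), "outcome")
  all_na <- pred[vapply(pred, function(nm) all(is.na(df[[nm]][fit_rows])), logical(1))]
  if (length(all_na)) stopf("column(s) entirely missing on the fitting rows: %s",
                            paste(all_na, collapse = ", "))
  log_env <- new.env(); log_env$log <- data.frame(action = character(0), cells = numeric(0))
  params <- .fit_cleaning(df, fit_rows, cfg)
  df <- .apply_cleaning(df, params, cfg, log_env)
  oversampled <- integer(0)
  if (cfg$balance) {
    y_fit <- df$outcome[fit_rows]
    tab <- table(y_fit)
    if (length(tab) == 2 && tab[1] != tab[2]) {
      minority <- as.numeric(names(tab)[which.min(tab)])
      need <- abs(diff(as.numeric(tab)))
      cand <- fit_rows[y_fit == minority]
      oversampled <- with_seed(cfg$seed + 7L,
                               sample(cand, need, replace = TRUE))
      log_env$log <- rbind(log_env$log,
                           data.frame(action = "oversample", cells = need))
    }
  }
  list(table = df, params = params, oversampled_rows = oversampled, log = log_env$log)
}

# stratified train/test split; depends only on y and the seed
.stratified_split <- function(y, test_prop, seed) {
  test <- integer(0)
  with_seed(seed, {
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      n_test <- round(length(idx) * test_prop)
      test <- c(test, idx[sample.int(length(idx), n_test)])
    }
  })
  sort(test)
}

#' One-step analysis pipeline
#'
#' The full headless pipeline: stratified train/test split, cleaning
#' fitted on training rows, IBAS hyperparameter evolution (optionally
#' with feature selection) on the training portion with cross-validated
#' fitness, final refit on the full cleaned training set, and one
#' evaluation of the held-out test set.  All artifacts can be written to
#' an output directory.
#'
#' @param data cohort data.frame, or path to a cohort CSV.
#' @param cfg a [pipeline_config()]; invalid configurations abort with
#'   the diagnostics from [validate_config()].
#' @param out_dir optional directory for the JSON report, metric panels,
#'   convergence trace and per-subject risk CSVs.
#' @return object of class `run_report`: config echo, cleaning log and
#'   parameters, HPO result, train/test metric panels, selected
#'   features, per-subject test risk probabilities and bands.
#' @export
one_step <- function(data, cfg = pipeline_config(), out_dir = NULL) {
  diags <- validate_config(cfg)
  if (length(diags)) stopf("invalid configuration:\n  %s", paste(diags, collapse = "\n  "))
  df <- if (is.character(data)) read_cohort(data) else as.data.frame(data)
  if (!"outcome" %in% names(df)) stopf("data must contain an 'outcome' column")

  y <- as.integer(df$outcome)
  test_idx <- .stratified_split(y, cfg$test_set_proportion, cfg$seed)
  train_idx <- setdiff(seq_len(nrow(df)), test_idx)

  cleaned <- clean_cohort(df, cfg, fit_rows = train_idx)
  cdf <- cleaned$table
  train_rows <- c(train_idx, cleaned$oversampled_rows)
  pred <- setdiff(names(cdf), "outcome")
  X_train <- as.matrix(cdf[train_rows, pred]); y_train <- y[train_rows]
  X_test <- as.matrix(cdf[test_idx, pred]); y_test <- y[test_idx]

  space <- hpo_space(cfg$model_kind)
  ocfg <- optimizer_config(population_size = cfg$population_size,
                           iterations = cfg$iteration_count, seed = cfg$seed,
                           walk_mode = "final", walk_step_init = 0.25,
                           walk_step_threshold = 0.01, walk_max_evals = 60L,
                           plateau_patience = 20L)
  hpo <- evolve_hyperparameters(space, X_train, y_train, cfg = ocfg,
                                k = cfg$cv_folds, metric = cfg$metric,
                                feature_mask = cfg$feature_selection)
  features <- hpo$selected_features %||% pred

  train_scores <- .fit_predict(cfg$model_kind, hpo$best_assignment,
                               X_train[, features, drop = FALSE], y_train,
                               X_train[, features, drop = FALSE], seed = cfg$seed)
  test_scores <- .fit_predict(cfg$model_kind, hpo$best_assignment,
                              X_train[, features, drop = FALSE], y_train,
                              X_test[, features, drop = FALSE], seed = cfg$seed)
  train_panel <- metrics_panel(y_train, train_scores)
  test_panel <- metrics_panel(y_test, test_scores)
  bands <- ifelse(test_scores >= cfg$risk_threshold, "high", "low")

  report <- structure(list(
    config = unclass(cfg),
    n_train = length(train_idx), n_test = length(test_idx),
    cleaning_log = cleaned$log, cleaning_params = cleaned$params,
    best_hyperparameters = hpo$best_assignment,
    cv_fitness = hpo$best_fitness, hpo_evaluations = hpo$evaluations,
    convergence = hpo$trace, selected_features = features,
    train_metrics = train_panel, test_metrics = test_panel,
    test_risk = data.frame(row = test_idx, probability = test_scores,
                           band = bands, outcome = y_test)),
    class = "run_report")

  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' Write the artifacts of a run report
#'
#' JSON report plus CSVs for the metric panels, convergence trace and
#' per-subject risks.  Writing is deterministic: the same report produces
#' byte-identical files.
#'
#' @param report a [one_step()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  json <- list(config = report$config, n_train = report$n_train, n_test = report$n_test,
               best_hyperparameters = report$best_hyperparameters,
               cv_fitness = report$cv_fitness,
               selected_features = report$selected_features,
               train_metrics = as.list(report$train_metrics[1, 1:7]),
               test_metrics = as.list(report$test_metrics[1, 1:7]))
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(rbind(cbind(split = "train", report$train_metrics),
                         cbind(split = "test", report$test_metrics)),
                   file.path(out_dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(data.frame(iteration = seq_along(report$convergence),
                              best_fitness = report$convergence),
                   file.path(out_dir, "convergence.csv"), row.names = FALSE)
  utils::write.csv(report$test_risk, file.path(out_dir, "risk.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' Per-subject risk report from a logistic fit
#'
#' Scores each subject with [predict_risk()] and attaches a risk band:
#' `"high"` when the probability is at or above the threshold (a
#' probability exactly at the threshold is banded high), `"low"`
#' otherwise.
#'
#' @param fit a [fit_logistic()] result.
#' @param subjects data.frame of covariates.
#' @param threshold banding threshold (default 0.5).
#' @param path optional CSV output path.
#' @return data.frame with `probability` and `band` per subject.
#' @export
risk_report <- function(fit, subjects, threshold = 0.5, path = NULL) {
  p <- predict_risk(fit, subjects)
  out <- data.frame(subject = seq_along(p), probability = p,
                    band = ifelse(p >= threshold, "high", "low"))
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("one-step run: %s model, %d train / %d test subjects\n",
              x$config$model_kind, x$n_train, x$n_test))
  cat(sprintf("  CV fitness (%s): %.4f after %d evaluations\n",
              x$config$metric, x$cv_fitness, x$hpo_evaluations))
  cat(sprintf("  test ROC-AUC %.4f, ACC %.4f\n",
              x$test_metrics$ROC_AUC, x$test_metrics$ACC))
  invisible(x)
}
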