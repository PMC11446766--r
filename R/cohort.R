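# Synthetic two-group diabetic-retinopathy-like cohort.
#
# The generator reproduces the published two-group summary structure of
# the clinical cohort: per-group Gaussian continuous variables matched to
# the printed mean +/- SD, per-group Bernoulli categorical variables
# matched to the printed proportions, 150 subjects per group.  It stands
# in for the undeposited patient data so every downstream stage is
# testable; it is synthetic and carries no real patient information.

#' Default cohort profile
#'
#' The 19-variable profile of the case (retinopathy, group 1) and control
#' (group 0) arms: 15 continuous variables (group mean/SD) and 4 binary
#' variables (group proportion; gender is coded 1 = male, the treatment
#' flag 1 = receives non-pharmacological treatment, so its association
#' with the outcome is protective).  Continuous draws are truncated to a
#' clinically plausible range, which slightly biases extreme moments; see
#' the package vignette.  The glucose units are carried verbatim from the
#' source table ("umol/L"), which is plausibly a misprint for mmol/L.
#'
#' @param n_per_group subjects per outcome arm (default 150).
#' @param correlation optional positive-definite correlation matrix over
#'   the 15 continuous variables (default `NULL` = independent), or the
#'   string `"clinical"` for a preset with SBP-DBP 0.6, FBG-HbA1c 0.6 and
#'   TC-LDL 0.7 (an engineering choice for robustness testing, not an
#'   estimate).
#' @return object of class `cohort_profile`: list with `variables` (one
#'   row per variable: name, label, type, units, group1/group0 moments or
#'   proportions, plausible range), `n_per_group`, `correlation`.
#' @export
default_cohort_profile <- function(n_per_group = 150L, correlation = NULL) {
  cont <- function(name, label, units, m1, s1, m0, s0, lo, hi)
    data.frame(name = name, label = label, type = "continuous", units = units,
               mean1 = m1, sd1 = s1, mean0 = m0, sd0 = s0,
               p1 = NA_real_, p0 = NA_real_, lo = lo, hi = hi)
  bin <- function(name, label, p1, p0)
    data.frame(name = name, label = label, type = "binary", units = "",
               mean1 = NA_real_, sd1 = NA_real_, mean0 = NA_real_, sd0 = NA_real_,
               p1 = p1, p0 = p0, lo = 0, hi = 1)
  vars <- rbind(
    bin("gender", "Gender (male = 1)", 97 / 150, 64 / 150),
    cont("age", "Age", "years", 64.18, 8.43, 60.87, 9.04, 18, 100),
    cont("diabetes_duration", "Duration of diabetes", "years", 10.87, 6.01, 9.11, 5.19, 0, 50),
    bin("smoking", "Smoking history", 71 / 150, 52 / 150),
    bin("drinking", "Drinking history", 37 / 150, 33 / 150),
    bin("non_pharm_treatment", "Non-pharmacological treatment", 54 / 150, 91 / 150),
    cont("serum_creatinine", "Serum creatinine", "umol/L", 82.13, 33.19, 77.65, 41.06, 10, 1000),
    cont("sbp", "Systolic blood pressure", "mmHg", 140.18, 19.83, 135.23, 15.74, 60, 260),
    cont("dbp", "Diastolic blood pressure", "mmHg", 83.12, 9.13, 82.49, 9.58, 40, 160),
    cont("fbg", "Fasting blood glucose", "umol/L", 7.84, 2.15, 7.33, 1.76, 2, 30),
    cont("pbg_2h", "2-hour postprandial blood glucose", "umol/L", 12.45, 2.43, 11.88, 1.81, 2, 40),
    cont("bmi", "Body mass index", "kg/m2", 25.41, 3.41, 25.56, 3.61, 12, 60),
    cont("hba1c", "Glycosylated hemoglobin", "%", 7.43, 1.31, 6.11, 0.75, 3, 20),
    cont("hdl_c", "HDL cholesterol", "mmol/L", 1.31, 0.81, 1.91, 1.05, 0.1, 6),
    cont("ldl_c", "LDL cholesterol", "mmol/L", 3.71, 1.13, 3.43, 0.83, 0.3, 12),
    cont("total_cholesterol", "Total cholesterol", "mmol/L", 5.48, 1.31, 5.52, 1.04, 1, 15),
    cont("triglycerides", "Triglyceride", "mmol/L", 2.84, 1.03, 2.71, 0.99, 0.1, 15),
    cont("bun", "Blood urea nitrogen", "mmol/L", 5.45, 1.74, 5.01, 1.66, 0.5, 30),
    cont("uacr", "Urinary albumin/creatinine ratio", "mg/g", 21.24, 6.28, 6.32, 2.76, 0, 300))
  rownames(vars) <- NULL
  if (identical(correlation, "clinical")) {
    cn <- vars$name[vars$type == "continuous"]
    R <- diag(length(cn)); dimnames(R) <- list(cn, cn)
    set_r <- function(a, b, r) { R[a, b] <<- r; R[b, a] <<- r }
    set_r("sbp", "dbp", 0.6); set_r("fbg", "hba1c", 0.6)
    set_r("total_cholesterol", "ldl_c", 0.7)
    correlation <- R
  }
  if (!is.null(correlation)) {
    ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stopf("correlation matrix is not positive definite")
  }
  structure(list(variables = vars, n_per_group = as.integer(n_per_group),
                 correlation = correlation),
            class = "cohort_profile")
}

# truncated normal draws by resampling out-of-range values
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Generate a synthetic cohort
#'
#' Draws `n_per_group` subjects per arm: continuous variables from the
#' per-group (optionally correlated) Gaussians truncated to the plausible
#' range, binary variables from the per-group Bernoulli proportions.  With
#' a correlation matrix the continuous block is drawn multivariate normal
#' (Cholesky) and clamped to range; without one, draws are independent and
#' truncation is by resampling.  The outcome column is 1 for the
#' retinopathy arm.
#'
#' @param profile a [default_cohort_profile()].
#' @param seed integer seed; generation is deterministic given the seed.
#' @return data.frame with the 19 predictors plus `outcome`, carrying the
#'   variable table as attribute `"variables"` (class `cohort_table`).
#' @export
generate_cohort <- function(profile = default_cohort_profile(), seed = 1L) {
  stopifnot(inherits(profile, "cohort_profile"))
  v <- profile$variables
  n <- profile$n_per_group
  with_seed(seed, {
    groups <- lapply(c(1, 0), function(g) {
      cols <- vector("list", nrow(v)); names(cols) <- v$name
      cont_idx <- which(v$type == "continuous")
      if (!is.null(profile$correlation)) {
        L <- chol(profile$correlation)
        Z <- matrix(stats::rnorm(n * length(cont_idx)), n) %*% L
      }
      for (j in seq_len(nrow(v))) {
        r <- v[j, ]
        if (r$type == "continuous") {
          m <- if (g == 1) r$mean1 else r$mean0
          s <- if (g == 1) r$sd1 else r$sd0
          cols[[j]] <- if (is.null(profile$correlation))
            .rtruncnorm(n, m, s, r$lo, r$hi)
          else pmin(pmax(m + s * Z[, match(j, cont_idx)], r$lo), r$hi)
        } else {
          p <- if (g == 1) r$p1 else r$p0
          cols[[j]] <- stats::rbinom(n, 1L, p)
        }
      }
      df <- as.data.frame(cols)
      df$outcome <- g
      df
    })
    out <- rbind(groups[[1]], groups[[2]])
    rownames(out) <- NULL
    attr(out, "variables") <- v
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

#' Inject missingness into a cohort table
#'
#' Sets each predictor cell to `NA` independently with probability `rate`;
#' the outcome column is never masked.  Used to exercise the cleaning
#' stage.
#'
#' @param table a cohort data.frame with an `outcome` column.
#' @param rate missingness probability in \[0, 1).
#' @param seed integer seed.
#' @return the table with missing cells.
#' @export
inject_missing <- function(table, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stopf("rate must be in [0, 1)")
  if (rate == 0) return(table)
  pred <- setdiff(names(table), "outcome")
  with_seed(seed, {
    for (cl in pred) {
      mask <- stats::runif(nrow(table)) < rate
      table[[cl]][mask] <- NA
    }
  })
  table
}

#' Read / write a cohort profile as YAML
#'
#' @param profile a [default_cohort_profile()].
#' @param path file path.
#' @return `read_profile` returns a `cohort_profile`.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "cohort_profile"))
  yaml::write_yaml(list(n_per_group = profile$n_per_group,
                        variables = lapply(seq_len(nrow(profile$variables)), function(i)
                          as.list(profile$variables[i, ]))), path,
                   precision = 15L)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  y <- yaml::read_yaml(path)
  vars <- do.call(rbind, lapply(y$variables, function(v)
    as.data.frame(v, stringsAsFactors = FALSE)))
  base <- default_cohort_profile(n_per_group = y$n_per_group)
  base$variables <- vars[, names(base$variables)]
  base
}

#' Read / write cohort CSV
#'
#' Plain CSV with a header of the 19 predictor names plus `outcome`.
#'
#' @param table cohort data.frame.
#' @param path file path.
#' @return `read_cohort` returns the cohort data.frame.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path)
  if (!"outcome" %in% names(df)) stopf("cohort CSV must contain an 'outcome' column")
  v <- default_cohort_profile()$variables
  attr(df, "variables") <- v[v$name %in% names(df), , drop = FALSE]
  class(df) <- c("cohort_table", "data.frame")
  df
}
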