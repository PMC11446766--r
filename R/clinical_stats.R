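# Case-control risk-factor statistics: univariate screening with the
# pooled two-sample t-test (continuous) and Pearson chi-square (binary),
# multivariate logistic regression with Wald statistics and odds ratios,
# and risk prediction from a fitted model.

#' Pooled-variance two-sample t-test from group summaries
#'
#' `t = (mean1 - mean2) / sqrt(sp2 * (1/n1 + 1/n2))` with `sp2` the pooled
#' variance and `df = n1 + n2 - 2`; two-sided p.  With equal group sizes
#' this reduces to `(mean1 - mean2) / sqrt((sd1^2 + sd2^2) / n)`, the form
#' under which published group-summary tables are reproduced exactly.
#'
#' @param mean1,sd1,n1 summary of group 1.
#' @param mean2,sd2,n2 summary of group 2.
#' @param variable optional variable name carried into the result.
#' @param alpha significance level (default 0.05).
#' @return one-row data.frame: variable, test, statistic, df, p_value,
#'   significant.
#' @export
two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2,
                         variable = NA_character_, alpha = 0.05) {
  if (n1 < 2 || n2 < 2) stopf("both groups need n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stopf("standard deviations must be positive")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  tt <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(tt), df)
  data.frame(variable = variable, test = "t", statistic = tt, df = df,
             p_value = p, significant = p < alpha)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Cells `(a, b)` are group-1 yes/no counts and `(c, d)` group-0 yes/no
#' counts.  Pearson chi-square without continuity correction, df = 1
#' (delegates to [stats::chisq.test()]).
#'
#' @param a,b,c,d non-negative cell counts with positive margins.
#' @inheritParams two_sample_t
#' @return one-row data.frame as in [two_sample_t()].
#' @export
chi_square_2x2 <- function(a, b, c, d, variable = NA_character_, alpha = 0.05) {
  if (any(c(a, b, c, d) < 0)) stopf("counts must be non-negative")
  m <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) stopf("2x2 table has a zero margin")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  data.frame(variable = variable, test = "chisq",
             statistic = unname(ct$statistic), df = 1,
             p_value = unname(ct$p.value), significant = ct$p.value < alpha)
}

#' Univariate screen of a two-group cohort
#'
#' Applies [two_sample_t()] to every continuous predictor (on per-group
#' summaries) and [chi_square_2x2()] to every binary predictor, against
#' the binary `outcome` column.  A predictor constant across the whole
#' table yields statistic 0 with a `degenerate` flag rather than an
#' error.
#'
#' @param table cohort data.frame with `outcome`; predictors with more
#'   than two distinct values are treated as continuous.
#' @param alpha significance level.
#' @return data.frame with one row per predictor: variable, test,
#'   statistic, df, p_value, significant, degenerate.
#' @export
univariate_screen <- function(table, alpha = 0.05) {
  y <- table$outcome
  if (is.null(y) || length(unique(y)) != 2) stopf("table needs a binary 'outcome' column")
  pred <- setdiff(names(table), "outcome")
  res <- lapply(pred, function(nm) {
    x <- table[[nm]]
    binary <- length(unique(stats::na.omit(x))) <= 2
    degenerate <- length(unique(stats::na.omit(x))) < 2
    if (degenerate) {
      warning(sprintf("predictor '%s' is constant; statistic set to 0", nm))
      return(data.frame(variable = nm, test = if (binary) "chisq" else "t",
                        statistic = 0, df = if (binary) 1 else length(x) - 2,
                        p_value = 1, significant = FALSE, degenerate = TRUE))
    }
    out <- if (binary) {
      chi_square_2x2(sum(x == 1 & y == 1, na.rm = TRUE), sum(x == 0 & y == 1, na.rm = TRUE),
                     sum(x == 1 & y == 0, na.rm = TRUE), sum(x == 0 & y == 0, na.rm = TRUE),
                     variable = nm, alpha = alpha)
    } else {
      x1 <- x[y == 1]; x0 <- x[y == 0]
      two_sample_t(mean(x1, na.rm = TRUE), stats::sd(x1, na.rm = TRUE), sum(!is.na(x1)),
                   mean(x0, na.rm = TRUE), stats::sd(x0, na.rm = TRUE), sum(!is.na(x0)),
                   variable = nm, alpha = alpha)
    }
    out$degenerate <- FALSE
    out
  })
  do.call(rbind, res)
}

#' Multivariate logistic regression fit
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm()]) with
#' intercept; standard errors from the inverse observed information.
#' Wald statistics `(beta/SE)^2` with chi-square(1) p-values, odds ratios
#' and both confidence-interval conventions are attached per coefficient.
#' Perfect separation and rank deficiency are reported as errors naming
#' the offending predictor rather than returned silently.
#'
#' @param X numeric predictor matrix or data.frame (no intercept column).
#' @param y binary outcome (0/1).
#' @param max_iter,tol IRLS iteration cap and convergence tolerance.
#' @return object of class `logistic_fit`: `coefficients` data.frame
#'   (term, beta, se, wald, p_value, or, ci_lo, ci_hi), `converged`,
#'   `iterations`, `log_likelihood`, `terms`, and the underlying `glm`.
#' @export
fit_logistic <- function(X, y, max_iter = 100L, tol = 1e-10) {
  X <- as.data.frame(X)
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stopf("y must be binary 0/1")
  mm <- cbind(`(Intercept)` = 1, as.matrix(X))
  q <- qr(mm)
  if (q$rank < ncol(mm)) {
    dropped <- colnames(mm)[q$pivot[(q$rank + 1):ncol(mm)]]
    stopf("rank-deficient design: collinear column(s) %s", paste(dropped, collapse = ", "))
  }
  dat <- cbind(X, .outcome = y)
  fit <- withCallingHandlers(
    stats::glm(.outcome ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(maxit = max_iter, epsilon = tol)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  cf <- summary(fit)$coefficients
  # perfect separation drives the residual deviance to zero (every fitted
  # probability exactly right at the boundary); a strong but finite fit
  # keeps positive deviance even with many boundary probabilities
  boundary <- any(fit$fitted.values > 1 - 1e-8 | fit$fitted.values < 1e-8)
  if (boundary && (fit$deviance < 1e-6 || !fit$converged)) {
    sds <- vapply(X, stats::sd, numeric(1))
    std_mag <- abs(cf[-1, "Estimate"]) * sds[rownames(cf)[-1]]
    worst <- names(std_mag)[which.max(std_mag)]
    stopf("perfect separation detected; offending predictor: %s", worst)
  }
  beta <- cf[, "Estimate"]; se <- cf[, "Std. Error"]
  wres <- wald(beta, se)
  coefs <- data.frame(term = rownames(cf), beta = unname(beta), se = unname(se),
                      wald = wres$statistic, p_value = wres$p_value,
                      or = exp(unname(beta)),
                      ci_lo = exp(unname(beta) - 1.96 * unname(se)),
                      ci_hi = exp(unname(beta) + 1.96 * unname(se)),
                      row.names = NULL)
  structure(list(coefficients = coefs, converged = fit$converged,
                 iterations = fit$iter, log_likelihood = as.numeric(stats::logLik(fit)),
                 terms = colnames(X), glm = fit),
            class = "logistic_fit")
}

#' Wald statistic
#'
#' `(beta / SE)^2`, referred to chi-square with 1 df.
#'
#' @param beta coefficient estimate(s).
#' @param se standard error(s), > 0.
#' @return list with `statistic` and `p_value` (vectorized).
#' @export
wald <- function(beta, se) {
  if (any(se <= 0)) stopf("SE must be positive")
  stat <- (beta / se)^2
  list(statistic = unname(stat), p_value = unname(stats::pchisq(stat, df = 1, lower.tail = FALSE)))
}

#' Odds ratio with 95% confidence interval
#'
#' `OR = exp(beta)`.  The `"standard"` convention puts the interval on the
#' exponential scale, `exp(beta +/- 1.96 SE)`.  The `"paper_compat"`
#' convention reproduces tables that print `OR +/- 1.96 SE(beta)` (an
#' additive interval around the OR); it exists for reproduction of such
#' tables and is not recommended.
#'
#' @inheritParams wald
#' @param convention `"standard"` (default) or `"paper_compat"`.
#' @return data.frame with `or`, `ci_lo`, `ci_hi` (vectorized).
#' @export
odds_ratio <- function(beta, se, convention = c("standard", "paper_compat")) {
  convention <- match.arg(convention)
  if (any(se <= 0)) stopf("SE must be positive")
  or <- exp(beta)
  if (convention == "standard")
    data.frame(or = or, ci_lo = exp(beta - 1.96 * se), ci_hi = exp(beta + 1.96 * se))
  else
    data.frame(or = or, ci_lo = or - 1.96 * se, ci_hi = or + 1.96 * se)
}

#' Predicted risk from a logistic fit
#'
#' Inverse-logit of the linear predictor for each subject.
#'
#' @param fit a [fit_logistic()] result.
#' @param covariates data.frame supplying every fitted predictor.
#' @return probabilities in (0, 1).
#' @export
predict_risk <- function(fit, covariates) {
  stopifnot(inherits(fit, "logistic_fit"))
  missing_cols <- setdiff(fit$terms, names(covariates))
  if (length(missing_cols))
    stopf("covariates are missing fitted predictor(s): %s", paste(missing_cols, collapse = ", "))
  as.numeric(stats::predict(fit$glm, newdata = as.data.frame(covariates), type = "response"))
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic fit: %d terms, %s after %d IRLS iterations, logLik %.3f\n",
              nrow(x$coefficients) - 1,
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$log_likelihood))
  print(x$coefficients, digits = 4)
  invisible(x)
}
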