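test_that("two_sample_t handles the null case and rejects bad input", {
  r <- two_sample_t(5, 1, 20, 5, 1, 20)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_false(r$significant)
  expect_error(two_sample_t(1, 1, 1, 2, 1, 20), "n >= 2")
  expect_error(two_sample_t(1, 0, 10, 2, 1, 10), "positive")
})

test_that("chi_square_2x2 is Pearson without continuity correction", {
  expect_equal(chi_square_2x2(50, 50, 50, 50)$statistic, 0)
  # cross-check the closed form n(ad-bc)^2 / product of margins
  a <- 30; b <- 10; c <- 15; d <- 25
  n <- a + b + c + d
  expect_equal(chi_square_2x2(a, b, c, d)$statistic,
               n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d)))
  expect_error(chi_square_2x2(0, 0, 5, 5), "zero margin")
})

test_that("univariate_screen covers all predictors and tolerates constants", {
  co <- generate_cohort(seed = 4)
  co$flat <- 1
  expect_warning(scr <- univariate_screen(co), "constant")
  expect_equal(nrow(scr), 20)
  fl <- scr[scr$variable == "flat", ]
  expect_equal(fl$statistic, 0)
  expect_true(fl$degenerate)
  expect_false(fl$significant)
})

test_that("logistic MLE matches the closed-form 2x2 estimator", {
  X <- data.frame(exposed = c(rep(1, 10), rep(0, 10)))
  y <- c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8))
  f <- fit_logistic(X, y)
  beta <- f$coefficients$beta[f$coefficients$term == "exposed"]
  expect_equal(beta, log(8 * 8 / (2 * 2)), tolerance = 1e-6)
  expect_true(f$converged)
  # label symmetry: swapping y negates every coefficient
  f2 <- fit_logistic(X, 1 - y)
  expect_equal(f2$coefficients$beta, -f$coefficients$beta, tolerance = 1e-8)
})

test_that("logistic fit errors on separation and collinearity, naming the culprit", {
  X <- data.frame(a = c(1, 2, 3, 4, 5, 6), b = c(2, 4, 6, 8, 10, 12))
  expect_error(fit_logistic(X, c(0, 1, 0, 1, 0, 1)), "collinear.*b")
  Xs <- data.frame(sep = c(-2, -1.5, -1, 1, 1.5, 2), ok = rnorm(6))
  expect_error(fit_logistic(Xs, c(0, 0, 0, 1, 1, 1)), "separation")
})

test_that("a planted null yields small coefficients and calibrated Wald p-values", {
  ibasml:::with_seed(23, {
    n <- 5000
    X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
    y <- rbinom(n, 1, 0.5)
    f <- fit_logistic(X, y)
    b <- f$coefficients[f$coefficients$term != "(Intercept)", ]
    expect_true(all(abs(b$beta) < 0.1))
    # Wald p of null predictors is approximately uniform
    ps <- replicate(40, {
      yy <- rbinom(n, 1, 0.5)
      fit_logistic(X["x1"], yy)$coefficients$p_value[2]
    })
    expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  })
})

test_that("wald and odds_ratio follow their definitions", {
  expect_equal(wald(0, 1)$statistic, 0)
  expect_equal(wald(2, 1)$p_value, stats::pchisq(4, 1, lower.tail = FALSE))
  expect_error(wald(1, 0), "positive")
  expect_equal(odds_ratio(0, 1)$or, 1)
  st <- odds_ratio(0.5, 0.1)
  expect_equal(c(st$ci_lo, st$ci_hi), exp(0.5 + c(-1, 1) * 1.96 * 0.1))
  pc <- odds_ratio(0.5, 0.1, "paper_compat")
  expect_equal(c(pc$ci_lo, pc$ci_hi), exp(0.5) + c(-1, 1) * 1.96 * 0.1)
})

test_that("predict_risk is the inverse link and is monotone in positive coefficients", {
  ibasml:::with_seed(6, {
    X <- data.frame(x = rnorm(80))
    y <- rbinom(80, 1, stats::plogis(-0.5 + 1.2 * X$x))
    f <- fit_logistic(X, y)
    b0 <- f$coefficients$beta[1]; b1 <- f$coefficients$beta[2]
    expect_equal(predict_risk(f, data.frame(x = 0)), stats::plogis(b0), tolerance = 1e-9)
    expect_equal(predict_risk(f, data.frame(x = 1)), stats::plogis(b0 + b1), tolerance = 1e-9)
    if (b1 > 0) {
      p <- predict_risk(f, data.frame(x = c(0, 1, 2)))
      expect_true(all(diff(p) > 0))
    }
    expect_error(predict_risk(f, data.frame(z = 1)), "missing.*x")
  })
})
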