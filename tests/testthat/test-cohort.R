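test_that("the default profile transcribes the two-group summary structure", {
  pr <- default_cohort_profile()
  v <- pr$variables
  expect_equal(nrow(v), 19)
  expect_equal(pr$n_per_group, 150L)
  age <- v[v$name == "age", ]
  expect_equal(c(age$mean1, age$sd1, age$mean0, age$sd0), c(64.18, 8.43, 60.87, 9.04))
  g <- v[v$name == "gender", ]
  expect_equal(c(g$p1, g$p0), c(97 / 150, 64 / 150))
  expect_equal(sum(v$type == "continuous"), 15)
  expect_equal(sum(v$type == "binary"), 4)
  expect_true(all(v$sd1[v$type == "continuous"] > 0))
  expect_true(all(v$lo < v$hi))
})

test_that("generation is deterministic, balanced, and respects plausible ranges", {
  co <- generate_cohort(seed = 31)
  expect_equal(dim(co), c(300L, 20L))
  expect_equal(as.vector(table(co$outcome)), c(150L, 150L))
  expect_identical(co, generate_cohort(seed = 31))
  expect_false(identical(co, generate_cohort(seed = 32)))
  v <- attr(co, "variables")
  for (j in seq_len(nrow(v)))
    expect_true(all(co[[v$name[j]]] >= v$lo[j] & co[[v$name[j]]] <= v$hi[j]),
                info = v$name[j])
  expect_false(anyNA(co))
})

test_that("large-cohort moments match the truncated-normal oracle within CLT bounds", {
  pr <- default_cohort_profile(n_per_group = 5000L)
  co <- generate_cohort(pr, seed = 77)
  v <- pr$variables
  # analytic mean of a normal truncated to [lo, hi] (the documented
  # truncation bias makes this, not the raw profile mean, the oracle)
  trunc_mean <- function(m, s, lo, hi) {
    a <- (lo - m) / s; b <- (hi - m) / s
    m + s * (stats::dnorm(a) - stats::dnorm(b)) / (stats::pnorm(b) - stats::pnorm(a))
  }
  for (g in c(1, 0)) {
    sub <- co[co$outcome == g, ]
    for (j in which(v$type == "continuous")) {
      m0 <- if (g == 1) v$mean1[j] else v$mean0[j]
      s0 <- if (g == 1) v$sd1[j] else v$sd0[j]
      m_target <- trunc_mean(m0, s0, v$lo[j], v$hi[j])
      expect_lt(abs(mean(sub[[v$name[j]]]) - m_target), 3 * s0 / sqrt(5000),
                label = sprintf("mean of %s in group %d", v$name[j], g))
    }
  }
  # independence by default: off-diagonal correlations stay small
  cont <- v$name[v$type == "continuous"]
  R <- cor(co[co$outcome == 1, cont])
  expect_lt(max(abs(R[upper.tri(R)])), 0.08)
})

test_that("the clinical correlation preset induces the requested structure", {
  pr <- default_cohort_profile(n_per_group = 3000L, correlation = "clinical")
  co <- generate_cohort(pr, seed = 5)
  sub <- co[co$outcome == 0, ]
  expect_equal(cor(sub$sbp, sub$dbp), 0.6, tolerance = 0.1)
  expect_equal(cor(sub$total_cholesterol, sub$ldl_c), 0.7, tolerance = 0.1)
  bad <- diag(15); bad[1, 2] <- bad[2, 1] <- 1.2
  expect_error(default_cohort_profile(correlation = bad), "positive definite")
})

test_that("missingness injection hits the expected rate and never masks the outcome", {
  co <- generate_cohort(seed = 2)
  expect_identical(inject_missing(co, 0), co)
  m <- inject_missing(co, 0.1, seed = 13)
  n_cells <- 300 * 19
  n_miss <- sum(is.na(m[, setdiff(names(m), "outcome")]))
  expect_lt(abs(n_miss - 0.1 * n_cells), 3 * sqrt(n_cells * 0.1 * 0.9))
  expect_false(anyNA(m$outcome))
})

test_that("cohort CSV and profile YAML round-trip", {
  co <- generate_cohort(seed = 3)
  tmp <- tempfile(fileext = ".csv")
  write_cohort(co, tmp)
  back <- read_cohort(tmp)
  expect_equal(as.data.frame(back), as.data.frame(co), tolerance = 1e-12)
  pr <- default_cohort_profile(n_per_group = 42L)
  ty <- tempfile(fileext = ".yaml")
  write_profile(pr, ty)
  pr2 <- read_profile(ty)
  expect_equal(pr2$n_per_group, 42L)
  expect_equal(pr2$variables, pr$variables, tolerance = 1e-9)
})

test_that("the univariate screen on a generated cohort flags the strong effects only", {
  co <- generate_cohort(seed = 19)
  scr <- univariate_screen(co)
  expect_equal(nrow(scr), 19)
  flag <- function(nm) scr$significant[scr$variable == nm]
  expect_true(flag("hba1c"))
  expect_true(flag("uacr"))
  expect_false(flag("drinking"))
  expect_false(flag("bmi"))
})
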