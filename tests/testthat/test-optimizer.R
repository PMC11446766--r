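sphere <- function(X) rowSums(X^2)

test_that("chaotic sample follows the piecewise map, stays in [0,1), and is seeded", {
  P <- 0.4
  M <- piecewise_chaotic_sample(50, 3, P = P, seed = 9)
  expect_true(all(M >= 0 & M < 1))
  # every consecutive pair in every orbit satisfies the 4-branch map
  map <- function(x) {
    if (x < P) x / P
    else if (x < 0.5) (x - P) / (0.5 - P)
    else if (x < 1 - P) (1 - P - x) / (0.5 - P)
    else (1 - x) / P
  }
  for (j in 1:3)
    for (k in 2:50)
      expect_equal(M[k, j], map(M[k - 1, j]), tolerance = 1e-9)
  expect_identical(M, piecewise_chaotic_sample(50, 3, P = P, seed = 9))
  expect_error(piecewise_chaotic_sample(10, 2, P = 0.6), "P must be")
})

test_that("a 30x30 chaotic sample spreads over most of the unit interval", {
  M <- piecewise_chaotic_sample(30, 30, seed = 1)
  spans <- apply(M, 2, function(x) diff(range(x)))
  # thresholds frozen from long-orbit reference runs of the same map
  expect_true(all(spans >= 0.6))
  expect_gte(mean(spans >= 0.8), 0.8)
})

test_that("scale_to_bounds is the affine map onto the space", {
  sp <- search_space(c(-5, 0), c(5, 100))
  expect_equal(drop(scale_to_bounds(matrix(c(0, 0.5), 1), sp)), c(-5, 50))
  U <- piecewise_chaotic_sample(20, 2, seed = 2)
  X <- scale_to_bounds(U, sp)
  expect_true(all(X[, 1] >= -5 & X[, 1] < 5) && all(X[, 2] >= 0 & X[, 2] < 100))
  expect_error(scale_to_bounds(matrix(0.5, 2, 3), sp), "dimensions")
})

test_that("bas_step is greedy and moves downhill on a monotone slope", {
  sp1 <- search_space(-10, 10, 1)
  ibasml:::with_seed(4, {
    for (i in 1:20) {
      r <- bas_step(1, fx = 1, objective = sphere, space = sp1, d = 1e-3, delta = 0.1)
      expect_lte(r$fx, 1)
      expect_lt(r$x, 1)  # sign of the slope sends the move toward 0
    }
  })
  # greedy retention on a rugged objective in 2-D
  sp2 <- search_space(-5.12, 5.12, 2)
  rast <- function(X) rowSums(X^2 - 10 * cos(2 * pi * X) + 10)
  ibasml:::with_seed(8, {
    x <- c(2, 2); fx <- rast(matrix(x, 1))
    for (i in 1:50) {
      r <- bas_step(x, fx, rast, sp2, d = 0.5, delta = 0.5)
      expect_lte(r$fx, fx)
      x <- r$x; fx <- r$fx
    }
  })
})

test_that("t_mutation keeps the zero vector fixed, never degrades fitness, and widens early", {
  sp <- search_space(-10, 10, 3)
  ibasml:::with_seed(3, {
    r <- t_mutation(c(0, 0, 0), fx = 0, objective = sphere, space = sp,
                    iteration = 1, p_m = 1)
    expect_equal(r$x, c(0, 0, 0))  # multiplicative perturbation of zero
    x <- c(1, -2, 3); fx <- sphere(matrix(x, 1))
    for (i in 1:30) {
      r <- t_mutation(x, fx, sphere, sp, iteration = i, p_m = 0.5)
      expect_lte(r$fx, fx)
      x <- r$x; fx <- r$fx
    }
  })
  # df = iteration: proposals at iteration 1 are much heavier-tailed than late
  probe <- function(iter) ibasml:::with_seed(12, {
    seen <- c()
    rec <- function(X) { seen <<- c(seen, abs(X[, 1])); rowSums(X^2) + 1e6 }  # reject all
    for (i in 1:200) t_mutation(1, 1e6, rec, search_space(-1e6, 1e6, 1),
                                iteration = iter, p_m = 1)
    seen
  })
  expect_gt(mean(probe(1) > 7), mean(probe(200) > 7))
})

test_that("random_walk improves, bounds its halvings, and refines a convex basin", {
  sp <- search_space(-100, 100, 2)
  bound <- ceiling(log2(0.5 / 1e-3))
  ok <- 0
  for (s in 1:30) {
    r <- ibasml:::with_seed(s, random_walk(c(1, 1), fx = 2, objective = sphere,
                                           space = sp, step_init = 0.5,
                                           step_threshold = 1e-3, N = 10))
    expect_lte(r$fx, 2)
    expect_lte(r$halvings, bound + 1)
    if (r$fx < 2) ok <- ok + 1
  }
  expect_equal(ok, 30)  # a convex basin always yields an accepted move
  expect_error(random_walk(c(0, 0), 0, sphere, sp, step_init = 1, step_threshold = 2),
               "step_init")
})

test_that("run_optimizer keeps candidates in bounds, traces monotonically, and is seed-deterministic", {
  sp <- search_space(-5, 5, 3)
  guard <- function(X) {
    if (any(X < -5 - 1e-12) || any(X > 5 + 1e-12)) stop("out of bounds")
    rowSums(X^2)
  }
  for (variant in c("BAS", "IBAS")) {
    cfg <- optimizer_config(population_size = 8, iterations = 25, seed = 6,
                            walk_max_evals = 200)
    r <- run_optimizer(guard, sp, cfg, variant)
    expect_true(all(diff(r$trace) <= 0))
    expect_equal(r$best$fitness, min(r$trace))
    expect_true(all(r$best$position >= -5 & r$best$position <= 5))
    r2 <- run_optimizer(guard, sp, cfg, variant)
    expect_identical(r$trace, r2$trace)
    expect_identical(r$best, r2$best)
  }
})

test_that("evaluation accounting matches the analytic BAS budget and the empirical count", {
  sp <- search_space(-5, 5, 2)
  env <- new.env(); env$n <- 0L
  counter <- function(X) { env$n <- env$n + nrow(X); rowSums(X^2) }
  cfg <- optimizer_config(population_size = 7, iterations = 13, seed = 2)
  r <- run_optimizer(counter, sp, cfg, "BAS")
  expect_equal(r$evaluations_used, 7 + 3 * 7 * 13)  # init + 3 probes/member/iter
  expect_equal(r$evaluations_used, env$n)
  env$n <- 0L
  ri <- run_optimizer(counter, sp, cfg, "IBAS")
  expect_equal(ri$evaluations_used, env$n)
})

test_that("non-finite objective values raise an error naming the position", {
  sp <- search_space(-1, 1, 2)
  bad <- function(X) ifelse(X[, 1] > 0.99, NaN, rowSums(X^2))
  expect_error(run_optimizer(bad, sp, optimizer_config(population_size = 10,
                                                       iterations = 5, seed = 1)),
               "non-finite")
})

test_that("a single-repeat campaign mean curve equals the run trace", {
  f <- benchmark_suite(2)[[1]]
  cfg <- optimizer_config(population_size = 5, iterations = 10,
                          walk_max_evals = 100)
  camp <- benchmark_campaign(list(f), cfg, repeats = 1, seed_base = 10)
  cfg1 <- cfg; cfg1$seed <- 11L; cfg1$plateau_patience <- NULL
  direct <- run_optimizer(f$fun, search_space(f$lower, f$upper, f$dim), cfg1, "IBAS")
  ib <- camp$curves[camp$curves$variant == "IBAS", ]
  expect_equal(ib$mean_best, direct$trace)
  expect_equal(nrow(camp$summary), 2)
})
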