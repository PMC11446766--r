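test_that("search spaces carry the published ranges and steps", {
  xgb <- hpo_space("xgb")
  expect_equal(length(xgb$specs), 3)
  expect_equal(sapply(xgb$specs, `[[`, "low"), c(0.01, 1, 1))
  expect_equal(sapply(xgb$specs, `[[`, "high"), c(1, 20, 100))
  expect_equal(sapply(xgb$specs, `[[`, "step"), c(0.1, 0.5, 10))
  lr <- hpo_space("lr")
  expect_equal(lr$specs[[1]]$low, 0.01)
  expect_equal(lr$specs[[1]]$high, 100)
  expect_equal(lr$specs[[2]]$levels, c("l1", "l2"))
  svm <- hpo_space("svm")
  expect_equal(length(svm$specs), 2)
  for (s in svm$specs) expect_equal(c(s$low, s$high), c(0.01, 100))
  expect_error(hpo_space("forest"))
})

test_that("decode maps the unit cube into valid assignments", {
  lr <- hpo_space("lr")
  expect_equal(decode_position(c(0.1, 0.3), lr)$penalty, "l1")
  expect_equal(decode_position(c(0.1, 0.7), lr)$penalty, "l2")
  xgb <- hpo_space("xgb")
  a <- decode_position(c(0, 0.35, 1), xgb)
  expect_equal(a$learning_rate, 0.01)
  expect_equal(a$max_depth, 8)      # 1 + 0.35*19 = 7.65, rounded half-up
  expect_equal(a$nrounds, 100)
  z <- decode_position(c(0, 0, 0), xgb)
  expect_equal(unlist(z), c(learning_rate = 0.01, max_depth = 1, nrounds = 1))
  expect_error(decode_position(0.5, xgb), "entries")
  # decode is identity on grid points, up to the integer rounding class
  gv <- ibasml:::.grid_values(xgb$specs[[3]])
  expect_equal(gv, c(seq(1, 91, 10), 100))
  for (v in gv) {
    u <- (v - 1) / 99
    expect_equal(decode_position(c(0.5, 0.5, u), xgb)$nrounds, v)
  }
})

test_that("grid enumeration includes both endpoints and dedups integer grids", {
  lr <- hpo_space("lr")
  g <- ibasml:::.grid_values(lr$specs[[1]])
  expect_equal(g, c(0.01 + 10 * (0:9), 100))
  expect_equal(length(g), 11)
  depth <- ibasml:::.grid_values(hpo_space("xgb")$specs[[2]])
  expect_equal(depth, 1:20)  # step 0.5 grid rounded to integers, dedup'd
})

test_that("cv_fitness separates the separable, nulls the permuted, and is deterministic", {
  d <- separable_data(n = 120, gap = 5)
  a <- list(reg_c = 1, penalty = "l2")
  f <- cv_fitness(a, d$X, d$y, "lr", k = 5, seed = 2)
  expect_gte(f, 0.99)
  expect_identical(f, cv_fitness(a, d$X, d$y, "lr", k = 5, seed = 2))
  # permutation null: mean AUC near one half
  ibasml:::with_seed(14, {
    co <- generate_cohort(seed = 1)
    X <- as.matrix(co[, setdiff(names(co), "outcome")])
    perm <- replicate(50, cv_fitness(a, X, sample(co$outcome), "lr", k = 5, seed = 3))
    expect_lt(abs(mean(perm) - 0.5), 0.1)
  })
})

test_that("cv_fitness rejects folds that lose a class", {
  d <- separable_data(n = 20)
  y <- c(rep(0L, 18), 1L, 1L)
  expect_error(cv_fitness(list(reg_c = 1, penalty = "l2"), d$X, y, "lr", k = 5),
               "fewer than k|missing a class")
})

test_that("grid_search enumerates the full Cartesian grid and returns the argmax", {
  d <- separable_data(n = 60)
  g <- grid_search(hpo_space("lr"), d$X, d$y, k = 3, seed = 7)
  expect_equal(g$evaluations, 11 * 2)
  expect_equal(nrow(g$history), 22)
  expect_equal(g$best_fitness, max(g$history$fitness))
  first_best <- which(g$history$fitness == g$best_fitness)[1]
  expect_equal(g$best_assignment$reg_c, g$history$reg_c[first_best])
  expect_true(all(g$history$reg_c >= 0.01 & g$history$reg_c <= 100))
})

test_that("evolved fitness values are valid, reproducible, and at least grid-competitive on an easy space", {
  d <- separable_data(n = 80, gap = 2.5)
  cfg <- optimizer_config(population_size = 6, iterations = 8, seed = 5,
                          walk_mode = "final", walk_step_init = 0.25,
                          walk_step_threshold = 0.05, walk_max_evals = 20L)
  e <- evolve_hyperparameters(hpo_space("lr"), d$X, d$y, cfg = cfg, k = 3)
  expect_true(all(e$history$fitness >= 0 & e$history$fitness <= 1))
  expect_equal(e$best_fitness, max(e$history$fitness))
  # the reported best is reproducible by re-running cv_fitness
  expect_equal(cv_fitness(e$best_assignment, d$X, d$y, "lr", k = 3, seed = cfg$seed),
               e$best_fitness, tolerance = 1e-12)
})

test_that("the feature-mask extension reports selected features", {
  d <- separable_data(n = 80, gap = 4)
  colnames(d$X) <- paste0("f", 1:4)
  cfg <- optimizer_config(population_size = 6, iterations = 6, seed = 9,
                          walk_mode = "none")
  e <- evolve_hyperparameters(hpo_space("lr"), d$X, d$y, cfg = cfg, k = 3,
                              feature_mask = TRUE)
  expect_true(length(e$selected_features) >= 1)
  expect_true(all(e$selected_features %in% colnames(d$X)))
})
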