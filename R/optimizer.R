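# Beetle Antennae Search (BAS) and the Improved BAS (IBAS).
#
# BAS probes the objective at two antenna points on either side of the
# current position and steps away from the worse side.  IBAS adds three
# components: a piecewise chaotic map spreads the initial population over
# the search space, an iteration-adaptive Student-t mutation perturbs
# members (heavy-tailed global moves early, near-Gaussian local moves
# late), and a step-halving random walk refines the iteration best.
#
# Objectives are minimized and must be vectorized over the rows of a
# matrix; wrap a scalar function with vectorize_objective().  All
# operators clip proposals to the bounds (never reflect) and are greedy:
# a retained candidate is never worse than its input.  Ties keep the
# incumbent.

#' Box-constrained search space
#'
#' @param lower,upper numeric vectors of finite per-dimension bounds with
#'   `lower < upper` elementwise (scalars are recycled to `dims`).
#' @param dims number of dimensions; defaults to `length(lower)`.
#' @return object of class `search_space`.
#' @export
search_space <- function(lower, upper, dims = length(lower)) {
  lower <- rep_len(as.numeric(lower), dims)
  upper <- rep_len(as.numeric(upper), dims)
  if (any(!is.finite(lower)) || any(!is.finite(upper))) stopf("bounds must be finite")
  if (any(lower >= upper)) stopf("lower must be < upper in every dimension")
  structure(list(dims = dims, lower = lower, upper = upper), class = "search_space")
}

.clip <- function(X, space) {
  X <- pmax(X, matrix(space$lower, nrow(X), space$dims, byrow = TRUE))
  pmin(X, matrix(space$upper, nrow(X), space$dims, byrow = TRUE))
}

#' Wrap a scalar objective for row-wise matrix evaluation
#'
#' @param f function taking one numeric vector and returning one number.
#' @return function taking a matrix and returning a numeric vector.
#' @export
vectorize_objective <- function(f) {
  function(X) vapply(seq_len(nrow(X)), function(i) f(X[i, ]), numeric(1))
}

#' Optimizer configuration
#'
#' Defaults follow the standardized experimental setup used for the
#' benchmark comparison (population 30, 200 iterations) and the standard
#' BAS schedule.  `d0` (initial antenna length) and `delta0` (initial step
#' size) default to 10% of the mean bound width of the space being
#' optimized, as does the random-walk geometry; they may be fixed
#' explicitly.
#'
#' @param population_size beetles run in parallel (independent; they share
#'   only the global-best tracker).
#' @param iterations iteration budget.
#' @param seed integer seed; runs are bit-reproducible given the seed.
#' @param d0,delta0 initial antenna length / step size (`NULL` = 10% of
#'   mean bound width).
#' @param eta geometric decay per iteration applied as
#'   `d <- eta * d + 0.01`, `delta <- eta * delta`.
#' @param p_m per-candidate probability of the t-distribution mutation.
#' @param walk_N consecutive failures before the walk step halves.
#' @param walk_step_init,walk_step_threshold initial / terminal walk
#'   radius (`NULL` = 10% / 1e-6 of mean bound width).
#' @param walk_max_evals hard cap on objective calls per walk invocation.
#' @param walk_mode `"per_iteration"` applies the walk to every
#'   iteration's best (the default variant); `"final"` only once at
#'   termination; `"none"` disables it.
#' @param chaotic_P piecewise chaotic map parameter in (0, 0.5).
#' @param plateau_tol,plateau_patience early stop when the best fitness
#'   improves by less than `plateau_tol` for `plateau_patience`
#'   consecutive iterations (`NULL` patience = run the full budget).
#' @return object of class `optimizer_config`.
#' @export
optimizer_config <- function(population_size = 30L, iterations = 200L, seed = 1L,
                             d0 = NULL, delta0 = NULL, eta = 0.95, p_m = 0.5,
                             walk_N = 10L, walk_step_init = NULL,
                             walk_step_threshold = NULL, walk_max_evals = 1000L,
                             walk_mode = c("per_iteration", "final", "none"),
                             chaotic_P = 0.4,
                             plateau_tol = 1e-4, plateau_patience = NULL) {
  walk_mode <- match.arg(walk_mode)
  if (population_size < 1L) stopf("population_size must be >= 1")
  if (iterations < 1L) stopf("iterations must be >= 1")
  if (eta <= 0 || eta >= 1) stopf("eta must be in (0,1)")
  if (p_m < 0 || p_m > 1) stopf("p_m must be in [0,1]")
  if (chaotic_P <= 0 || chaotic_P >= 0.5) stopf("chaotic_P must be in (0, 0.5)")
  if (!is.null(walk_step_init) && !is.null(walk_step_threshold) &&
      walk_step_threshold >= walk_step_init)
    stopf("walk_step_threshold must be < walk_step_init")
  structure(list(population_size = as.integer(population_size),
                 iterations = as.integer(iterations), seed = as.integer(seed),
                 d0 = d0, delta0 = delta0, eta = eta, p_m = p_m,
                 walk_N = as.integer(walk_N), walk_step_init = walk_step_init,
                 walk_step_threshold = walk_step_threshold,
                 walk_max_evals = as.integer(walk_max_evals),
                 walk_mode = walk_mode, chaotic_P = chaotic_P,
                 plateau_tol = plateau_tol, plateau_patience = plateau_patience),
            class = "optimizer_config")
}

#' Piecewise chaotic map sample on the unit interval
#'
#' Each column is an orbit of the piecewise-linear chaotic map
#' \deqn{x_{k+1} = x_k/P,\ x_k \in [0,P);\quad (x_k-P)/(0.5-P),\ [P,0.5);}
#' \deqn{(1-P-x_k)/(0.5-P),\ [0.5,1-P);\quad (1-x_k)/P,\ [1-P,1)}
#' started from a seeded uniform initial state per column.  States landing
#' on the degenerate fixed set \{0, P, 0.5, 1-P\} are nudged by 1e-12.
#'
#' @param n orbit length (rows).
#' @param dims number of independent orbits (columns).
#' @param P map parameter in (0, 0.5), default 0.4.
#' @param seed integer seed.
#' @return `n` x `dims` matrix with entries in \[0, 1).
#' @export
piecewise_chaotic_sample <- function(n, dims, P = 0.4, seed = 1L) {
  if (P <= 0 || P >= 0.5) stopf("P must be in (0, 0.5)")
  if (n < 1 || dims < 1) stopf("n and dims must be >= 1")
  step <- function(x) {
    ifelse(x < P, x / P,
           ifelse(x < 0.5, (x - P) / (0.5 - P),
                  ifelse(x < 1 - P, (1 - P - x) / (0.5 - P), (1 - x) / P)))
  }
  nudge <- function(x) {
    bad <- x %in% c(0, P, 0.5, 1 - P)
    x[bad] <- x[bad] + 1e-12
    x
  }
  with_seed(seed, {
    M <- matrix(NA_real_, n, dims)
    M[1, ] <- nudge(stats::runif(dims))
    if (n > 1) for (k in 2:n) M[k, ] <- nudge(step(M[k - 1, ]))
    M
  })
}

#' Scale unit-cube points into a search space
#'
#' Affine map `lower + u * (upper - lower)` applied columnwise.
#'
#' @param unit matrix with entries in \[0, 1), one column per dimension.
#' @param space a [search_space()].
#' @return matrix of in-bounds positions.
#' @export
scale_to_bounds <- function(unit, space) {
  if (ncol(unit) != space$dims)
    stopf("unit has %d columns but the space has %d dimensions", ncol(unit), space$dims)
  sweep(sweep(unit, 2, space$upper - space$lower, "*"), 2, space$lower, "+")
}

# random unit directions, one per row
.unit_directions <- function(n, dims) {
  B <- matrix(stats::rnorm(n * dims), n, dims)
  B / sqrt(rowSums(B^2))
}

.check_finite <- function(f, X) {
  if (any(!is.finite(f))) {
    i <- which(!is.finite(f))[1]
    stopf("objective returned a non-finite value at (%s)",
          paste(signif(X[i, ], 6), collapse = ", "))
  }
  f
}

# One vectorized BAS step for a population.  P: pop x dims positions with
# fitness fp.  Returns list(P, f, evals).
.bas_step_pop <- function(P, fp, objective, space, d, delta, counter = NULL) {
  n <- nrow(P)
  B <- .unit_directions(n, ncol(P))
  Xr <- .clip(P + d * B, space); Xl <- .clip(P - d * B, space)
  fr <- .check_finite(objective(Xr), Xr)
  fl <- .check_finite(objective(Xl), Xl)
  Xn <- .clip(P - delta * B * sign(fr - fl), space)
  fn <- .check_finite(objective(Xn), Xn)
  better <- fn < fp                      # ties keep the incumbent
  P[better, ] <- Xn[better, , drop = FALSE]
  fp[better] <- fn[better]
  list(P = P, f = fp, evals = 3L * n)
}

#' Single-candidate BAS step
#'
#' Draws a random unit direction `b`, probes the objective at the two
#' antenna points `x + d*b` and `x - d*b` (clipped to bounds before
#' evaluation), moves by `-delta * b * sign(f(right) - f(left))`, clips,
#' and keeps the better of the move and the input (greedy).
#'
#' @param x numeric position within `space`.
#' @param fx fitness of `x` (`NULL` = evaluate).
#' @param objective row-vectorized objective.
#' @param space a [search_space()].
#' @param d antenna length; `delta` step size (both > 0).
#' @param delta step size.
#' @return list with `x`, `fx`, `evals`.
#' @export
bas_step <- function(x, fx = NULL, objective, space, d, delta) {
  if (is.null(fx)) fx <- objective(matrix(x, nrow = 1))
  r <- .bas_step_pop(matrix(x, nrow = 1), fx, objective, space, d, delta)
  list(x = drop(r$P), fx = r$f, evals = r$evals)
}

# Vectorized adaptive t mutation: with probability p_m per row propose
# x * (1 + t), t ~ Student-t(df), greedy acceptance.
.t_mutation_pop <- function(P, fp, objective, space, df, p_m) {
  n <- nrow(P)
  sel <- stats::runif(n) < p_m
  # draw the full perturbation block regardless of acceptance so the RNG
  # stream layout does not depend on data values
  Tm <- matrix(stats::rt(n * ncol(P), df = df), n, ncol(P))
  evals <- 0L
  if (any(sel)) {
    Xm <- .clip(P[sel, , drop = FALSE] * (1 + Tm[sel, , drop = FALSE]), space)
    fm <- .check_finite(objective(Xm), Xm)
    evals <- nrow(Xm)
    acc <- fm < fp[sel]
    idx <- which(sel)[acc]
    P[idx, ] <- Xm[acc, , drop = FALSE]
    fp[idx] <- fm[acc]
  }
  list(P = P, f = fp, evals = evals)
}

#' Adaptive t-distribution mutation
#'
#' With probability `p_m` proposes `x * (1 + t)` with `t` a vector of
#' i.i.d. Student-t draws whose degrees of freedom equal the current
#' iteration number: Cauchy-like global moves at iteration 1, near-Gaussian
#' local moves late.  The proposal is clipped to bounds and accepted only
#' if strictly better.
#'
#' @inheritParams bas_step
#' @param iteration current iteration (degrees of freedom), >= 1.
#' @param p_m mutation probability.
#' @return list with `x`, `fx`, `evals`.
#' @export
t_mutation <- function(x, fx = NULL, objective, space, iteration, p_m = 0.5) {
  if (iteration < 1) stopf("iteration must be >= 1")
  if (is.null(fx)) fx <- objective(matrix(x, nrow = 1))
  r <- .t_mutation_pop(matrix(x, nrow = 1), fx, objective, space, df = iteration, p_m = p_m)
  list(x = drop(r$P), fx = r$f, evals = r$evals)
}

#' Step-halving random-walk refinement
#'
#' Samples neighbors uniformly in the ball of the current step radius
#' around the incumbent (clipped to bounds).  A better neighbor becomes
#' the incumbent and resets the failure counter; after `N` consecutive
#' failures the radius halves.  Terminates when the radius falls below
#' `step_threshold` or the evaluation cap is reached.  The returned
#' fitness is never worse than the input.
#'
#' @inheritParams bas_step
#' @param N failures before halving.
#' @param step_init,step_threshold initial / terminal radius
#'   (`step_threshold < step_init`).
#' @param max_evals cap on objective calls.
#' @return list with `x`, `fx`, `evals`, `halvings`.
#' @export
random_walk <- function(x, fx = NULL, objective, space, step_init, step_threshold,
                        N = 10L, max_evals = 1000L) {
  if (step_threshold <= 0 || step_init <= step_threshold)
    stopf("need step_init > step_threshold > 0")
  if (is.null(fx)) fx <- objective(matrix(x, nrow = 1))
  dims <- space$dims
  step <- step_init
  evals <- 0L; halvings <- 0L
  while (step >= step_threshold && evals < max_evals) {
    m <- min(N, max_evals - evals)
    # N candidate neighbors, uniform in the radius-`step` ball
    B <- .unit_directions(m, dims)
    radii <- step * stats::runif(m)^(1 / dims)
    Xc <- .clip(matrix(x, m, dims, byrow = TRUE) + radii * B, space)
    fc <- .check_finite(objective(Xc), Xc)
    evals <- evals + m
    hit <- which(fc < fx)
    if (length(hit)) {       # first improving neighbor in draw order wins
      i <- hit[1]
      x <- Xc[i, ]; fx <- fc[i]
    } else if (m == N) {
      step <- step / 2
      halvings <- halvings + 1L
    } else break             # cap reached mid-block
  }
  list(x = x, fx = fx, evals = evals, halvings = halvings)
}

#' Run BAS or IBAS on a box-constrained minimization problem
#'
#' The `"BAS"` variant initializes the population uniformly and applies
#' one antenna step per member per iteration.  The `"IBAS"` variant
#' initializes from the piecewise chaotic map and, per iteration, applies
#' the antenna step, then the adaptive t mutation to each member, then the
#' random-walk refinement to the iteration's best (per
#' `cfg$walk_mode`).  Both track the global best across the population;
#' beetles are otherwise independent.
#'
#' @param objective row-vectorized objective to minimize (see
#'   [vectorize_objective()]).
#' @param space a [search_space()].
#' @param cfg an [optimizer_config()].
#' @param variant `"IBAS"` (default) or `"BAS"`.
#' @return object of class `opt_result`: list with `best` (list of
#'   `position`, `fitness`, `origin`), `trace` (best-so-far fitness per
#'   executed iteration, non-increasing), `evaluations_used`,
#'   `iterations_run`, `variant` and the `config` snapshot.
#' @export
run_optimizer <- function(objective, space, cfg = optimizer_config(),
                          variant = c("IBAS", "BAS")) {
  variant <- match.arg(variant)
  stopifnot(inherits(space, "search_space"), inherits(cfg, "optimizer_config"))
  width <- mean(space$upper - space$lower)
  d <- cfg$d0 %||% (0.1 * width)
  delta <- cfg$delta0 %||% (0.1 * width)
  wstep <- cfg$walk_step_init %||% (0.1 * width)
  wthr <- cfg$walk_step_threshold %||% (1e-6 * width)
  n <- cfg$population_size

  with_seed(cfg$seed, {
    if (variant == "IBAS") {
      U <- piecewise_chaotic_sample(n, space$dims, P = cfg$chaotic_P,
                                    seed = sample.int(2^31 - 2, 1))
      P <- scale_to_bounds(U, space)
    } else {
      P <- scale_to_bounds(matrix(stats::runif(n * space$dims), n, space$dims), space)
    }
    fp <- .check_finite(objective(P), P)
    evals <- n
    bi <- which.min(fp)
    best_x <- P[bi, ]; best_f <- fp[bi]; best_origin <- "init"
    trace <- numeric(cfg$iterations)
    stall <- 0L
    iters_run <- 0L

    for (t in seq_len(cfg$iterations)) {
      prev_best <- best_f
      s <- .bas_step_pop(P, fp, objective, space, d, delta)
      P <- s$P; fp <- s$f; evals <- evals + s$evals
      if (min(fp) < best_f) {
        bi <- which.min(fp); best_x <- P[bi, ]; best_f <- fp[bi]; best_origin <- "bas_step"
      }
      if (variant == "IBAS") {
        m <- .t_mutation_pop(P, fp, objective, space, df = t, p_m = cfg$p_m)
        P <- m$P; fp <- m$f; evals <- evals + m$evals
        if (min(fp) < best_f) {
          bi <- which.min(fp); best_x <- P[bi, ]; best_f <- fp[bi]; best_origin <- "mutation"
        }
        if (cfg$walk_mode == "per_iteration") {
          w <- random_walk(best_x, best_f, objective, space, wstep, wthr,
                           N = cfg$walk_N, max_evals = cfg$walk_max_evals)
          evals <- evals + w$evals
          if (w$fx < best_f) { best_x <- w$x; best_f <- w$fx; best_origin <- "random_walk" }
        }
      }
      d <- cfg$eta * d + 0.01
      delta <- cfg$eta * delta
      trace[t] <- best_f
      iters_run <- t
      stall <- if (prev_best - best_f < cfg$plateau_tol) stall + 1L else 0L
      if (!is.null(cfg$plateau_patience) && stall >= cfg$plateau_patience) break
    }
    if (variant == "IBAS" && cfg$walk_mode == "final") {
      w <- random_walk(best_x, best_f, objective, space, wstep, wthr,
                       N = cfg$walk_N, max_evals = cfg$walk_max_evals)
      evals <- evals + w$evals
      if (w$fx < best_f) { best_x <- w$x; best_f <- w$fx; best_origin <- "random_walk" }
      trace[iters_run] <- best_f
    }
    structure(list(best = list(position = best_x, fitness = best_f, origin = best_origin),
                   trace = trace[seq_len(iters_run)],
                   evaluations_used = evals, iterations_run = iters_run,
                   variant = variant, config = cfg),
              class = "opt_result")
  })
}

#' @export
print.opt_result <- function(x, ...) {
  cat(sprintf("%s: best fitness %.6g after %d iterations (%d evaluations)\n",
              x$variant, x$best$fitness, x$iterations_run, x$evaluations_used))
  invisible(x)
}

#' Paired BAS/IBAS benchmark campaign
#'
#' Runs both optimizer variants on each supplied benchmark function with
#' matched budgets and matched seeds `seed_base + 1 ... seed_base + repeats`,
#' and aggregates mean best-so-far convergence curves and final-best
#' summaries.
#'
#' @param suite list of `benchmark_function`s (default the full 23).
#' @param cfg an [optimizer_config()]; its `seed` field is overridden per
#'   repeat.
#' @param repeats runs per function and variant (default 30).
#' @param seed_base offset for the per-repeat seeds.
#' @return list with `curves` (data.frame: function_id, variant, iteration,
#'   mean_best, sd_best) and `summary` (data.frame: function_id, name,
#'   category, variant, mean_final, sd_final).
#' @export
benchmark_campaign <- function(suite = benchmark_suite(), cfg = optimizer_config(),
                               repeats = 30L, seed_base = 0L) {
  if (repeats < 1) stopf("repeats must be >= 1")
  curves <- list(); summ <- list()
  for (fn in suite) {
    space <- search_space(fn$lower, fn$upper, fn$dim)
    for (variant in c("BAS", "IBAS")) {
      finals <- numeric(repeats)
      tr <- matrix(NA_real_, repeats, cfg$iterations)
      for (r in seq_len(repeats)) {
        cfg_r <- cfg; cfg_r$seed <- as.integer(seed_base + r)
        cfg_r$plateau_patience <- NULL   # full-budget runs for curve averaging
        res <- run_optimizer(fn$fun, space, cfg_r, variant)
        tr[r, ] <- res$trace
        finals[r] <- res$best$fitness
      }
      curves[[length(curves) + 1L]] <- data.frame(
        function_id = fn$id, variant = variant, iteration = seq_len(cfg$iterations),
        mean_best = colMeans(tr), sd_best = apply(tr, 2, stats::sd))
      summ[[length(summ) + 1L]] <- data.frame(
        function_id = fn$id, name = fn$name, category = fn$category,
        variant = variant, mean_final = mean(finals), sd_final = stats::sd(finals))
    }
  }
  list(curves = do.call(rbind, curves), summary = do.call(rbind, summ))
}
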