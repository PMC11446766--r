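---
title: "Self-evolving hyperparameter optimization with an improved beetle antennae search: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-evolving hyperparameter optimization with an improved beetle antennae search: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibasml)
```

## Scope

`ibasml` implements a "self-evolving" modelling workflow for binary
clinical risk prediction, built around a population metaheuristic that
evolves classifier hyperparameters. The motivating application is early
prediction of diabetic retinopathy from routine clinical and laboratory
indicators, and the package bundles everything that study design needs:
the optimizer and its benchmark validation suite, the hyperparameter
search layer, the classical risk-factor statistics, classifier
evaluation metrics, a synthetic cohort generator, and a one-step
pipeline tying them together.

## The optimizer

### Baseline beetle antennae search

Beetle antennae search (BAS) is a derivative-free minimizer. At
position $x$ with antenna length $d$ and step size $\delta$, it draws a
random unit direction $b$, probes the objective at $x + d b$ and
$x - d b$ (both clipped into the box), and moves

$$x \leftarrow x - \delta\, b\, \operatorname{sign}\!\big(f(x + d b) - f(x - d b)\big),$$

keeping the move only if it improves (greedy; ties keep the
incumbent). Both schedule parameters decay geometrically per iteration,
$d \leftarrow 0.95\,d + 0.01$ and $\delta \leftarrow 0.95\,\delta$, the
standard published schedule. BAS is single-agent in origin; here a
population of independent beetles is run (default 30 for 200
iterations) sharing only the global-best tracker, which is the simplest
population reading of the comparison setup the optimizer is validated
under. $d_0$ and $\delta_0$ default to 10% of the mean bound width;
no published values exist for them and this scale-free default behaves
consistently across the benchmark suite's very different box sizes.

### The three IBAS components

**Piecewise chaotic initialization.** Initial positions come from
columnwise orbits of the piecewise-linear chaotic map on $[0,1)$ with
parameter $P = 0.4$ (branches $x/P$, $(x-P)/(0.5-P)$,
$(1-P-x)/(0.5-P)$, $(1-x)/P$), scaled affinely into the box. Chaotic
orbits are dense and near-uniform, so a small population covers the
space better than i.i.d. uniform draws of the same size. Orbit states
landing exactly on the degenerate fixed set $\{0, P, 0.5, 1-P\}$ are
nudged by $10^{-12}$.

**Adaptive $t$-distribution mutation.** With probability $p_m = 0.5$ a
member proposes $x' = x\,(1 + t)$ with $t$ i.i.d. Student-$t$ whose
degrees of freedom equal the iteration number: Cauchy-like global jumps
at the start, near-Gaussian local perturbation at the end. The
multiplicative form is assumed (the additive variant is not
implemented); it makes the move scale-equivariant in each coordinate
but leaves exact zeros fixed, which is harmless in practice because
boxes here never collapse onto the origin and the antenna step moves
members off any axis. Acceptance is greedy.

**Random-walk refinement.** The iteration's best is refined by
sampling neighbors uniformly in a ball whose radius starts at 10% of
the mean bound width; an improving neighbor becomes the incumbent and
resets the failure counter, and after $N = 10$ consecutive failures the
radius halves. The walk stops below a radius of $10^{-6}$ of the mean
bound width or at a hard cap of 1000 objective calls per invocation.
Whether the walk should run every iteration or once at termination is
genuinely open; the default variant applies it to every iteration's
best (stronger refinement, matching the aggressive convergence the
method claims on benchmarks), while the hyperparameter layer uses the
end-only switch because there each objective call is a $k$-fold model
fit and a per-iteration walk would dominate the budget.

All operators clip to the box rather than reflecting, and every
retained candidate is at least as good as its input, so best-so-far
traces are non-increasing by construction. Runs are bit-reproducible
given the seed.

### Benchmark validation

The 23-function registry is the canonical F1--F23 suite (7 unimodal,
16 multimodal), the only widely used 23-function collection with that
unimodal/multimodal split; the source study names the count and split
but not the functions, so adopting this suite is an informed
substitution, not a transcribed fact. Scalable functions default to
30-D (the acceptance runs use 10-D to keep a 1380-run campaign inside
a sensible wall-clock on one core); the fixed-dimension functions keep
their natural 2--6 dimensions. Optima without a closed form are
recorded at the precision of their published optimum points, with the
registered minimum being the function value at that point
(`opt_exact = FALSE` marks these). The noisy quartic draws its
uniform(0,1) noise from the caller's RNG stream so campaigns stay
reproducible.

The campaign runs both variants at matched budgets (population 30, 200
iterations) with matched seed sets and averages best-so-far curves
over repeats. The headline property checked in the tests — IBAS's mean
final best at worst equal to BAS's on a majority of the 23 functions,
and sub-$10^{-3}$ accuracy on the 2-D sphere in at least 27 of 30
seeds — was frozen before being asserted, from reference runs of this
implementation at those budgets.

## Hyperparameter evolution

The search spaces are taken verbatim from the published optimization
table: logistic regression (inverse regularization strength
$[0.01, 100]$ step 10, penalty L1/L2), RBF SVM (cost and gamma
$[0.01, 100]$ step 10), XGBoost (learning rate $[0.01, 1]$ step 0.1,
maximum depth $[1, 20]$ step 0.5, boosting rounds $[1, 100]$ step 10).
Grids include both endpoints, with the final point clipped to the
upper bound; integer parameters (depth, rounds) round half-up and drop
duplicates, so the printed step-0.5 depth grid becomes the integers
1--20. IBAS searches the continuous unit cube and decodes positions
through the same rounding, which guarantees every evaluated assignment
is in-range.

Fitness is the stratified $k$-fold cross-validated metric (default
ROC-AUC, the headline metric of the evaluation tables; accuracy and F1
are available) of the classifier fitted with the candidate assignment.
Z-score normalization parameters are fitted per training fold and
applied to its validation fold — never across the fold boundary. Fold
assignment is deterministic given the seed, and grid search and
evolution share the same folds, so their fitness values are directly
comparable. Early stopping uses an absolute plateau tolerance of
$10^{-4}$ with patience 20 iterations, a concrete reading of
"no significant improvement in fitness".

Classifiers are consumed through a uniform fit/predict-probability
adapter: `glmnet` for penalized logistic regression (the inverse
strength $C$ maps to `lambda = 1/(C n)`; single-feature fits fall back
to an unpenalized GLM because the elastic-net solver requires two
columns), `e1071::svm` with Platt-scaled probabilities (its internal
calibration CV is run under a pinned RNG so fitness is deterministic),
and `xgboost` with the exact tree method on one thread. Re-implementing
any of these learners is explicitly out of scope.

Joint feature selection is supported through an optional per-feature
mask appended to the IBAS position vector and thresholded at 0.5
(all-dropped proposals fall back to the full feature set). The
mechanism by which the original one-step system couples feature
selection to the optimizer is not described anywhere; this encoding is
the package's interpretation and ships disabled by default.

## Clinical statistics

The univariate screen uses the pooled-variance two-sample $t$-test for
continuous indicators and the Pearson $\chi^2$ (no continuity
correction) for binary ones; both choices reproduce every recomputable
statistic of the published univariate table to three decimals, which
Welch's $t$ and the Yates-corrected $\chi^2$ do not. The multivariate
model is maximum-likelihood logistic regression (IRLS via `stats::glm`)
on the original predictor scales, with Wald statistics
$(\beta/\mathrm{SE})^2$ against $\chi^2_1$, odds ratios $e^\beta$, and
two interval conventions: the standard $\exp(\beta \pm 1.96\,
\mathrm{SE})$ and a compatibility mode $\mathrm{OR} \pm 1.96\,
\mathrm{SE}$ that reproduces the published intervals (which match the
additive form, not the exponential one); the package asserts neither as
"correct" and defaults to the standard form. Perfect separation and
rank deficiency abort with the offending column named rather than
returning silently unstable estimates. No multiplicity correction is
applied in the screen, matching the source analysis.

## The synthetic cohort

No patient-level data are deposited, so the generator emulates the
published two-group summary table: 150 subjects per arm, 15 continuous
indicators drawn per-group Gaussian at the printed mean/SD, 4 binary
indicators drawn per-group Bernoulli at the printed proportions.
Distributional shape beyond mean/SD is unknowable from the table;
independent Gaussians are the minimal model consistent with it, with
an optional correlation preset (SBP--DBP 0.6, FBG--HbA1c 0.6, TC--LDL
0.7 — engineering choices for robustness testing, not estimates).
Continuous draws are truncated to clinically plausible ranges by
resampling, which biases the moments of range-cut variables (diabetes
duration, HDL-C, serum creatinine most visibly); the tests therefore
check empirical means against the analytic truncated-normal moment
rather than the raw profile mean. The glucose units are carried
verbatim from the source table ("umol/L"), almost certainly a misprint
for mmol/L; the values are consistent with mmol/L.

What passing tests on this cohort do show: the pipeline's mechanics,
leakage hygiene, determinism, and the optimizer's behaviour on a
realistic 19-column tabular problem. What they cannot show: real-data
performance. The generated cohort is close to separable (the
albumin/creatinine ratio alone has a standardized group difference
near 3), so absolute metric values here are optimistic relative to the
published patient-cohort tables, which depend on private data and are
deliberately not asserted anywhere in the package.

## The one-step pipeline

`one_step()` performs: stratified 80/20 split (seed-deterministic,
depending only on the outcome vector), cleaning fitted on training
rows only (median/mode imputation, winsorization at median $\pm 3\,
\mathrm{IQR}/1.349$, z-scoring; optional random minority oversampling
of training rows), IBAS hyperparameter evolution with cross-validated
fitness on the training portion, a final refit on the full cleaned
training set, and a single evaluation of the untouched test set. The
original workflow normalized before splitting; that leaks test
statistics into training, so the default here is train-only fitting
with a `normalization_scope = "global"` compatibility switch. The
leakage contract is load-bearing and is enforced by a test that
poisons every held-out cell with sentinel values and requires all
training-fitted artifacts to be bit-identical. Risk banding uses a
0.5 threshold by default (the original system's threshold is
unstated), with probabilities exactly at the threshold banded high.

## Numerical and runtime choices

* Optimizer objectives must be finite; a non-finite value aborts with
  the offending position, rather than being silently ranked.
* The random walk evaluates its $N$ candidate neighbors as one batch;
  when an earlier neighbor improves, later draws in the batch are
  discarded. Distributionally this matches the sequential description
  (the discarded draws are i.i.d.), and it keeps the walk vectorized.
* Acceptance-scale runs use 10-D scalable benchmarks, 30 campaign
  repeats in the test suite and 10 in the reporting script, and
  reduced evolution budgets (population 10, 30 iterations) for the
  model layer — sizes chosen so a full verification pass stays
  comfortable on a single core.
* All randomness is derived from explicit integer seeds; functions
  restore the caller's RNG state.

## Known limitations

* The per-iteration random walk makes IBAS spend roughly an order of
  magnitude more objective evaluations per iteration than BAS at the
  same population; the benchmark comparison is therefore a comparison
  of the full improved procedure at matched *iteration* budgets, not
  matched evaluation counts (the campaign records evaluation counts so
  either view can be taken).
* Grid search and evolution maximize the same cross-validated surface;
  neither provides an unbiased generalization estimate (no nested CV).
* The cohort generator does not model longitudinal structure, missing
  not-at-random patterns, or measurement error.
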