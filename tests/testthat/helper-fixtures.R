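# Shared fixture builders; everything is generated in code at test time.

# tiny linearly separable two-class dataset
separable_data <- function(n = 60, p = 4, gap = 4, seed = 42) {
  ibasml:::with_seed(seed, {
    y <- rep(c(0L, 1L), each = n / 2)
    X <- matrix(rnorm(n * p), n, p)
    X[, 1] <- X[, 1] + gap * y
    list(X = X, y = y)
  })
}

# XOR-style dataset: the signal lives in a two-feature interaction, so a
# depth-1 (stump) booster cannot represent it but depth >= 2 can
xor_data <- function(n = 240, seed = 11, noise = 0.05) {
  ibasml:::with_seed(seed, {
    x1 <- rbinom(n, 1, 0.5)
    x2 <- rbinom(n, 1, 0.5)
    y <- as.integer(xor(x1 == 1, x2 == 1))
    flip <- runif(n) < noise
    y[flip] <- 1L - y[flip]
    X <- cbind(x1 = x1 + rnorm(n, 0, 0.01), x2 = x2 + rnorm(n, 0, 0.01),
               junk = rnorm(n))
    list(X = X, y = y)
  })
}

# brute-force ROC AUC by exhaustive positive-negative pair counting
pair_count_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
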