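# Shared fixtures and independent oracles used across the test files.
# Everything here is built in code at test time; no stored data.

# Wrap a plain function of the feature matrix as a predictor object.
oracle_predictor <- function(fn, outcome_type = "continuous") {
  new_predictor(function(X) fn(X), outcome_type = outcome_type,
                label = "oracle")
}

# Brute-force enumeration of the population importance score
#   M_j = E[ (mu(X) - mu(X^(j)))^2 ]
# for two features that each take values in `vals` with equal probability,
# replacing feature `j` by an independent copy.  Independent of the
# permutation machinery: a plain triple sum over the support.
enumerate_m_twopoint <- function(mu_fn, vals = c(-1, 1), j = 1) {
  tot <- 0
  pr <- 1 / length(vals)^3
  for (x1 in vals) for (x2 in vals) for (xr in vals) {
    x <- c(x1, x2)
    xperm <- x
    xperm[j] <- xr
    tot <- tot + pr * (mu_fn(x[1], x[2]) - mu_fn(xperm[1], xperm[2]))^2
  }
  tot
}

# Monte-Carlo mean of the empirical permutation score with the TRUE mean
# function plugged in (no model fitting): D independent datasets of size N,
# one uniform permutation each, squared-error contributions for feature 1.
# Vectorized over datasets; returns the draws so the caller can form a
# Monte-Carlo confidence band.
mc_perm_score_feature1 <- function(D, N, mu_fn, vals = c(-1, 1),
                                   noise_sd = 1) {
  X1 <- matrix(sample(vals, D * N, replace = TRUE), D, N)
  X2 <- matrix(sample(vals, D * N, replace = TRUE), D, N)
  y <- mu_fn(X1, X2) + matrix(rnorm(D * N, sd = noise_sd), D, N)
  # one uniform permutation of 1..N per dataset
  ord <- t(apply(matrix(runif(D * N), D, N), 1L, order))
  X1p <- matrix(X1[cbind(rep(seq_len(D), N), as.vector(ord))], D, N)
  rowMeans((y - mu_fn(X1p, X2))^2 - (y - mu_fn(X1, X2))^2)
}

# Linear-model fitting backend used as a transparent learner in tests.
lm_backend <- function(X, y) {
  df <- data.frame(y = y, X)
  fit <- stats::lm(y ~ ., data = df)
  new_predictor(
    function(newX) as.numeric(stats::predict(fit, data.frame(newX))),
    outcome_type = "continuous", label = "lm")
}

# Small continuous dataset with a known linear signal in feature 1.
make_linear_data <- function(n, p = 5, beta1 = 1, seed = NULL,
                             noise_sd = 1) {
  gen <- function() {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("X", seq_len(p))))
    list(X = X, y = beta1 * X[, 1] + rnorm(n, sd = noise_sd))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
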