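# Block-correlated Gaussian simulation designs with known causal features.
#
# Features are multivariate normal with a block-diagonal compound-symmetric
# covariance: unit variances, correlation `rho` within blocks of size `p0`,
# zero across blocks.  One feature from each of the first five blocks
# carries signal; the remaining features split into S0 (nulls correlated
# with a causal feature, i.e. sharing its block) and S1 (independent nulls).

#' Specify a block compound-symmetric covariance
#'
#' @param p0 block size (default 10).
#' @param n_blocks number of blocks (default 10, giving `p = 100`).
#' @param rho within-block correlation in `[0, 1)`.
#' @return an object of class `block_cov_spec`.
#' @export
block_cov_spec <- function(p0 = 10L, n_blocks = 10L, rho = 0) {
  if (!is.numeric(rho) || rho < 0 || rho >= 1) {
    stop("`rho` must lie in [0, 1)", call. = FALSE)
  }
  if (p0 < 1L || n_blocks < 1L) {
    stop("`p0` and `n_blocks` must be positive integers", call. = FALSE)
  }
  structure(
    list(p0 = as.integer(p0), n_blocks = as.integer(n_blocks),
         rho = rho, p = as.integer(p0) * as.integer(n_blocks)),
    class = "block_cov_spec"
  )
}

#' Build the block-diagonal compound-symmetric covariance matrix
#'
#' Ones on the diagonal, `rho` within each `p0 x p0` block, zero across
#' blocks.  Positive definite for `rho` in `[0, 1)`: the block eigenvalues
#' are `1 + (p0 - 1) * rho` and `1 - rho`.
#'
#' @param spec a [block_cov_spec()].
#' @return a `p x p` covariance matrix.
#' @export
build_block_covariance <- function(spec) {
  stopifnot(inherits(spec, "block_cov_spec"))
  block <- matrix(spec$rho, spec$p0, spec$p0)
  diag(block) <- 1
  Sigma <- matrix(0, spec$p, spec$p)
  for (b in seq_len(spec$n_blocks)) {
    idx <- (b - 1L) * spec$p0 + seq_len(spec$p0)
    Sigma[idx, idx] <- block
  }
  Sigma
}

# Index bookkeeping: causal features are the first feature of each of the
# first five blocks; S0 = rest of those blocks; S1 = all later blocks.
signal_index_sets <- function(spec) {
  if (spec$n_blocks < 5L) {
    stop("the signal design needs at least 5 blocks", call. = FALSE)
  }
  causal <- spec$p0 * (0:4) + 1L
  S0 <- setdiff(seq_len(5L * spec$p0), causal)
  S1 <- setdiff(seq_len(spec$p), seq_len(5L * spec$p0))
  list(causal = causal, S0 = S0, S1 = S1)
}

# MVN draw via the lower-triangular Cholesky factor of Sigma (row i of X is
# L z_i); the factorization order is fixed so identical seeds give
# bit-identical layouts across runs.
draw_features <- function(N, spec) {
  Sigma <- build_block_covariance(spec)
  R <- chol(Sigma) # upper triangular, t(R) = L
  Z <- matrix(stats::rnorm(N * spec$p), N, spec$p)
  X <- Z %*% R
  colnames(X) <- paste0("X", seq_len(spec$p))
  X
}

# The nonlinear regression surface: a linear term, a log-quadratic term and
# a product interaction, one causal feature per block.
mean_surface <- function(X, p0) {
  X[, 1L] +
    2 * log(1 + 2 * X[, p0 + 1L]^2 + (X[, 2L * p0 + 1L] + 1)^2) +
    X[, 3L * p0 + 1L] * X[, 4L * p0 + 1L]
}

new_sim_dataset <- function(X, y, spec, seed, outcome_type, mu, prob = NULL) {
  sets <- signal_index_sets(spec)
  structure(
    list(X = X, y = y, outcome_type = outcome_type,
         mu = mu, prob = prob,
         causal = sets$causal, S0 = sets$S0, S1 = sets$S1,
         spec = spec, seed = seed, rng_kind = RNGkind()[1L]),
    class = "permfit_sim"
  )
}

#' Simulate the continuous-outcome scenario
#'
#' Draws `X ~ MVN(0, Sigma)` with the block covariance of `spec` and
#' `Y = X_1 + 2 log(1 + 2 X_{p0+1}^2 + (X_{2p0+1} + 1)^2) +
#' X_{3p0+1} X_{4p0+1} + eps` with `eps ~ N(0, 1)` independent of `X`.
#'
#' @param N sample size.
#' @param spec a [block_cov_spec()]; needs at least 5 blocks.
#' @param seed optional seed (bit-identical data for identical seeds).
#' @return an object of class `permfit_sim`: list with `X`, `y`, the true
#'   surface `mu`, `outcome_type`, and the index sets `causal`, `S0`
#'   (correlated nulls) and `S1` (independent nulls).
#' @export
generate_continuous <- function(N, spec = block_cov_spec(), seed = NULL) {
  stopifnot(N >= 1L)
  signal_index_sets(spec) # validates the block count up front
  with_seed(seed, {
    X <- draw_features(N, spec)
    mu <- mean_surface(X, spec$p0)
    y <- mu + stats::rnorm(N)
    new_sim_dataset(X, y, spec, seed, "continuous", mu)
  })
}

#' Simulate the binary-outcome scenario
#'
#' Same feature design as [generate_continuous()]; the outcome is
#' `Y ~ Bernoulli(expit(4 X_1 + 8 log(1 + 2 X_{p0+1}^2 +
#' (X_{2p0+1} + 1)^2) + 4 X_{3p0+1} X_{4p0+1} - 11))`.  The true event
#' probabilities are retained in `$prob` for oracle checks.
#'
#' @inheritParams generate_continuous
#' @return a `permfit_sim` with binary `y` and the true probability
#'   vector `prob`.
#' @export
generate_binary <- function(N, spec = block_cov_spec(), seed = NULL) {
  stopifnot(N >= 1L)
  signal_index_sets(spec)
  with_seed(seed, {
    X <- draw_features(N, spec)
    p0 <- spec$p0
    eta <- 4 * X[, 1L] +
      8 * log(1 + 2 * X[, p0 + 1L]^2 + (X[, 2L * p0 + 1L] + 1)^2) +
      4 * X[, 3L * p0 + 1L] * X[, 4L * p0 + 1L] - 11
    prob <- stats::plogis(eta)
    y <- stats::rbinom(N, 1L, prob)
    new_sim_dataset(X, y, spec, seed, "binary", eta, prob)
  })
}

#' Cartesian grid of simulation scenarios
#'
#' Expands correlation levels, sample sizes and dimensions into one row per
#' scenario, each with a scenario id and a derived base seed so replicate
#' streams are distinct across scenarios.
#'
#' @param rhos numeric vector of within-block correlations.
#' @param Ns integer vector of sample sizes.
#' @param ps integer vector of feature dimensions (multiples of `p0`).
#' @param p0 block size.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param base_seed master seed from which per-scenario seeds are derived.
#' @return a data frame with columns `scenario`, `rho`, `N`, `p`, `p0`,
#'   `outcome_type`, `seed`.
#' @export
scenario_grid <- function(rhos, Ns, ps = 100L, p0 = 10L,
                          outcome_type = "continuous", base_seed = 1L) {
  stopifnot(length(rhos) >= 1L, length(Ns) >= 1L, length(ps) >= 1L)
  if (any(ps %% p0 != 0L)) {
    stop("each `ps` entry must be a multiple of `p0`", call. = FALSE)
  }
  g <- expand.grid(rho = rhos, N = Ns, p = ps,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$p0 <- as.integer(p0)
  g$outcome_type <- outcome_type
  g$scenario <- sprintf("rho%s_N%d_p%d_%s", g$rho, g$N, g$p, outcome_type)
  g$seed <- vapply(g$scenario, function(s) derive_seed(base_seed, s),
                   integer(1L))
  g[, c("scenario", "rho", "N", "p", "p0", "outcome_type", "seed")]
}
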