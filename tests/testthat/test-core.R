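# Core estimator: permutation, loss contributions, inference, cross-fitting.

test_that("permute_column reorders only the target column and preserves the multiset", {
  X <- cbind(a = c(1, 2, 3), b = c(10, 20, 30))
  out <- permute_column(X, 2, order = c(3, 1, 2))
  expect_identical(out[, "a"], X[, "a"])
  expect_equal(out[, "b"], c(30, 10, 20), ignore_attr = TRUE)
  expect_identical(X[, "b"], c(10, 20, 30)) # input untouched

  # constant column: permutation is invisible
  Xc <- cbind(a = 1:4, b = rep(7, 4))
  expect_identical(permute_column(Xc, "b", seed = 5), Xc + 0)

  # determinism under a fixed seed
  X2 <- matrix(rnorm(50), 10, 5)
  expect_identical(permute_column(X2, 3, seed = 42),
                   permute_column(X2, 3, seed = 42))

  # property: output column is always a permutation of the input column
  set.seed(99)
  for (i in 1:20) {
    Xr <- matrix(rnorm(40), 8, 5,
                 dimnames = list(NULL, paste0("X", 1:5)))
    j <- sample(5, 1)
    out <- permute_column(Xr, j)
    expect_identical(sort(out[, j]), sort(Xr[, j]))
    expect_identical(out[, -j], Xr[, -j])
  }
})

test_that("permute_column moves a column block as one unit", {
  # one-hot pair: rows must stay paired after the joint permutation
  X <- cbind(g1 = c(1, 0, 0, 1), g2 = c(0, 1, 1, 0), z = rnorm(4))
  out <- permute_column(X, c(1, 2), order = c(4, 3, 2, 1))
  expect_equal(out[, 1] + out[, 2], rep(1, 4), ignore_attr = TRUE)
  expect_equal(out[, 1], c(1, 0, 0, 1)[c(4, 3, 2, 1)], ignore_attr = TRUE)
})

test_that("permute_column validates its arguments", {
  X <- matrix(1:6, 3, 2)
  expect_error(permute_column(X, 5), "index")
  expect_error(permute_column(X, 1, order = c(1, 2)), "permutation")
  expect_error(permute_column(X, 1, order = c(1, 1, 2)), "permutation")
})

test_that("squared-error contributions match the closed form", {
  y <- c(3, 0, -1)
  expect_equal(loss_contrib_continuous(y, y), c(0, 0, 0))
  expect_equal(loss_contrib_continuous(3, 1), 4)
  expect_error(loss_contrib_continuous(1:3, 1:2), "length")
  # mean over standard normal residuals estimates the noise variance 1
  set.seed(1)
  e <- rnorm(2e5)
  expect_equal(mean(loss_contrib_continuous(e, rep(0, length(e)))), 1, tolerance = 0.02)
})

test_that("binomial deviance contributions match hand evaluation", {
  expect_equal(deviance_contrib(1, 0.8, 0.5), log(1.6))
  expect_equal(deviance_contrib(c(0, 1), c(0.3, 0.6), c(0.3, 0.6)),
               c(0, 0))
  # clipped boundary: permuted probability of exactly 1 stays finite
  v <- deviance_contrib(0, 0.5, 1, clip_eps = 1e-6)
  expect_true(is.finite(v) && v > 0)
  expect_equal(v, log(0.5 / 1e-6))
  expect_error(deviance_contrib(c(0, 2), c(.5, .5), c(.5, .5)), "binary")
  expect_error(deviance_contrib(1, 0.5, 0.5, clip_eps = 0.7), "clip_eps")
})

test_that("one-sided p-values follow the normal tail and its degenerate conventions", {
  expect_equal(one_sided_pvalue(0, 1), 0.5)
  expect_equal(one_sided_pvalue(stats::qnorm(0.95), 1), 0.05)
  expect_equal(one_sided_pvalue(0, 0), 1)
  expect_equal(one_sided_pvalue(-2, 0), 1)
  expect_warning(p0 <- one_sided_pvalue(2, 0), "zero standard error")
  expect_equal(p0, 0)
  expect_error(one_sided_pvalue(1, -1), "nonnegative")
  # strictly decreasing in the importance for fixed positive std error
  imps <- seq(-2, 2, by = 0.25)
  ps <- one_sided_pvalue(imps, 0.7)
  expect_true(all(diff(ps) < 0))
})

test_that("FDR adjustment reproduces hand-computed step-up values", {
  expect_equal(adjust_fdr(0.37), 0.37)
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.2, 0.8)
  expect_true(all(adjust_fdr(p) >= p))
  expect_error(adjust_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("select_features thresholds raw or adjusted p-values", {
  res <- data.frame(p_value = c(0.001, 0.5, 0.09),
                    q_value = c(0.003, 0.5, 0.27))
  expect_identical(select_features(res, 0.1), c(1L, 3L))
  expect_identical(select_features(res, 0.1, use_fdr = TRUE), 1L)
  expect_identical(select_features(data.frame(p_value = rep(1, 4)), 0.05),
                   integer(0))
  expect_error(select_features(res, 1.5), "alpha")
})

test_that("cross-fit plans balance fold sizes and are reproducible", {
  plan <- make_crossfit_plan(10, 5, seed = 1)
  expect_equal(as.integer(table(plan$fold_assignment)), rep(2L, 5))
  plan2 <- make_crossfit_plan(11, 5, seed = 1)
  expect_equal(sort(as.integer(table(plan2$fold_assignment))),
               c(2L, 2L, 2L, 2L, 3L))
  expect_identical(make_crossfit_plan(37, 4, seed = 9)$fold_assignment,
                   make_crossfit_plan(37, 4, seed = 9)$fold_assignment)
  expect_error(make_crossfit_plan(10, 1), "K")
  expect_error(make_crossfit_plan(3, 5), "K")
})

test_that("a predictor that ignores the permuted feature gets exactly zero importance", {
  pred <- oracle_predictor(function(X) 2 * X[, 1]) # ignores feature 2
  set.seed(3)
  X <- matrix(rnorm(60), 30, 2)
  y <- 2 * X[, 1] + rnorm(30)
  res <- importance_single_split(pred, X, y, features = 2, seed = 7)
  expect_identical(res$importance, 0)
  expect_identical(res$variance, 0)
  expect_identical(res$p_value, 1)
})

test_that("split importance recovers the linear closed form 2 beta^2 Var(X)", {
  # oracle mu(X) = 2 X1, X1 ~ N(0,1), noiseless outcome:
  # population importance = 2 * 2^2 * 1 = 8
  pred <- oracle_predictor(function(X) 2 * X[, 1])
  set.seed(11)
  X <- matrix(rnorm(2e4 * 2), ncol = 2)
  y <- 2 * X[, 1]
  res <- importance_single_split(pred, X, y, features = 1, n_perm = 5,
                                 seed = 13)
  expect_equal(res$importance, 8, tolerance = 0.05)
  expect_true(res$p_value < 1e-6)
})

test_that("plug-in permutation score with the true mean has expectation (N-1)/N * M_j", {
  mu_fn <- function(x1, x2) x1 + x1 * x2
  m1 <- enumerate_m_twopoint(function(a, b) a + a * b, j = 1)
  expect_equal(m1, 4) # analytic cross-check of the enumeration oracle
  for (N in c(5, 50)) {
    set.seed(100 + N)
    draws <- mc_perm_score_feature1(30000, N, mu_fn)
    mc_se <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - (N - 1) / N * m1), 4 * mc_se + 1e-9)
  }
})

test_that("reported estimates satisfy the mean and variance identities exactly", {
  set.seed(21)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- X[, 1] + rnorm(40)
  plan <- make_crossfit_plan(40, 4, seed = 2)
  res <- importance_crossfit(lm_backend, X, y, plan, seed = 5)
  D <- attr(res, "contributions")
  expect_equal(res$importance, unname(colMeans(D)), tolerance = 1e-12)
  expect_equal(res$variance * nrow(D),
               unname(colMeans(sweep(D, 2, colMeans(D))^2)),
               tolerance = 1e-12)
  expect_true(all(res$n_eval == 40))
})

test_that("cross-fitted importance converges to the linear closed form", {
  set.seed(31)
  dat <- make_linear_data(4000, p = 4, beta1 = 1)
  plan <- make_crossfit_plan(4000, 5, seed = 3)
  res <- importance_crossfit(lm_backend, dat$X, dat$y, plan,
                             n_perm = 5, seed = 4)
  # M_1 = 2 * beta1^2 * Var(X_1) = 2
  expect_equal(res$importance[1], 2, tolerance = 0.15)
  expect_true(res$p_value[1] < 1e-8)
  # null features: neither systematically positive nor significant
  expect_true(all(res$p_value[2:4] > 0.01))
})

test_that("cross-fitting covers every sample exactly once and is seed-stable", {
  set.seed(41)
  X <- matrix(rnorm(30 * 3), 30, 3)
  y <- rnorm(30)
  plan <- make_crossfit_plan(30, 3, seed = 8)
  r1 <- importance_crossfit(lm_backend, X, y, plan, seed = 9)
  r2 <- importance_crossfit(lm_backend, X, y, plan, seed = 9)
  expect_identical(r1$importance, r2$importance)
  expect_false(anyNA(attr(r1, "contributions")))
})

test_that("feature groups are tested jointly and named by group", {
  set.seed(51)
  n <- 200
  g <- sample(0:1, n, replace = TRUE)
  X <- cbind(d1 = as.numeric(g == 0), d2 = as.numeric(g == 1),
             z = rnorm(n))
  y <- 3 * X[, "d1"] + rnorm(n, sd = 0.3)
  pred <- oracle_predictor(function(M) 3 * M[, "d1"])
  res <- importance_single_split(pred, X, y, seed = 6,
                                 feature_groups = list(grp = c("d1", "d2")))
  expect_identical(res$feature, c("grp", "z"))
  expect_true(res$p_value[res$feature == "grp"] < 1e-4)
  expect_identical(res$importance[res$feature == "z"], 0)
})

test_that("named seed substreams are deterministic and distinct", {
  expect_identical(derive_seed(42, "fold"), derive_seed(42, "fold"))
  expect_false(derive_seed(42, "fold") == derive_seed(42, "perm"))
  expect_false(derive_seed(42, "fold") == derive_seed(43, "fold"))
  s <- vapply(1:500, function(i) derive_seed(7, paste0("rep", i)),
              integer(1))
  expect_true(all(s >= 0 & s < 2^31))
  expect_gt(length(unique(s)), 495) # collisions essentially absent
})
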