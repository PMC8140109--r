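# Learner backends: predictor contract, determinism, fit quality, and the
# per-tree out-of-bag importance baseline.

make_toy <- function(n = 120, p = 4, binary = FALSE, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("X", 1:p)))
  if (binary) {
    y <- rbinom(n, 1, plogis(2 * X[, 1]))
  } else {
    y <- X[, 1] + rnorm(n, sd = 0.5)
  }
  list(X = X, y = y)
}

test_that("all backends satisfy the predictor contract", {
  fits <- list(
    rf = function(X, y, ot) fit_rf(X, y, n_trees = 60, outcome_type = ot,
                                   seed = 2),
    dnn = function(X, y, ot) fit_bagged_dnn(
      X, y, dnn_config(bagging_size = 3, epochs = 20,
                       hidden_nodes = c(8L, 8L), n_hidden_layers = 2L),
      outcome_type = ot, seed = 2),
    svm = function(X, y, ot) fit_svm(X, y, cost_grid = c(1, 8),
                                     gamma_grid = c(0.05, 0.5),
                                     outcome_type = ot, seed = 2)
  )
  for (binary in c(FALSE, TRUE)) {
    dat <- make_toy(binary = binary, seed = if (binary) 8 else 3)
    ot <- if (binary) "binary" else "continuous"
    for (nm in names(fits)) {
      pred <- fits[[nm]](dat$X, dat$y, ot)
      expect_s3_class(pred, "permfit_predictor")
      out <- predict(pred, dat$X)
      expect_length(out, nrow(dat$X))
      expect_true(all(is.finite(out)), info = paste(nm, ot))
      if (binary) {
        expect_true(all(out >= 0 & out <= 1), info = paste(nm, ot))
      }
    }
  }
})

test_that("rf and svm are deterministic given a seed; dnn is reproducible", {
  dat <- make_toy(seed = 4)
  Xn <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, colnames(dat$X)))
  f1 <- fit_rf(dat$X, dat$y, n_trees = 50, seed = 7)
  f2 <- fit_rf(dat$X, dat$y, n_trees = 50, seed = 7)
  expect_identical(predict(f1, Xn), predict(f2, Xn))
  s1 <- fit_svm(dat$X, dat$y, cost_grid = 2, gamma_grid = 0.25, seed = 7)
  s2 <- fit_svm(dat$X, dat$y, cost_grid = 2, gamma_grid = 0.25, seed = 7)
  expect_identical(predict(s1, Xn), predict(s2, Xn))
  cfg <- dnn_config(bagging_size = 2, epochs = 10,
                    hidden_nodes = c(8L, 8L), n_hidden_layers = 2L)
  d1 <- fit_bagged_dnn(dat$X, dat$y, cfg, seed = 7)
  d2 <- fit_bagged_dnn(dat$X, dat$y, cfg, seed = 7)
  expect_identical(predict(d1, Xn), predict(d2, Xn))
})

test_that("rf nails a deterministic step function of one feature", {
  set.seed(5)
  X <- matrix(rnorm(200 * 3), 200, 3)
  y <- as.numeric(X[, 1] > 0) * 2 - 1
  pred <- fit_rf(X, y, n_trees = 100, seed = 6)
  expect_lt(mean((predict(pred, X) - y)^2), 0.05)
})

test_that("rf default tree count is 1000", {
  expect_identical(formals(fit_rf)$n_trees, 1000L)
  expect_identical(formals(vanilla_rf_importance)$n_trees, 1000L)
})

test_that("rf refuses a single-class binary outcome", {
  dat <- make_toy(seed = 6)
  expect_error(fit_rf(dat$X, rep(1, nrow(dat$X)), outcome_type = "binary"),
               "single class")
})

test_that("bagged dnn fits a constant outcome with a constant prediction", {
  set.seed(7)
  X <- matrix(rnorm(200), 50, 4)
  y <- rep(3.7, 50)
  pred <- fit_bagged_dnn(X, y, dnn_config(bagging_size = 2, epochs = 15,
                                          hidden_nodes = c(8L, 8L),
                                          n_hidden_layers = 2L), seed = 1)
  expect_equal(predict(pred, X), rep(3.7, 50), tolerance = 0.05)
})

test_that("bagged dnn defaults mirror the reference configuration", {
  cfg <- dnn_config()
  expect_identical(cfg$bagging_size, 100L)
  expect_identical(cfg$batch_size, 50L)
  expect_identical(cfg$hidden_nodes, c(50L, 40L, 30L, 20L))
  expect_identical(cfg$lambda, 1e-4)
  expect_error(dnn_config(n_hidden_layers = 3), "length")
  expect_error(dnn_config(keep_fraction = 0), "keep_fraction")
})

test_that("keep_fraction = 1 reproduces the unfiltered bag mean", {
  dat <- make_toy(seed = 9)
  cfg <- dnn_config(bagging_size = 4, epochs = 15, keep_fraction = 1,
                    hidden_nodes = c(8L, 8L), n_hidden_layers = 2L)
  pred <- fit_bagged_dnn(dat$X, dat$y, cfg, seed = 3)
  expect_identical(sort(pred$model$kept), 1:4)
  Xn <- dat$X[1:7, ]
  member_mean <- rowMeans(vapply(pred$model$members, function(m) {
    as.numeric(permfit:::cpp_dnn_predict(m, pred$model$standardize(Xn),
                                         FALSE))
  }, numeric(7)))
  expect_equal(predict(pred, Xn),
               member_mean * pred$model$y_scale + pred$model$y_center,
               tolerance = 1e-12)
})

test_that("dnn learns a pure interaction better than the constant predictor", {
  set.seed(10)
  n <- 600
  X <- matrix(rnorm(n * 4), n, 4)
  y <- X[, 1] * X[, 2] + rnorm(n, sd = 0.3)
  test_X <- matrix(rnorm(2000 * 4), 2000, 4)
  test_y <- test_X[, 1] * test_X[, 2] + rnorm(2000, sd = 0.3)
  pred <- fit_bagged_dnn(X, y, dnn_config(bagging_size = 6, epochs = 60,
                                          hidden_nodes = c(16L, 16L),
                                          n_hidden_layers = 2L), seed = 2)
  mspe <- mean((test_y - predict(pred, test_X))^2)
  expect_lt(mspe, var(test_y))
})

test_that("svm separates separable classes and defaults to fivefold search", {
  set.seed(11)
  n <- 80
  X <- rbind(matrix(rnorm(n * 2, -2), n, 2), matrix(rnorm(n * 2, 2), n, 2))
  y <- rep(c(0, 1), each = n)
  colnames(X) <- c("a", "b")
  pred <- fit_svm(X, y, cost_grid = c(1, 10), gamma_grid = c(0.1, 1),
                  seed = 3)
  expect_equal(mean((predict(pred, X) >= 0.5) == (y == 1)), 1)
  expect_identical(formals(fit_svm)$cv_folds, 5L)
})

test_that("svm regression beats the constant predictor on a radial target", {
  set.seed(12)
  n <- 250
  X <- matrix(rnorm(n * 3), n, 3)
  y <- exp(-rowSums(X^2)) + rnorm(n, sd = 0.05)
  test_X <- matrix(rnorm(1000 * 3), 1000, 3)
  test_y <- exp(-rowSums(test_X^2)) + rnorm(1000, sd = 0.05)
  pred <- fit_svm(X, y, seed = 4)
  expect_lt(mean((test_y - predict(pred, test_X))^2), var(test_y))
  expect_true(all(c("cost", "gamma") %in% names(pred$model)))
})

test_that("vanilla importance is centered at zero under the null and ranks signals first", {
  set.seed(13)
  X <- matrix(rnorm(150 * 6), 150, 6)
  y_null <- rnorm(150)
  tab <- vanilla_rf_importance(X, y_null, n_trees = 150, seed = 5)
  expect_equal(nrow(tab), 6)
  # importance scores straddle zero: |mean over features| stays within
  # a couple of cross-feature standard deviations of zero
  expect_lt(abs(mean(tab$importance)),
            2 * sd(tab$importance) + 1e-12)
  # single strong linear predictor among noise features ranks first
  y_sig <- 2 * X[, 3] + rnorm(150, sd = 0.5)
  tab2 <- vanilla_rf_importance(X, y_sig, n_trees = 150, seed = 6)
  expect_equal(which.max(tab2$importance), 3)
  expect_lt(tab2$p_value[3], 1e-4)
})
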