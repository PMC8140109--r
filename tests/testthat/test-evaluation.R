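# Replication harness: detection rates, prediction metrics, refit
# comparison, scenario determinism.

test_that("detection rates agree with a brute-force count", {
  set.seed(1)
  p_matrix <- matrix(runif(20 * 10), 20, 10)
  causal <- c(1, 4)
  S0 <- c(2, 3, 5)
  S1 <- 6:10
  r <- detection_rates(p_matrix, 0.2, causal, S0, S1)
  # independent brute force: explicit loops over the matrix
  brute <- function(cols) {
    hits <- 0; tot <- 0
    for (i in seq_len(nrow(p_matrix))) for (j in cols) {
      tot <- tot + 1
      if (p_matrix[i, j] < 0.2) hits <- hits + 1
    }
    100 * hits / tot
  }
  expect_equal(unname(r$detection), vapply(causal, brute, numeric(1)))
  expect_equal(r$s0_rejection, brute(S0))
  expect_equal(r$s1_rejection, brute(S1))
  expect_equal(mean(r$s1_by_feature), r$s1_rejection)
})

test_that("detection rates handle edge cases and validate the partition", {
  p1 <- matrix(1, 5, 4)
  r <- detection_rates(p1, 0.05, 1, 2, 3:4)
  expect_equal(unname(r$detection), 0)
  expect_equal(r$s0_rejection, 0)
  expect_error(detection_rates(p1, 0.05, 1, 2, 3), "partition")
  # uniform p-values reject at about the nominal rate
  set.seed(2)
  pu <- matrix(runif(500 * 20), 500, 20)
  r2 <- detection_rates(pu, 0.05, 1, 2:10, 11:20)
  expect_equal(r2$s1_rejection, 5, tolerance = 0.75)
})

test_that("prediction metrics match their definitions", {
  y <- c(0.5, 1.2, -0.3)
  expect_equal(prediction_metrics(y, y, "continuous"),
               c(mspe = 0, cor = 1))
  set.seed(3)
  ys <- rnorm(5000)
  expect_equal(unname(prediction_metrics(ys, rep(0, 5000),
                                         "continuous")["mspe"]),
               mean(ys^2))
  expect_equal(prediction_metrics(c(0, 1), c(0.2, 0.8), "binary"),
               c(accuracy = 1, auc = 1))
  # AUC equals the Mann-Whitney statistic on unique predictions
  yb <- c(0, 0, 1, 1, 0, 1)
  pr <- c(0.1, 0.4, 0.35, 0.8, 0.2, 0.7)
  u <- 0
  for (i in which(yb == 1)) for (j in which(yb == 0)) {
    u <- u + (pr[i] > pr[j])
  }
  expect_equal(unname(prediction_metrics(yb, pr, "binary")["auc"]),
               u / (sum(yb == 1) * sum(yb == 0)))
  expect_warning(m <- prediction_metrics(c(1, 1), c(0.6, 0.7), "binary"),
                 "one outcome class")
  expect_true(is.na(m["auc"]))
})

test_that("refit comparison evaluates full and selected models", {
  set.seed(4)
  dat <- make_linear_data(150, p = 4, beta1 = 2)
  test <- make_linear_data(400, p = 4, beta1 = 2)
  cmp <- refit_with_selected(lm_backend, dat$X, dat$y, 1L,
                             test$X, test$y)
  expect_false(cmp$fallback)
  # oracle selection keeps the causal feature: no worse than full fit
  expect_lte(cmp$selected["mspe"], cmp$full["mspe"] * 1.05)
  # empty selection falls back to the full model, flagged
  cmp0 <- refit_with_selected(lm_backend, dat$X, dat$y, integer(0),
                              test$X, test$y)
  expect_true(cmp0$fallback)
  expect_identical(cmp0$selected, cmp0$full)
  # selecting everything is the same specification up to refit noise
  cmp_all <- refit_with_selected(lm_backend, dat$X, dat$y, 1:4,
                                 test$X, test$y)
  expect_equal(cmp_all$selected["mspe"], cmp_all$full["mspe"],
               tolerance = 1e-10)
})

test_that("scenario replication is deterministic and aggregates correctly", {
  scen <- list(rho = 0, N = 120, p = 20, p0 = 2,
               outcome_type = "continuous")
  args <- list(scenario = scen, method = "permfit", backend = "rf",
               n_reps = 3, master_seed = 77,
               backend_args = list(n_trees = 60))
  r1 <- do.call(replicate_scenario, args)
  r2 <- do.call(replicate_scenario, args)
  expect_identical(r1$p_matrix, r2$p_matrix)
  expect_equal(dim(r1$p_matrix), c(3, 20))
  expect_equal(r1$n_replicates, 3)
  expect_identical(r1$causal, c(1L, 3L, 5L, 7L, 9L))
  # rates recompute from the stored p-value matrix
  expect_equal(r1$rates$s1_rejection,
               100 * mean(r1$p_matrix[, r1$S1] < 0.05))
  tab <- scenario_table(r1)
  expect_equal(tab$S1, r1$rates$s1_rejection)
  expect_equal(nrow(tab), 1)
})

test_that("refit metrics are attached when requested", {
  scen <- list(rho = 0, N = 120, p = 20, p0 = 2,
               outcome_type = "continuous")
  r <- replicate_scenario(scen, method = "permfit", backend = "rf",
                          n_reps = 2, master_seed = 5, refit = TRUE,
                          test_n = 300,
                          backend_args = list(n_trees = 60))
  expect_true(!is.null(r$metrics_full))
  expect_named(r$metrics_full$mean, c("mspe", "cor"))
  expect_true(all(is.finite(r$metrics_full$mean)))
  expect_true(all(is.finite(r$metrics_selected$mean)))
})
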