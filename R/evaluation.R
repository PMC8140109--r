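# Replication harness and metrics: per-feature detection rates across
# simulation replicates, prediction-error comparison before/after feature
# selection, and the scenario loop tying them together.

#' Detection and null-rejection rates from a replicate p-value matrix
#'
#' @param p_matrix numeric matrix of p-values, replicates in rows and
#'   features in columns.
#' @param alpha p-value cutoff.
#' @param causal integer indices of the causal features.
#' @param S0 indices of null features correlated with causal ones.
#' @param S1 indices of independent null features.
#' @return a list with `detection` (percentage per causal feature across
#'   replicates), pooled percentages `s0_rejection` and `s1_rejection`
#'   over all (replicate, feature) pairs, their feature-averaged
#'   counterparts `s0_by_feature` / `s1_by_feature`, `alpha` and
#'   `n_replicates`.
#' @export
detection_rates <- function(p_matrix, alpha = 0.05, causal, S0, S1) {
  if (!is.matrix(p_matrix)) p_matrix <- as.matrix(p_matrix)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)",
                                     call. = FALSE)
  p <- ncol(p_matrix)
  idx <- c(causal, S0, S1)
  if (length(idx) != p || !setequal(idx, seq_len(p))) {
    stop("`causal`, `S0`, `S1` must partition the feature columns",
         call. = FALSE)
  }
  nm <- colnames(p_matrix)
  if (is.null(nm)) nm <- paste0("X", seq_len(p))
  rej <- p_matrix < alpha
  named_rates <- function(cols) {
    stats::setNames(100 * colMeans(rej[, cols, drop = FALSE]), nm[cols])
  }
  list(
    detection = named_rates(causal),
    s0_rejection = 100 * mean(rej[, S0, drop = FALSE]),
    s1_rejection = 100 * mean(rej[, S1, drop = FALSE]),
    s0_by_feature = named_rates(S0),
    s1_by_feature = named_rates(S1),
    alpha = alpha,
    n_replicates = nrow(p_matrix)
  )
}

#' Prediction-performance metrics
#'
#' Continuous outcomes: mean squared prediction error and Pearson
#' correlation.  Binary outcomes: accuracy at the 0.5 threshold and area
#' under the ROC curve computed from the rank (Mann-Whitney) statistic
#' with mid-ranks for ties.
#'
#' @param y_true observed outcomes.
#' @param y_pred predictions (probabilities for binary outcomes).
#' @param outcome_type `"continuous"` or `"binary"`.
#' @return a named numeric vector: `mspe` and `cor`, or `accuracy` and
#'   `auc`.  AUC is `NA` (with a warning) when only one class is present.
#' @export
prediction_metrics <- function(y_true, y_pred,
                               outcome_type = c("continuous", "binary")) {
  outcome_type <- match.arg(outcome_type)
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have the same length", call. = FALSE)
  }
  if (outcome_type == "continuous") {
    # constant predictions have no defined correlation; report NA quietly
    r <- if (stats::sd(y_pred) == 0 || stats::sd(y_true) == 0) NA_real_
         else stats::cor(y_true, y_pred)
    c(mspe = mean((y_true - y_pred)^2), cor = r)
  } else {
    n1 <- sum(y_true == 1)
    n0 <- sum(y_true == 0)
    auc <- if (n1 == 0L || n0 == 0L) {
      warning("AUC undefined: only one outcome class present")
      NA_real_
    } else {
      r <- rank(y_pred)
      (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
    c(accuracy = mean((y_pred >= 0.5) == (y_true == 1)), auc = auc)
  }
}

#' Refit a backend on selected features and compare prediction metrics
#'
#' Fits the learner twice -- on the full feature set and on the selected
#' subset -- and evaluates both on held-out test data.  An empty selection
#' falls back to the full model (flagged), so aggregate metrics are always
#' defined.
#'
#' @param fit fitting function `(X, y) -> permfit_predictor`.
#' @param X_train,y_train training data.
#' @param selected integer indices of the selected feature columns.
#' @param X_test,y_test held-out evaluation data.
#' @return a list with `full` and `selected` metric vectors (see
#'   [prediction_metrics()]), `fallback` flag and the `selected` indices
#'   used.
#' @export
refit_with_selected <- function(fit, X_train, y_train, selected,
                                X_test, y_test) {
  X_train <- as_feature_matrix(X_train, "X_train")
  X_test <- as_feature_matrix(X_test, "X_test")
  full_model <- fit(X_train, y_train)
  outcome_type <- full_model$outcome_type
  m_full <- prediction_metrics(y_test, predict(full_model, X_test),
                               outcome_type)
  fallback <- length(selected) == 0L
  m_sel <- if (fallback) {
    m_full
  } else {
    sub_model <- fit(X_train[, selected, drop = FALSE], y_train)
    prediction_metrics(y_test,
                       predict(sub_model, X_test[, selected, drop = FALSE]),
                       outcome_type)
  }
  list(full = m_full, selected = m_sel, fallback = fallback,
       selected_features = selected)
}

#' Replicate a simulation scenario and aggregate detection and error rates
#'
#' For each replicate: generate a fresh dataset from the block-correlated
#' Gaussian design, run the chosen importance method, record the p-value
#' vector, and optionally refit on the selected features and score both
#' models on an independent test set.  Aggregates per-causal-feature
#' detection rates, pooled null rejection rates over `S0` and `S1`, and
#' (when refitting) mean and standard deviation of the prediction metrics.
#'
#' @param scenario a list or one-row data frame with `rho`, `N`, `p`,
#'   `p0` and `outcome_type` (see [scenario_grid()]).
#' @param method `"permfit"` or `"vanilla_rf"` (the per-tree out-of-bag
#'   baseline, fitted on the full sample).
#' @param backend learner backend for `method = "permfit"`.
#' @param n_reps number of replicates.
#' @param master_seed seed from which each replicate's data, fits and
#'   permutations derive.
#' @param alpha_detect p-value cutoff for detection/rejection rates.
#' @param alpha_select cutoff for the refit selection step.
#' @param protocol `"split"` or `"crossfit"` for the permutation test.
#' @param train_frac,K,n_perm passed to [permfit()].
#' @param refit if `TRUE`, refit full/selected models per replicate and
#'   score them on a fresh test set of `test_n` samples.
#' @param test_n test-set size for refit metrics.
#' @param backend_args extra backend arguments (for `"vanilla_rf"`,
#'   `n_trees`/`mtry`/`nodesize`).
#' @return an object of class `scenario_result`: detection and rejection
#'   rates, the replicate-by-feature p-value matrix, refit metric
#'   summaries (if any), the effective replicate count and the scenario
#'   description.
#' @export
replicate_scenario <- function(scenario, method = c("permfit", "vanilla_rf"),
                               backend = "rf", n_reps = 100L,
                               master_seed = 1L, alpha_detect = 0.05,
                               alpha_select = 0.1,
                               protocol = c("split", "crossfit"),
                               train_frac = 0.8, K = 5L, n_perm = 1L,
                               refit = FALSE, test_n = 10000L,
                               backend_args = list()) {
  method <- match.arg(method)
  protocol <- match.arg(protocol)
  scenario <- as.list(scenario)
  stopifnot(n_reps >= 1L)
  spec <- block_cov_spec(p0 = scenario$p0,
                         n_blocks = scenario$p / scenario$p0,
                         rho = scenario$rho)
  outcome_type <- match.arg(scenario$outcome_type,
                            c("continuous", "binary"))
  gen <- if (outcome_type == "continuous") generate_continuous
         else generate_binary
  scen_id <- if (!is.null(scenario$scenario)) scenario$scenario else
    sprintf("rho%s_N%d_p%d_%s", scenario$rho, scenario$N, scenario$p,
            outcome_type)

  p_rows <- list()
  metrics_full <- list()
  metrics_sel <- list()
  n_selected <- integer(0)
  fallbacks <- 0L
  failures <- 0L

  for (r in seq_len(n_reps)) {
    rep_seed <- derive_seed(master_seed, sprintf("%s_rep%d", scen_id, r))
    out <- tryCatch({
      sim <- gen(scenario$N, spec, seed = rep_seed)
      tab <- if (method == "vanilla_rf") {
        do.call(vanilla_rf_importance,
                c(list(X = sim$X, y = sim$y, outcome_type = outcome_type,
                       seed = derive_seed(rep_seed, "vrf")),
                  backend_args))
      } else {
        permfit(sim$X, sim$y, backend = backend,
                outcome_type = outcome_type, method = protocol,
                train_frac = train_frac, K = K, n_perm = n_perm,
                alpha = alpha_detect, seed = derive_seed(rep_seed, "pf"),
                backend_args = backend_args)$importance
      }
      rep_out <- list(p = tab$p_value)
      if (refit) {
        sel <- which(tab$p_value < alpha_select)
        test <- gen(test_n, spec,
                    seed = derive_seed(rep_seed, "test"))
        fit_fun <- backend_fit_fun(
          if (method == "vanilla_rf") "rf" else backend,
          outcome_type, backend_args)
        cmp <- with_seed(derive_seed(rep_seed, "refit"),
          refit_with_selected(fit_fun, sim$X, sim$y, sel, test$X, test$y))
        rep_out$cmp <- cmp
      }
      rep_out
    }, error = function(e) {
      warning(sprintf("replicate %d failed and was excluded: %s",
                      r, conditionMessage(e)))
      NULL
    })
    if (is.null(out)) { failures <- failures + 1L; next }
    p_rows[[length(p_rows) + 1L]] <- out$p
    if (refit) {
      metrics_full[[length(metrics_full) + 1L]] <- out$cmp$full
      metrics_sel[[length(metrics_sel) + 1L]] <- out$cmp$selected
      n_selected <- c(n_selected, length(out$cmp$selected_features))
      fallbacks <- fallbacks + out$cmp$fallback
    }
  }
  if (length(p_rows) == 0L) {
    stop("every replicate failed", call. = FALSE)
  }
  p_matrix <- do.call(rbind, p_rows)
  colnames(p_matrix) <- paste0("X", seq_len(ncol(p_matrix)))
  sets <- signal_index_sets(spec)
  rates <- detection_rates(p_matrix, alpha_detect,
                           sets$causal, sets$S0, sets$S1)

  summarize <- function(lst) {
    if (length(lst) == 0L) return(NULL)
    M <- do.call(rbind, lst)
    list(mean = colMeans(M, na.rm = TRUE),
         sd = if (nrow(M) > 1L) apply(M, 2L, stats::sd, na.rm = TRUE)
              else stats::setNames(rep(NA_real_, ncol(M)), colnames(M)))
  }

  structure(
    list(scenario = scen_id, method = method,
         backend = if (method == "vanilla_rf") "rf" else
           if (is.function(backend)) "custom" else backend,
         rho = scenario$rho, N = scenario$N, p = scenario$p,
         outcome_type = outcome_type,
         rates = rates, p_matrix = p_matrix,
         causal = sets$causal, S0 = sets$S0, S1 = sets$S1,
         metrics_full = summarize(metrics_full),
         metrics_selected = summarize(metrics_sel),
         mean_n_selected = if (refit) mean(n_selected) else NA_real_,
         fallbacks = fallbacks,
         n_replicates = nrow(p_matrix), n_failed = failures,
         alpha_detect = alpha_detect, alpha_select = alpha_select,
         master_seed = master_seed),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario %s: %s%s, %d replicate(s)%s\n",
              x$scenario, x$method,
              if (x$method == "permfit") paste0("-", x$backend) else "",
              x$n_replicates,
              if (x$n_failed > 0) sprintf(" (%d failed)", x$n_failed)
              else ""))
  cat(sprintf("  detection %% at alpha=%g: %s\n", x$alpha_detect,
              paste(sprintf("%s=%.0f", names(x$rates$detection),
                            x$rates$detection), collapse = " ")))
  cat(sprintf("  null rejection %%: S0=%.1f S1=%.1f\n",
              x$rates$s0_rejection, x$rates$s1_rejection))
  if (!is.null(x$metrics_full)) {
    cat("  full model:     ",
        paste(sprintf("%s=%.4f", names(x$metrics_full$mean),
                      x$metrics_full$mean), collapse = " "), "\n")
    cat("  selected model: ",
        paste(sprintf("%s=%.4f", names(x$metrics_selected$mean),
                      x$metrics_selected$mean), collapse = " "), "\n")
  }
  invisible(x)
}

#' Tabulate one or more scenario results
#'
#' @param results a `scenario_result` or list of them.
#' @return a data frame, one row per scenario x method, with detection
#'   percentages for the causal features and pooled S0/S1 rejection rates.
#' @export
scenario_table <- function(results) {
  if (inherits(results, "scenario_result")) results <- list(results)
  do.call(rbind, lapply(results, function(x) {
    det <- x$rates$detection
    out <- data.frame(
      scenario = x$scenario,
      method = if (x$method == "permfit")
        paste0("permfit_", x$backend) else x$method,
      n_replicates = x$n_replicates,
      stringsAsFactors = FALSE)
    for (i in seq_along(det)) out[[names(det)[i]]] <- det[[i]]
    out$S0 <- x$rates$s0_rejection
    out$S1 <- x$rates$s1_rejection
    if (!is.null(x$metrics_full)) {
      for (m in names(x$metrics_full$mean)) {
        out[[paste0("full_", m)]] <- x$metrics_full$mean[[m]]
        out[[paste0("selected_", m)]] <- x$metrics_selected$mean[[m]]
      }
    }
    out
  }))
}
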