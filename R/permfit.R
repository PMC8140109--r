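#' Permutation feature importance test on a dataset
#'
#' End-to-end driver: fits the chosen learner backend, then estimates and
#' tests each feature's importance by permutation, either on a single
#' train/validation split (the protocol used for simulation studies) or
#' with K-fold cross-fitting (the protocol for data analyses, where every
#' sample contributes to the importance estimate).
#'
#' A single master `seed` fans out to named substreams -- train/validation
#' split or fold assignment, backend fitting, and per-feature permutations
#' -- so each stage is reproducible in isolation via [derive_seed()].
#'
#' @param X feature matrix or all-numeric data frame (no missing values;
#'   categorical features must arrive numerically encoded).
#' @param y outcome vector; 0/1 vectors are treated as binary unless
#'   `outcome_type` says otherwise.
#' @param backend `"rf"`, `"dnn"`, `"svm"`, or a function `(X, y)`
#'   returning a `permfit_predictor`.
#' @param outcome_type `"continuous"`, `"binary"`, or `NULL` to infer.
#' @param method `"split"` (single train/validation split, default
#'   80/20) or `"crossfit"` (K folds).
#' @param train_frac training fraction for `method = "split"`.
#' @param K fold count for `method = "crossfit"`.
#' @param n_perm permutations per feature; contributions are averaged over
#'   them.  Default 1 (a single permuted copy).
#' @param alpha significance level used for the `selected` column.
#' @param use_fdr select on Benjamini-Hochberg q-values instead of raw
#'   p-values.
#' @param feature_groups optional named list of column blocks permuted
#'   jointly.
#' @param seed master seed.
#' @param backend_args named list of extra arguments for the backend
#'   (e.g. `list(n_trees = 500)` or `list(config = dnn_config(...))`).
#' @param clip_eps probability clipping bound for binary deviance.
#' @return an object of class `permfit_result`: list with `importance`
#'   (data frame with columns `feature`, `importance`, `variance`,
#'   `std_error`, `z`, `p_value`, `q_value`, `selected`, `n_eval`) and
#'   `metadata` (seed, protocol, backend, thresholds, RNG kind).
#' @export
#' @examples
#' sim <- generate_continuous(300, block_cov_spec(p0 = 2, n_blocks = 5),
#'                            seed = 1)
#' fit <- permfit(sim$X, sim$y, backend = "rf", method = "split",
#'                backend_args = list(n_trees = 100), seed = 1)
#' head(fit$importance)
permfit <- function(X, y, backend = "rf", outcome_type = NULL,
                    method = c("split", "crossfit"), train_frac = 0.8,
                    K = 5L, n_perm = 1L, alpha = 0.05, use_fdr = FALSE,
                    feature_groups = NULL, seed = NULL,
                    backend_args = list(), clip_eps = 1e-6) {
  method <- match.arg(method)
  X <- as_feature_matrix(X)
  n <- nrow(X)
  outcome_type <- check_outcome(y, outcome_type, n)
  fit_fun <- backend_fit_fun(backend, outcome_type, backend_args)

  if (method == "split") {
    if (train_frac <= 0 || train_frac >= 1) {
      stop("`train_frac` must lie in (0, 1)", call. = FALSE)
    }
    n_train <- floor(train_frac * n)
    if (n_train < 1L || n_train >= n) {
      stop("split leaves an empty training or validation set", call. = FALSE)
    }
    train <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, "split"),
                       sample.int(n, n_train))
    valid <- setdiff(seq_len(n), train)
    predictor <- with_seed(
      if (is.null(seed)) NULL else derive_seed(seed, "fit"),
      fit_fun(X[train, , drop = FALSE], y[train]))
    res <- importance_single_split(
      predictor, X[valid, , drop = FALSE], y[valid],
      n_perm = n_perm,
      seed = if (is.null(seed)) NULL else derive_seed(seed, "perm"),
      feature_groups = feature_groups, clip_eps = clip_eps)
  } else {
    plan <- make_crossfit_plan(
      n, K, if (is.null(seed)) NULL else derive_seed(seed, "folds"))
    res <- importance_crossfit(fit_fun, X, y, plan, n_perm = n_perm,
                               seed = seed, feature_groups = feature_groups,
                               clip_eps = clip_eps)
  }

  res$q_value <- adjust_fdr(res$p_value)
  crit <- if (use_fdr) res$q_value else res$p_value
  res$selected <- crit < alpha
  res <- res[, c("feature", "importance", "variance", "std_error", "z",
                 "p_value", "q_value", "selected", "n_eval")]

  metadata <- list(
    backend = if (is.function(backend)) "custom" else backend,
    outcome_type = outcome_type,
    method = method,
    train_frac = if (method == "split") train_frac else NULL,
    K = if (method == "crossfit") as.integer(K) else NULL,
    n_perm = as.integer(n_perm),
    alpha = alpha,
    fdr_procedure = "Benjamini-Hochberg",
    use_fdr = use_fdr,
    clip_eps = clip_eps,
    seed = seed,
    rng_kind = RNGkind()[1L],
    n_samples = n,
    n_features = ncol(X),
    package_version = as.character(utils::packageVersion("permfit"))
  )
  structure(list(importance = res, metadata = metadata),
            class = "permfit_result")
}

#' @export
print.permfit_result <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("Permutation feature importance test (%s backend, %s)\n",
              md$backend,
              if (md$method == "split")
                sprintf("%.0f/%.0f split", 100 * md$train_frac,
                        100 * (1 - md$train_frac))
              else sprintf("%d-fold cross-fitting", md$K)))
  cat(sprintf("  %d samples, %d features, outcome: %s\n",
              md$n_samples, md$n_features, md$outcome_type))
  sel <- x$importance[x$importance$selected, , drop = FALSE]
  cat(sprintf("  %d feature(s) selected at alpha = %g (%s)\n",
              nrow(sel), md$alpha,
              if (md$use_fdr) "BH-adjusted" else "raw p"))
  if (nrow(sel) > 0L) {
    show <- sel[order(sel$p_value), c("feature", "importance", "std_error",
                                      "p_value", "q_value")]
    print(utils::head(show, 10L), row.names = FALSE, digits = 4L)
  }
  invisible(x)
}
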