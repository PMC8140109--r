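# Core estimator: feature permutation, per-sample loss contributions,
# split and cross-fitted importance estimates, one-sided normal inference.

#' Permute one feature column (or a block of columns) of a feature matrix
#'
#' Reorders the rows of the selected column(s) by a permutation drawn
#' without replacement, leaving every other column untouched.  When `j`
#' indexes several columns (e.g. a one-hot block encoding one original
#' feature) the whole block is reordered by the same permutation, so the
#' block moves as a unit.
#'
#' @param X numeric feature matrix (or all-numeric data frame).
#' @param j column index (or vector of indices for a block), or column
#'   name(s).
#' @param order integer permutation of `seq_len(nrow(X))`.  If `NULL`, a
#'   uniform random permutation is drawn (use `seed` for reproducibility).
#' @param seed optional seed used only when `order` is `NULL`.
#' @return a matrix equal to `X` except for the permuted column(s); `X`
#'   itself is not modified.
#' @export
#' @examples
#' X <- cbind(a = 1:3, b = c(10, 20, 30))
#' permute_column(X, "b", order = c(3, 1, 2))
permute_column <- function(X, j, order = NULL, seed = NULL) {
  X <- as_feature_matrix(X)
  if (is.character(j)) {
    idx <- match(j, colnames(X))
    if (anyNA(idx)) {
      stop("unknown feature name(s): ",
           paste(j[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    j <- idx
  }
  if (!is.numeric(j) || length(j) < 1L ||
      any(j < 1L) || any(j > ncol(X)) || any(j != as.integer(j))) {
    stop("`j` must index columns of `X` (1..", ncol(X), ")", call. = FALSE)
  }
  n <- nrow(X)
  if (is.null(order)) {
    order <- with_seed(seed, sample.int(n))
  }
  if (length(order) != n || !setequal(order, seq_len(n))) {
    stop("`order` must be a permutation of 1..", n, call. = FALSE)
  }
  X[, j] <- X[order, j, drop = FALSE]
  X
}

#' Per-sample squared-error loss contributions
#'
#' @param y numeric outcome vector.
#' @param pred numeric prediction vector of the same length.
#' @return `(y - pred)^2`, elementwise.
#' @export
loss_contrib_continuous <- function(y, pred) {
  if (length(y) != length(pred)) {
    stop("`y` and `pred` must have the same length", call. = FALSE)
  }
  (y - pred)^2
}

#' Per-sample binomial-deviance importance contributions
#'
#' For a binary outcome the importance contribution of a permuted
#' prediction is the increase in per-sample negative log-likelihood:
#' `y * log(p / p') + (1 - y) * log((1 - p) / (1 - p'))`, where `p` is the
#' probability predicted from the intact features and `p'` from the
#' permuted ones.  Probabilities are clipped into
#' `[clip_eps, 1 - clip_eps]` before any logarithm because backends can
#' emit exact 0/1 probabilities.
#'
#' @param y binary outcome vector (0/1).
#' @param prob_orig predicted probabilities from intact features.
#' @param prob_perm predicted probabilities from permuted features.
#' @param clip_eps clipping bound in `(0, 0.5)`; default `1e-6`.
#' @return numeric vector of per-sample contributions.
#' @export
#' @examples
#' deviance_contrib(1, 0.8, 0.5) # log(1.6)
deviance_contrib <- function(y, prob_orig, prob_perm, clip_eps = 1e-6) {
  if (!all(y %in% c(0, 1))) {
    stop("`y` must be binary (0/1)", call. = FALSE)
  }
  if (length(prob_orig) != length(y) || length(prob_perm) != length(y)) {
    stop("probability vectors must match `y` in length", call. = FALSE)
  }
  if (any(prob_orig < 0 | prob_orig > 1) || any(prob_perm < 0 | prob_perm > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(clip_eps) || clip_eps <= 0 || clip_eps >= 0.5) {
    stop("`clip_eps` must lie in (0, 0.5)", call. = FALSE)
  }
  p <- pmin(pmax(prob_orig, clip_eps), 1 - clip_eps)
  q <- pmin(pmax(prob_perm, clip_eps), 1 - clip_eps)
  y * log(p / q) + (1 - y) * log((1 - p) / (1 - q))
}

#' One-sided p-value for a positive importance score
#'
#' Tests `H0: importance <= 0` against `H1: importance > 0` assuming
#' approximate normality of the estimate: `p = 1 - pnorm(importance /
#' std_error)`.  Degenerate convention when `std_error == 0`:
#' `importance <= 0` gives `p = 1`; `importance > 0` gives `p = 0` with a
#' warning (this cannot arise from nondegenerate data).
#'
#' @param importance numeric importance estimate(s).
#' @param std_error nonnegative standard error(s).
#' @return p-value(s) in `[0, 1]`.
#' @export
one_sided_pvalue <- function(importance, std_error) {
  if (any(std_error < 0)) {
    stop("`std_error` must be nonnegative", call. = FALSE)
  }
  if (any(std_error == 0 & importance > 0)) {
    warning("positive importance with zero standard error; p-value set to 0")
  }
  ifelse(std_error > 0,
         stats::pnorm(importance / std_error, lower.tail = FALSE),
         ifelse(importance > 0, 0, 1))
}

#' Benjamini-Hochberg adjustment of importance p-values
#'
#' @param p_values vector of raw p-values in `(0, 1]`.
#' @return adjusted values (q-values), monotone in p-rank, capped at 1.
#' @export
adjust_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1) || anyNA(p_values)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Select significant features from an importance table
#'
#' @param results a data frame of importance estimates as returned by
#'   [importance_single_split()], [importance_crossfit()] or [permfit()]
#'   (needs columns `p_value` and, when `use_fdr = TRUE`, `q_value`).
#' @param alpha significance level in `(0, 1)`.
#' @param use_fdr select on FDR-adjusted q-values instead of raw p-values.
#' @return integer vector of selected row indices, in original feature
#'   order.
#' @export
select_features <- function(results, alpha = 0.05, use_fdr = FALSE) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }
  p <- if (use_fdr) results$q_value else results$p_value
  if (is.null(p)) {
    stop("`results` lacks the required p-value column", call. = FALSE)
  }
  which(p < alpha)
}

#' Partition samples into folds for cross-fitting
#'
#' Randomly assigns the `N` samples to `K` folds of as equal size as
#' possible (sizes differ by at most one).
#'
#' @param N number of samples (`N >= K`).
#' @param K number of folds (`K >= 2`).
#' @param seed optional seed; the assignment is reproducible from it.
#' @return an object of class `crossfit_plan`: list with `K`,
#'   `fold_assignment` (length-`N` integer vector of fold labels) and
#'   `seed`.
#' @export
make_crossfit_plan <- function(N, K, seed = NULL) {
  if (!is.numeric(K) || K < 2L || K > N) {
    stop("`K` must satisfy 2 <= K <= N", call. = FALSE)
  }
  base <- rep_len(seq_len(K), N) # sizes differ by <= 1
  assignment <- with_seed(seed, sample(base))
  structure(
    list(K = as.integer(K), fold_assignment = assignment, seed = seed),
    class = "crossfit_plan"
  )
}

# -- contribution machinery ---------------------------------------------------

# Resolve which columns move together.  `feature_groups` is a named list of
# column indices/names; columns not covered by any group become singleton
# terms named after themselves.
resolve_terms <- function(X, features = NULL, feature_groups = NULL) {
  p <- ncol(X)
  nm <- colnames(X)
  if (is.null(feature_groups)) {
    terms <- as.list(seq_len(p))
    names(terms) <- nm
  } else {
    groups <- lapply(feature_groups, function(g) {
      if (is.character(g)) g <- match(g, nm)
      if (anyNA(g) || any(g < 1L) || any(g > p)) {
        stop("feature group refers to unknown columns", call. = FALSE)
      }
      as.integer(g)
    })
    covered <- unlist(groups, use.names = FALSE)
    if (anyDuplicated(covered)) {
      stop("feature groups must not overlap", call. = FALSE)
    }
    rest <- setdiff(seq_len(p), covered)
    terms <- c(groups, stats::setNames(as.list(rest), nm[rest]))
    # keep original column order: sort terms by their first column
    terms <- terms[order(vapply(terms, min, integer(1L)))]
  }
  if (!is.null(features)) {
    if (is.character(features)) features <- match(features, names(terms))
    if (anyNA(features) || any(features < 1L) ||
        any(features > length(terms))) {
      stop("`features` must index the resolved feature terms", call. = FALSE)
    }
    terms <- terms[features]
  }
  terms
}

# Per-sample contribution matrix (n_eval x n_terms).  Each column holds, for
# one feature term, the loss difference (permuted minus intact) averaged over
# `n_perm` independent permutations.  Consumes the current RNG stream.
perm_contributions <- function(predictor, X, y, terms, n_perm = 1L,
                               clip_eps = 1e-6) {
  n <- nrow(X)
  pred0 <- predict(predictor, X)
  binary <- predictor$outcome_type == "binary"
  base_loss <- if (binary) NULL else loss_contrib_continuous(y, pred0)
  D <- matrix(0, n, length(terms),
              dimnames = list(NULL, names(terms)))
  for (t in seq_along(terms)) {
    cols <- terms[[t]]
    acc <- numeric(n)
    for (b in seq_len(n_perm)) {
      ord <- sample.int(n)
      Xp <- X
      Xp[, cols] <- X[ord, cols, drop = FALSE]
      predp <- predict(predictor, Xp)
      if (binary) {
        acc <- acc + deviance_contrib(y, pred0, predp, clip_eps)
      } else {
        acc <- acc + loss_contrib_continuous(y, predp) - base_loss
      }
    }
    D[, t] <- acc / n_perm
  }
  D
}

# Collapse a contribution matrix into the importance table.
# variance = (empirical second central moment of contributions) / n_eval,
# i.e. the variance of the mean contribution.
summarize_contributions <- function(D) {
  n <- nrow(D)
  imp <- colMeans(D)
  m2 <- colMeans(sweep(D, 2L, imp, "-")^2)
  variance <- m2 / n
  se <- sqrt(variance)
  p <- one_sided_pvalue(imp, se)
  out <- data.frame(
    feature = colnames(D),
    importance = unname(imp),
    variance = unname(variance),
    std_error = unname(se),
    z = unname(ifelse(se > 0, imp / se, NA_real_)),
    p_value = unname(p),
    n_eval = n,
    stringsAsFactors = FALSE
  )
  attr(out, "contributions") <- D
  out
}

#' Permutation importance on a held-out validation set
#'
#' Estimates each feature's importance as the mean, over validation
#' samples, of the increase in prediction loss caused by permuting that
#' feature's column (squared error for continuous outcomes, binomial
#' deviance for binary ones), together with its standard error and a
#' one-sided Z p-value.  The predictor must have been fitted on samples
#' disjoint from the validation set; this disjointness is the caller's
#' responsibility and is not verified.
#'
#' @param predictor a `permfit_predictor` (see [new_predictor()] or the
#'   built-in backends).
#' @param X_valid validation feature matrix (nonempty, no missing values).
#' @param y_valid validation outcome vector.
#' @param features optional indices (or names) of the feature terms to
#'   test; default all.
#' @param n_perm number of independent permutations per feature; the
#'   per-sample contribution is averaged over them before the variance is
#'   computed.  Default 1 (a single permuted copy).
#' @param seed optional seed for the permutations.
#' @param feature_groups optional named list of column blocks permuted
#'   jointly (e.g. one-hot encodings of a single categorical feature).
#' @param clip_eps probability clipping bound for binary deviance.
#' @return a data frame with one row per feature term and columns
#'   `feature`, `importance`, `variance`, `std_error`, `z`, `p_value`,
#'   `n_eval`; the per-sample contribution matrix is attached as attribute
#'   `"contributions"`.
#' @export
importance_single_split <- function(predictor, X_valid, y_valid,
                                    features = NULL, n_perm = 1L,
                                    seed = NULL, feature_groups = NULL,
                                    clip_eps = 1e-6) {
  if (!inherits(predictor, "permfit_predictor")) {
    stop("`predictor` must be a permfit_predictor", call. = FALSE)
  }
  X_valid <- as_feature_matrix(X_valid, "X_valid")
  if (nrow(X_valid) == 0L) {
    stop("validation set is empty", call. = FALSE)
  }
  check_outcome(y_valid, predictor$outcome_type, nrow(X_valid), "y_valid")
  terms <- resolve_terms(X_valid, features, feature_groups)
  D <- with_seed(seed,
    perm_contributions(predictor, X_valid, y_valid, terms, n_perm, clip_eps))
  summarize_contributions(D)
}

#' Cross-fitted permutation importance
#'
#' Implements K-fold cross-fitting: for each fold `V_k` a predictor is
#' fitted on the complement and per-sample importance contributions are
#' computed on `V_k` (with a permutation drawn independently within each
#' fold), so every sample contributes exactly once per feature.  The
#' importance estimate is the overall mean contribution and its variance
#' is the empirical second central moment of the contributions divided by
#' `N`.
#'
#' @param fit model-fitting function called as `fit(X_train, y_train)` and
#'   returning a `permfit_predictor` (the built-in backends can be
#'   partially applied for this, see [permfit()]).
#' @param X feature matrix for the full sample.
#' @param y outcome vector.
#' @param plan a `crossfit_plan` from [make_crossfit_plan()].
#' @param n_perm,seed,feature_groups,clip_eps as in
#'   [importance_single_split()]; the seed fans out into independent
#'   substreams for each fold's fit and permutations.
#' @return as [importance_single_split()], with `n_eval = N`.
#' @export
importance_crossfit <- function(fit, X, y, plan, n_perm = 1L, seed = NULL,
                                feature_groups = NULL, clip_eps = 1e-6) {
  stopifnot(is.function(fit))
  if (!inherits(plan, "crossfit_plan")) {
    stop("`plan` must come from make_crossfit_plan()", call. = FALSE)
  }
  X <- as_feature_matrix(X)
  n <- nrow(X)
  if (length(plan$fold_assignment) != n) {
    stop("cross-fit plan covers ", length(plan$fold_assignment),
         " samples but `X` has ", n, " rows", call. = FALSE)
  }
  terms <- resolve_terms(X, NULL, feature_groups)
  D <- matrix(NA_real_, n, length(terms),
              dimnames = list(NULL, names(terms)))
  outcome_type <- NULL
  for (k in seq_len(plan$K)) {
    in_fold <- plan$fold_assignment == k
    predictor <- tryCatch(
      with_seed(if (is.null(seed)) NULL else derive_seed(seed, paste0("fit", k)),
                fit(X[!in_fold, , drop = FALSE], y[!in_fold])),
      error = function(e) {
        stop(sprintf("model fitting failed on fold %d: %s",
                     k, conditionMessage(e)), call. = FALSE)
      })
    if (!inherits(predictor, "permfit_predictor")) {
      stop("`fit` must return a permfit_predictor", call. = FALSE)
    }
    outcome_type <- predictor$outcome_type
    check_outcome(y[in_fold], outcome_type, sum(in_fold))
    D[in_fold, ] <- with_seed(
      if (is.null(seed)) NULL else derive_seed(seed, paste0("perm", k)),
      perm_contributions(predictor, X[in_fold, , drop = FALSE], y[in_fold],
                         terms, n_perm, clip_eps))
  }
  summarize_contributions(D)
}
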