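# Learner backends satisfying the predictor contract: bagged deep neural
# network, random forest, radial-kernel SVM, plus the classical per-tree
# out-of-bag RF importance baseline.  The tree, network and SMO engines are
# implemented in compiled code in this package (no external learner
# packages are required).

#' Configuration for the bagged deep neural network backend
#'
#' Defaults follow the reference settings for desk-scale biomedical
#' tabular data: 100 bagged networks, mini-batches of 50, four hidden
#' layers of 50/40/30/20 rectified-linear units, and an L2 penalty weight
#' of 1e-4.  Only the best-fitting half of the bag (lowest out-of-bag
#' loss) is kept for prediction ("many could be better than all").
#'
#' @param n_hidden_layers number of hidden layers.
#' @param hidden_nodes integer vector of nodes per hidden layer; its length
#'   must equal `n_hidden_layers`.
#' @param activation hidden activation; only `"relu"` is implemented.
#' @param lambda L2 penalty weight on the connection weights.
#' @param bagging_size number of bootstrap members.
#' @param batch_size mini-batch size for stochastic gradient descent.
#' @param epochs maximum training epochs per member.
#' @param learning_rate initial Adam step size.
#' @param lr_decay multiplicative learning-rate decay applied per epoch.
#' @param keep_fraction fraction (0, 1] of members with the lowest
#'   out-of-bag loss retained in the ensemble; at least one is kept.
#' @param validation_frac member-internal holdout fraction for early
#'   stopping.
#' @param patience epochs without holdout improvement before a member
#'   stops early; `0` disables early stopping.
#' @return a list of class `dnn_config`.
#' @export
dnn_config <- function(n_hidden_layers = 4L,
                       hidden_nodes = c(50L, 40L, 30L, 20L),
                       activation = "relu",
                       lambda = 1e-4,
                       bagging_size = 100L,
                       batch_size = 50L,
                       epochs = 100L,
                       learning_rate = 0.03,
                       lr_decay = 0.995,
                       keep_fraction = 0.5,
                       validation_frac = 0.1,
                       patience = 10L) {
  if (length(hidden_nodes) != n_hidden_layers) {
    stop("`hidden_nodes` must have length `n_hidden_layers`", call. = FALSE)
  }
  if (!identical(activation, "relu")) {
    stop("only the rectified linear activation is implemented", call. = FALSE)
  }
  if (bagging_size < 1L) stop("`bagging_size` must be >= 1", call. = FALSE)
  if (keep_fraction <= 0 || keep_fraction > 1) {
    stop("`keep_fraction` must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(n_hidden_layers = as.integer(n_hidden_layers),
         hidden_nodes = as.integer(hidden_nodes),
         activation = activation, lambda = lambda,
         bagging_size = as.integer(bagging_size),
         batch_size = as.integer(batch_size),
         epochs = as.integer(epochs),
         learning_rate = learning_rate,
         lr_decay = lr_decay,
         keep_fraction = keep_fraction,
         validation_frac = validation_frac,
         patience = as.integer(patience)),
    class = "dnn_config"
  )
}

#' Fit a bagged deep neural network
#'
#' Trains `bagging_size` feed-forward networks, each on a bootstrap
#' resample, by mini-batch stochastic gradient descent with Adam and an L2
#' weight penalty.  Each member is scored on its out-of-bag samples and
#' only the best `keep_fraction` of members form the ensemble, whose
#' prediction is the kept-member mean (mean probability for binary
#' outcomes).  Features are standardized with training statistics;
#' continuous outcomes are standardized internally and predictions mapped
#' back.
#'
#' @param X training feature matrix.
#' @param y training outcome vector.
#' @param config a [dnn_config()].
#' @param outcome_type `"continuous"`, `"binary"`, or `NULL` to infer
#'   (0/1 outcomes are treated as binary).
#' @param seed optional seed; with it, fitting is reproducible.
#' @return a `permfit_predictor`.
#' @export
fit_bagged_dnn <- function(X, y, config = dnn_config(),
                           outcome_type = NULL, seed = NULL) {
  X <- as_feature_matrix(X)
  outcome_type <- check_outcome(y, outcome_type, nrow(X))
  stopifnot(inherits(config, "dnn_config"))
  classify <- outcome_type == "binary"
  n <- nrow(X)

  std <- col_standardizer(X)
  Xs <- std$apply(X)
  y_center <- 0; y_scale <- 1
  ys <- y
  if (!classify) {
    y_center <- mean(y)
    y_scale <- stats::sd(y)
    if (!is.finite(y_scale) || y_scale < .Machine$double.eps) y_scale <- 1
    ys <- (y - y_center) / y_scale
  }

  members <- with_seed(seed, {
    lapply(seq_len(config$bagging_size), function(b) {
      boot <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), boot)
      fit <- cpp_dnn_fit(Xs[boot, , drop = FALSE], ys[boot], classify,
                         config$hidden_nodes, config$epochs,
                         config$batch_size, config$learning_rate,
                         config$lr_decay, config$lambda,
                         config$validation_frac, config$patience)
      score <- if (length(oob) > 0L) {
        pr <- as.numeric(cpp_dnn_predict(fit, Xs[oob, , drop = FALSE],
                                         classify))
        if (classify) {
          pc <- pmin(pmax(pr, 1e-10), 1 - 1e-10)
          -mean(ys[oob] * log(pc) + (1 - ys[oob]) * log(1 - pc))
        } else {
          mean((ys[oob] - pr)^2)
        }
      } else {
        fit$train_loss
      }
      list(fit = fit, score = score)
    })
  })

  scores <- vapply(members, `[[`, numeric(1L), "score")
  finite <- is.finite(scores)
  if (any(!finite)) {
    warning(sum(!finite), " ensemble member(s) discarded for non-finite loss")
  }
  if (!any(finite)) {
    stop("all ensemble members diverged; lower the learning rate",
         call. = FALSE)
  }
  n_keep <- max(1L, ceiling(config$keep_fraction * sum(finite)))
  keep <- order(ifelse(finite, scores, Inf))[seq_len(n_keep)]
  kept <- members[keep]

  predict_fn <- function(newX) {
    Xn <- std$apply(newX)
    preds <- vapply(kept, function(m) {
      as.numeric(cpp_dnn_predict(m$fit, Xn, classify))
    }, numeric(nrow(Xn)))
    if (nrow(Xn) == 1L) preds <- matrix(preds, nrow = 1L)
    out <- rowMeans(preds)
    if (classify) pmin(pmax(out, 0), 1) else out * y_scale + y_center
  }
  new_predictor(predict_fn, outcome_type,
                training_indices = seq_len(n),
                model = list(config = config, oob_scores = scores,
                             kept = keep,
                             members = lapply(kept, `[[`, "fit"),
                             standardize = std$apply,
                             y_scale = y_scale, y_center = y_center),
                label = "dnn")
}

#' Fit a random forest
#'
#' Bootstrap-aggregated CART trees with `mtry` candidate features per
#' split: regression forests predict the tree-mean, probability forests
#' the fraction of tree votes for class 1.  Defaults mirror common
#' practice: 1000 trees, `mtry = p/3` (regression) or `sqrt(p)`
#' (classification), terminal node size 5 (regression) or 1
#' (classification).
#'
#' @param X training feature matrix.
#' @param y training outcome vector.
#' @param n_trees number of trees.
#' @param mtry candidate features per split; `NULL` for the default.
#' @param nodesize minimal node size below which splitting stops; `NULL`
#'   for the default.
#' @param outcome_type `"continuous"`, `"binary"`, or `NULL` to infer.
#' @param seed optional seed.
#' @return a `permfit_predictor`.
#' @export
fit_rf <- function(X, y, n_trees = 1000L, mtry = NULL, nodesize = NULL,
                   outcome_type = NULL, seed = NULL) {
  X <- as_feature_matrix(X)
  outcome_type <- check_outcome(y, outcome_type, nrow(X))
  if (n_trees < 1L) stop("`n_trees` must be >= 1", call. = FALSE)
  classify <- outcome_type == "binary"
  if (classify && length(unique(y)) < 2L) {
    stop("binary outcome has a single class; cannot grow a classification forest",
         call. = FALSE)
  }
  p <- ncol(X)
  if (is.null(mtry)) {
    mtry <- if (classify) max(1L, floor(sqrt(p))) else max(1L, floor(p / 3))
  }
  if (is.null(nodesize)) nodesize <- if (classify) 1L else 5L
  forest <- with_seed(seed,
    cpp_rf_fit(X, as.numeric(y), classify, as.integer(n_trees),
               as.integer(mtry), as.integer(nodesize), FALSE))
  handle <- cpp_rf_handle(forest)
  predict_fn <- function(newX) {
    as.numeric(cpp_rf_predict_ptr(handle, newX))
  }
  new_predictor(predict_fn, outcome_type,
                training_indices = seq_len(nrow(X)),
                model = list(forest = forest, mtry = mtry,
                             nodesize = nodesize, n_trees = n_trees),
                label = "rf")
}

#' Per-tree out-of-bag random-forest importance (the classical baseline)
#'
#' For every tree, each feature is permuted within the tree's out-of-bag
#' samples and the increase in out-of-bag prediction error (squared error
#' for regression, misclassification rate for binary outcomes) is
#' recorded.  A feature's importance is the mean increase over trees, its
#' standard error the tree-wise standard deviation divided by
#' `sqrt(n_trees)`, and the one-sided Z p-value follows.  This estimator
#' has no train/validation separation, which is exactly why it serves as
#' the baseline against the cross-fitted permutation test.
#'
#' @inheritParams fit_rf
#' @return a data frame with columns `feature`, `importance`, `variance`,
#'   `std_error`, `z`, `p_value`, `n_eval` (trees contributing); the
#'   per-tree importance matrix is attached as attribute
#'   `"tree_importance"`.
#' @export
vanilla_rf_importance <- function(X, y, n_trees = 1000L, mtry = NULL,
                                  nodesize = NULL, outcome_type = NULL,
                                  seed = NULL) {
  X <- as_feature_matrix(X)
  outcome_type <- check_outcome(y, outcome_type, nrow(X))
  classify <- outcome_type == "binary"
  if (classify && length(unique(y)) < 2L) {
    stop("binary outcome has a single class", call. = FALSE)
  }
  p <- ncol(X)
  if (is.null(mtry)) {
    mtry <- if (classify) max(1L, floor(sqrt(p))) else max(1L, floor(p / 3))
  }
  if (is.null(nodesize)) nodesize <- if (classify) 1L else 5L
  forest <- with_seed(seed,
    cpp_rf_fit(X, as.numeric(y), classify, as.integer(n_trees),
               as.integer(mtry), as.integer(nodesize), TRUE))
  M <- forest$tree_importance
  ok <- stats::complete.cases(M)
  if (!any(ok)) {
    stop("no tree had out-of-bag samples; increase `n_trees`", call. = FALSE)
  }
  M <- M[ok, , drop = FALSE]
  nt <- nrow(M)
  imp <- colMeans(M)
  se <- apply(M, 2L, stats::sd) / sqrt(nt)
  out <- data.frame(
    feature = colnames(X),
    importance = unname(imp),
    variance = unname(se^2),
    std_error = unname(se),
    z = unname(ifelse(se > 0, imp / se, NA_real_)),
    p_value = unname(one_sided_pvalue(imp, se)),
    n_eval = nt,
    stringsAsFactors = FALSE
  )
  attr(out, "tree_importance") <- M
  out
}

#' Fit a radial-kernel support vector machine
#'
#' Epsilon-regression for continuous outcomes, C-classification with
#' sigmoid (Platt) probability calibration for binary outcomes.  Cost and
#' kernel width are chosen on a log2 grid by minimizing cross-validated
#' loss (squared error, or misclassification rate for binary outcomes);
#' the chosen pair is recorded in the returned predictor's `model`.
#' Features are standardized with training statistics; continuous outcomes
#' are standardized internally.
#'
#' @param X training feature matrix.
#' @param y training outcome vector.
#' @param cv_folds folds for the hyperparameter search (>= 2).
#' @param cost_grid candidate soft-margin costs.
#' @param gamma_grid candidate RBF kernel widths.
#' @param epsilon tube half-width for regression (on the standardized
#'   outcome scale).
#' @param outcome_type `"continuous"`, `"binary"`, or `NULL` to infer.
#' @param seed optional seed (controls the cross-validation folds).
#' @return a `permfit_predictor` whose `model` records the chosen
#'   hyperparameters and the search grid.
#' @export
fit_svm <- function(X, y, cv_folds = 5L,
                    cost_grid = 2^seq(-3, 7, by = 2),
                    gamma_grid = 2^seq(-7, 3, by = 2),
                    epsilon = 0.1, outcome_type = NULL, seed = NULL) {
  X <- as_feature_matrix(X)
  outcome_type <- check_outcome(y, outcome_type, nrow(X))
  if (cv_folds < 2L) stop("`cv_folds` must be >= 2", call. = FALSE)
  classify <- outcome_type == "binary"
  if (classify && length(unique(y)) < 2L) {
    stop("binary outcome has a single class", call. = FALSE)
  }
  n <- nrow(X)
  std <- col_standardizer(X)
  Xs <- std$apply(X)
  y_center <- 0; y_scale <- 1
  ys <- y
  if (!classify) {
    y_center <- mean(y)
    y_scale <- stats::sd(y)
    if (!is.finite(y_scale) || y_scale < .Machine$double.eps) y_scale <- 1
    ys <- (y - y_center) / y_scale
  }
  max_iter <- max(20000L, 50L * n)

  plan <- make_crossfit_plan(n, cv_folds,
                             if (is.null(seed)) NULL
                             else derive_seed(seed, "svm_cv"))
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  cv_loss <- vapply(seq_len(nrow(grid)), function(g) {
    C <- grid$cost[g]; gam <- grid$gamma[g]
    loss <- 0
    for (k in seq_len(cv_folds)) {
      hold <- plan$fold_assignment == k
      Xtr <- Xs[!hold, , drop = FALSE]; Xte <- Xs[hold, , drop = FALSE]
      f <- if (classify) {
        if (length(unique(ys[!hold])) < 2L) return(Inf)
        m <- cpp_svc_fit(Xtr, ys[!hold], C, gam, 1e-3, max_iter)
        as.numeric(cpp_svm_decision(Xtr, m$coef, m$b, gam, Xte))
      } else {
        m <- cpp_svr_fit(Xtr, ys[!hold], C, gam, epsilon, 1e-3, max_iter)
        as.numeric(cpp_svm_decision(Xtr, m$coef, m$b, gam, Xte))
      }
      loss <- loss + if (classify) {
        sum((f >= 0) != (ys[hold] == 1))
      } else {
        sum((ys[hold] - f)^2)
      }
    }
    loss / n
  }, numeric(1L))
  if (!any(is.finite(cv_loss))) {
    stop("hyperparameter grid exhausted without a finite score", call. = FALSE)
  }
  best <- which.min(cv_loss)
  C <- grid$cost[best]; gam <- grid$gamma[best]

  if (classify) {
    m <- cpp_svc_fit(Xs, ys, C, gam, 1e-3, max_iter)
    f_train <- as.numeric(cpp_svm_decision(Xs, m$coef, m$b, gam, Xs))
    # Platt scaling within the training fold
    calib <- suppressWarnings(
      stats::glm(ys ~ f_train, family = stats::binomial()))
    a <- stats::coef(calib)
    predict_fn <- function(newX) {
      f <- as.numeric(cpp_svm_decision(Xs, m$coef, m$b, gam, std$apply(newX)))
      pmin(pmax(stats::plogis(a[1L] + a[2L] * f), 0), 1)
    }
  } else {
    m <- cpp_svr_fit(Xs, ys, C, gam, epsilon, 1e-3, max_iter)
    predict_fn <- function(newX) {
      f <- as.numeric(cpp_svm_decision(Xs, m$coef, m$b, gam, std$apply(newX)))
      f * y_scale + y_center
    }
  }
  new_predictor(predict_fn, outcome_type,
                training_indices = seq_len(n),
                model = list(cost = C, gamma = gam, epsilon = epsilon,
                             cv_loss = cv_loss, grid = grid,
                             n_sv = sum(abs(m$coef) > 1e-12)),
                label = "svm")
}

# Resolve a backend name (or user function) into fit(X, y) -> predictor.
backend_fit_fun <- function(backend, outcome_type, backend_args = list(),
                            seed = NULL) {
  if (is.function(backend)) {
    return(function(X, y) backend(X, y))
  }
  backend <- match.arg(backend, c("rf", "dnn", "svm"))
  switch(backend,
    rf = function(X, y) {
      do.call(fit_rf, c(list(X = X, y = y, outcome_type = outcome_type),
                        backend_args))
    },
    dnn = function(X, y) {
      do.call(fit_bagged_dnn,
              c(list(X = X, y = y, outcome_type = outcome_type),
                backend_args))
    },
    svm = function(X, y) {
      do.call(fit_svm, c(list(X = X, y = y, outcome_type = outcome_type),
                         backend_args))
    })
}
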