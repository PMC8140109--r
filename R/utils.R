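# Internal helpers: input validation and reproducible seed management.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' previous RNG state so callers see no side effect.  A `NULL` seed leaves
#' the RNG stream untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Derive a named substream seed from a master seed
#'
#' Deterministically maps a (master seed, label) pair to an integer in
#' `[0, 2^31 - 2]`, so that each stage of a pipeline (fold assignment,
#' per-feature permutations, backend fitting, replicates) owns its own
#' reproducible stream and can be re-run in isolation.
#'
#' @param seed integer master seed.
#' @param label character tag naming the substream, e.g. `"fold"` or
#'   `"rep3"`.
#' @return an integer seed.
#' @export
#' @examples
#' derive_seed(42, "fold") != derive_seed(42, "perm")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647 # 2^31 - 1, Lehmer modulus keeps results in R's int range
  h <- (abs(seed) %% m) + 1
  h <- (h * 48271) %% m
  for (ch in utf8ToInt(label)) {
    h <- (h * 69621 + ch) %% m
  }
  as.integer(h)
}

# -- validation ---------------------------------------------------------------

as_feature_matrix <- function(X, arg = "X") {
  if (is.data.frame(X)) {
    non_num <- names(X)[!vapply(X, is.numeric, logical(1L))]
    if (length(non_num) > 0L) {
      stop(sprintf("non-numeric feature column(s): %s",
                   paste(non_num, collapse = ", ")), call. = FALSE)
    }
    X <- as.matrix(X)
  }
  if (!is.matrix(X) || !is.numeric(X)) {
    stop(sprintf("`%s` must be a numeric matrix or all-numeric data frame",
                 arg), call. = FALSE)
  }
  if (anyNA(X) || any(!is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing or non-finite value in `%s` at row %d, column %d; impute before calling",
                 arg, bad[1L], bad[2L]), call. = FALSE)
  }
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("X", seq_len(ncol(X)))
  }
  X
}

check_outcome <- function(y, outcome_type = NULL, n = NULL, arg = "y") {
  if (!is.numeric(y) || !is.null(dim(y))) {
    stop(sprintf("`%s` must be a numeric vector", arg), call. = FALSE)
  }
  if (anyNA(y) || any(!is.finite(y))) {
    stop(sprintf("missing or non-finite value in `%s`", arg), call. = FALSE)
  }
  if (!is.null(n) && length(y) != n) {
    stop(sprintf("`%s` has length %d but the feature matrix has %d rows",
                 arg, length(y), n), call. = FALSE)
  }
  if (is.null(outcome_type)) {
    outcome_type <- if (all(y %in% c(0, 1))) "binary" else "continuous"
  }
  outcome_type <- match.arg(outcome_type, c("continuous", "binary"))
  if (outcome_type == "binary" && !all(y %in% c(0, 1))) {
    stop(sprintf("binary `%s` must contain only 0 and 1", arg), call. = FALSE)
  }
  outcome_type
}

# Standardize columns with train-fold statistics; constant columns pass
# through unscaled to avoid 0/0.
col_standardizer <- function(X) {
  mu <- colMeans(X)
  sigma <- apply(X, 2L, stats::sd)
  sigma[sigma < .Machine$double.eps] <- 1
  list(
    center = mu, scale = sigma,
    apply = function(M) sweep(sweep(M, 2L, mu, "-"), 2L, sigma, "/")
  )
}
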