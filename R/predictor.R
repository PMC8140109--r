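#' Wrap a fitted model as a predictor usable by the importance estimators
#'
#' The importance machinery only needs a prediction rule: a function mapping
#' a numeric feature matrix to expected outcomes (continuous) or event
#' probabilities in `[0, 1]` (binary).  `new_predictor()` packages such a
#' rule, its outcome type and (optionally) the indices of the samples it was
#' trained on into a `permfit_predictor` object, so that any model -- not
#' just the built-in backends -- can be tested.
#'
#' @param predict_fn function of one argument (a numeric matrix with the
#'   same columns as the training features) returning a numeric vector of
#'   predictions, one per row.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param training_indices optional integer vector of row indices the model
#'   was fitted on.  Purely informational: the estimators do *not* verify
#'   disjointness between training and evaluation samples (caller contract).
#' @param model optional underlying model object, kept for inspection.
#' @param label short backend name recorded in metadata.
#' @return an object of class `permfit_predictor`.
#' @export
#' @examples
#' fit <- lm(mpg ~ ., data = mtcars)
#' pred <- new_predictor(
#'   function(X) predict(fit, as.data.frame(X)),
#'   outcome_type = "continuous"
#' )
#' head(predict(pred, as.matrix(mtcars[, -1])))
new_predictor <- function(predict_fn, outcome_type = c("continuous", "binary"),
                          training_indices = NULL, model = NULL,
                          label = "custom") {
  stopifnot(is.function(predict_fn))
  outcome_type <- match.arg(outcome_type)
  structure(
    list(
      predict = predict_fn,
      outcome_type = outcome_type,
      training_indices = training_indices,
      model = model,
      label = label
    ),
    class = "permfit_predictor"
  )
}

#' @export
predict.permfit_predictor <- function(object, newdata, ...) {
  newdata <- as_feature_matrix(newdata, "newdata")
  out <- as.numeric(object$predict(newdata))
  if (length(out) != nrow(newdata)) {
    stop("predictor returned ", length(out), " values for ",
         nrow(newdata), " rows", call. = FALSE)
  }
  if (any(!is.finite(out))) {
    stop("predictor returned non-finite predictions", call. = FALSE)
  }
  if (object$outcome_type == "binary" &&
      (any(out < 0) || any(out > 1))) {
    stop("binary predictor returned probabilities outside [0, 1]",
         call. = FALSE)
  }
  out
}

#' @export
print.permfit_predictor <- function(x, ...) {
  cat(sprintf("<permfit_predictor> backend=%s outcome=%s trained_n=%s\n",
              x$label, x$outcome_type,
              if (is.null(x$training_indices)) "?"
              else length(x$training_indices)))
  invisible(x)
}
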