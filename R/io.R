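# Delimited-text readers and writers for datasets, importance tables and
# run metadata.

#' Read a delimited dataset into a feature matrix and outcome vector
#'
#' Reads a CSV or TSV file with a header row, pulls out the outcome
#' column, and validates that every feature column is numeric and
#' complete.  The delimiter is inferred from the file extension
#' (`.tsv`/`.txt` = tab, otherwise comma) unless given explicitly.
#'
#' @param path file path.
#' @param outcome name of the outcome column.
#' @param outcome_type `"continuous"`, `"binary"`, or `NULL` to infer.
#' @param sep field delimiter, or `NULL` to infer from the extension.
#' @return a list with `X` (numeric matrix), `y`, `outcome_type` and
#'   `feature_names`.
#' @export
read_dataset <- function(path, outcome, outcome_type = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty dataset: ", path, call. = FALSE)
  if (!outcome %in% names(df)) {
    stop(sprintf("outcome column '%s' not found (columns: %s)",
                 outcome, paste(names(df), collapse = ", ")), call. = FALSE)
  }
  y <- df[[outcome]]
  feats <- df[setdiff(names(df), outcome)]
  if (ncol(feats) == 0L) stop("no feature columns", call. = FALSE)
  for (nm in names(feats)) {
    if (!is.numeric(feats[[nm]])) {
      stop(sprintf("non-numeric feature column '%s'; encode it numerically",
                   nm), call. = FALSE)
    }
    if (anyNA(feats[[nm]])) {
      stop(sprintf("missing value in column '%s' at row %d; impute before loading",
                   nm, which(is.na(feats[[nm]]))[1L]), call. = FALSE)
    }
  }
  if (anyNA(y)) {
    stop(sprintf("missing outcome value at row %d", which(is.na(y))[1L]),
         call. = FALSE)
  }
  X <- as.matrix(feats)
  outcome_type <- check_outcome(y, outcome_type, nrow(X), outcome)
  list(X = X, y = as.numeric(y), outcome_type = outcome_type,
       feature_names = colnames(X))
}

#' Write an importance table as TSV
#'
#' Numeric columns are written with 6 significant digits; use the JSON
#' metadata sidecar for full-precision run information.
#'
#' @param result a `permfit_result` or an importance data frame.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_importance <- function(result, path) {
  tab <- if (inherits(result, "permfit_result")) result$importance else result
  out <- tab
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], signif, digits = 6L)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back an importance table written by [write_importance()]
#'
#' @param path TSV file path.
#' @return a data frame.
#' @export
read_importance <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write run metadata as a JSON sidecar
#'
#' @param metadata named list (e.g. `permfit_result$metadata`).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_run_metadata <- function(metadata, path) {
  jsonlite::write_json(metadata, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
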