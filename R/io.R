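#' Read a long-format longitudinal count table
#'
#' One row per subject-visit; comma- or tab-delimited with a header.
#' Rows are grouped by subject and sorted by visit; visits must be
#' consecutive 1-based integers and the outcome a non-negative integer.
#' An intercept column is prepended to the covariates.
#'
#' @param path Delimited text file.
#' @param subject_col,visit_col,outcome_col Column names.
#' @param covariate_cols Character vector of covariate column names
#'   (may be empty for an intercept-only model).
#' @param sep Field separator; `NULL` (default) picks tab when the header
#'   contains one, comma otherwise.
#' @return An [ad_data] object.
#' @export
read_long_table <- function(path, subject_col = "subject",
                            visit_col = "visit", outcome_col = "y",
                            covariate_cols = character(), sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(subject_col, visit_col, outcome_col, covariate_cols)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  y <- df[[outcome_col]]
  if (!is.numeric(y) || any(!is.finite(y)) || any(y < 0) || any(y != round(y)))
    stop("outcome column '", outcome_col,
         "' must contain non-negative integers", call. = FALSE)
  X <- cbind(`(Intercept)` = 1,
             as.matrix(df[, covariate_cols, drop = FALSE]))
  if (!is.numeric(X)) stop("covariate columns must be numeric", call. = FALSE)
  ad_data(y = y, X = X, subject = df[[subject_col]],
          visit = df[[visit_col]])
}

#' Write a dataset as a long-format delimited table
#'
#' Inverse of [read_long_table]; the intercept column is dropped.
#'
#' @param data An [ad_data] object.
#' @param path Output file.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_long_table <- function(data, path, sep = ",") {
  X <- data$X[, -1L, drop = FALSE]
  df <- data.frame(subject = data$subject, visit = data$visit,
                   y = data$y, check.names = FALSE)
  if (ncol(X)) df <- cbind(df, as.data.frame(X))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
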