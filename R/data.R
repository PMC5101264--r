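#' Longitudinal count dataset
#'
#' Builds the dataset container used throughout the package: ordered,
#' equally spaced count series per subject with a covariate row per
#' subject-visit.  Visits must be consecutively indexed from 1 within each
#' subject (equal spacing is assumed, not checked against timestamps).
#'
#' @param y Integer vector of non-negative counts, one per subject-visit.
#' @param X Numeric matrix of covariates, one row per subject-visit, first
#'   column the intercept (all 1).
#' @param subject Vector of subject identifiers, parallel to `y`.
#' @param visit Integer vector of 1-based visit indices, parallel to `y`.
#'
#' @return An object of class `ad_data`: a list with elements `y`, `X`,
#'   `subject`, `visit`, and precomputed index bookkeeping (`first`:
#'   logical, TRUE for each subject's first visit; `later`: row indices of
#'   visits j >= 2; `prev`: for each later row, the row index of the
#'   preceding visit; `is_j2`: logical over `later`, TRUE when the later
#'   row is visit 2), plus `m` (number of subjects), `n_obs` (total rows)
#'   and `p` (number of covariates).
#' @export
ad_data <- function(y, X, subject, visit) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1L)))[seq_len(ncol(X))]
  }
  n <- length(y)
  if (nrow(X) != n || length(subject) != n || length(visit) != n)
    stop("y, X rows, subject and visit must have equal length", call. = FALSE)
  if (any(!is.finite(y)) || any(y < 0) || any(y != round(y)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (!all(is.finite(X)))
    stop("covariates must be finite", call. = FALSE)
  y <- as.integer(round(y))
  visit <- as.integer(visit)

  ord <- order(match(subject, unique(subject)), visit)
  y <- y[ord]; X <- X[ord, , drop = FALSE]
  subject <- subject[ord]; visit <- visit[ord]

  sid <- match(subject, unique(subject))
  for (s in split(seq_len(n), sid)) {
    v <- visit[s]
    if (anyDuplicated(v))
      stop("duplicated (subject, visit) pair for subject ", subject[s[1L]],
           call. = FALSE)
    if (!identical(v, seq_len(length(v))))
      stop("visits for subject ", subject[s[1L]],
           " are not consecutive 1-based integers", call. = FALSE)
  }

  first <- visit == 1L
  later <- which(!first)
  # visits are sorted within subject, so the previous visit is the previous row
  prev <- later - 1L
  structure(list(
    y = y, X = X, subject = subject, visit = visit,
    first = first, later = later, prev = prev,
    is_j2 = visit[later] == 2L,
    m = length(unique(subject)), n_obs = n, p = ncol(X)
  ), class = "ad_data")
}

#' @export
print.ad_data <- function(x, ...) {
  cat("<ad_data> ", x$m, " subjects, ", x$n_obs, " observations, ",
      x$p, " covariates (incl. intercept)\n", sep = "")
  nvis <- table(table(x$subject))
  cat("  visits per subject: ",
      paste0(names(nvis), " visits x ", nvis, " subjects", collapse = "; "),
      "\n", sep = "")
  invisible(x)
}

#' Model parameters
#'
#' @param beta Numeric vector of regression coefficients on the log-mean
#'   scale (first entry the intercept).
#' @param alpha Adjacent correlation, in (-1, 1).
#' @return An object of class `ad_params` (list with `beta`, `alpha`).
#' @export
ad_params <- function(beta, alpha) {
  beta <- as.numeric(beta)
  alpha <- as.numeric(alpha)
  if (length(alpha) != 1L || !is.finite(alpha) || abs(alpha) >= 1)
    stop("alpha must be a single value in (-1, 1)", call. = FALSE)
  if (!all(is.finite(beta)))
    stop("beta must be finite", call. = FALSE)
  structure(list(beta = beta, alpha = alpha), class = "ad_params")
}

# coerce (params | numeric vector c(beta, alpha)) to ad_params for a dataset
as_ad_params <- function(theta, p) {
  if (inherits(theta, "ad_params")) {
    if (length(theta$beta) != p)
      stop("beta has length ", length(theta$beta), ", expected ", p,
           call. = FALSE)
    return(theta)
  }
  if (length(theta) != p + 1L)
    stop("parameter vector has length ", length(theta), ", expected ",
         p + 1L, call. = FALSE)
  ad_params(theta[seq_len(p)], theta[p + 1L])
}
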