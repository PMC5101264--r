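#' Marginal mean of a count at one visit
#'
#' The marginal expectation is log-linear in the covariates:
#' lambda = exp(x'beta).
#'
#' @param x Covariate row (numeric vector, first entry 1 for the intercept).
#' @param beta Regression coefficient vector of the same length.
#' @return The positive marginal mean exp(x'beta).
#' @export
marginal_mean <- function(x, beta) {
  if (length(x) != length(beta))
    stop("x and beta must have the same length", call. = FALSE)
  exp(sum(x * beta))
}

#' Marginal standard deviation of a count
#'
#' First-visit counts are Poisson, so var = lambda.  Later visits are
#' overdispersed by the serial correlation: var = lambda / (1 - alpha^2).
#'
#' @param lam Positive marginal mean.
#' @param alpha Adjacent correlation in (-1, 1).
#' @param is_first_visit TRUE for a subject's first visit.
#' @return Marginal standard deviation.
#' @export
marginal_sd <- function(lam, alpha, is_first_visit) {
  if (any(lam <= 0)) stop("lam must be positive", call. = FALSE)
  if (abs(alpha) >= 1) stop("alpha must satisfy |alpha| < 1", call. = FALSE)
  ifelse(is_first_visit, sqrt(lam), sqrt(lam / (1 - alpha^2)))
}

#' Conditional mean given the previous count
#'
#' Under first-order antedependence with linear conditional expectations,
#' E(Y_j | Y_{j-1} = y_prev) = lam_cur + alpha (sd_cur / sd_prev)
#' (y_prev - lam_prev).  The result can be non-positive (e.g. alpha < 0
#' with a large previous count); callers must check positivity before
#' using it as a Poisson rate.
#'
#' @param lam_cur,lam_prev Marginal means at the current and previous visit.
#' @param sd_cur,sd_prev Marginal standard deviations at the two visits.
#' @param y_prev Observed previous count.
#' @param alpha Adjacent correlation.
#' @return The conditional mean (may be <= 0; not checked here).
#' @export
conditional_mean <- function(lam_cur, lam_prev, sd_cur, sd_prev, y_prev, alpha) {
  lam_cur + alpha * (sd_cur / sd_prev) * (y_prev - lam_prev)
}
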