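# Internal kernel shared by the likelihood, score and constraint code.
#
# For each within-subject adjacent pair (row j >= 2 with previous row),
# the sd ratio is
#   sigma_j / sigma_{j-1} = k * sqrt(lam_j / lam_prev),
# with k = 1/sqrt(1 - alpha^2) when j = 2 (previous visit is the Poisson
# first visit) and k = 1 for j >= 3 (both visits overdispersed, the
# 1/(1-alpha^2) factors cancel).  The case split matters because the
# alpha-derivative differs between the two cases.
ad_kernel <- function(data, params) {
  beta <- params$beta; alpha <- params$alpha
  lam <- exp(drop(data$X %*% beta))
  later <- data$later
  lam_j <- lam[later]
  lam_p <- lam[data$prev]
  k <- ifelse(data$is_j2, 1 / sqrt(1 - alpha^2), 1)
  ratio <- k * sqrt(lam_j / lam_p)
  # slack of validity constraint (3): lam_j - alpha * ratio * lam_prev
  slack <- lam_j - alpha * ratio * lam_p
  lamstar <- lam_j + alpha * ratio * (data$y[data$prev] - lam_p)
  list(lam = lam, lam_j = lam_j, lam_p = lam_p, k = k, ratio = ratio,
       slack = slack, lamstar = lamstar)
}

#' Joint log-likelihood of the antedependent Poisson model
#'
#' First-visit counts contribute independent Poisson terms with mean
#' lambda_i1 = exp(x_i1' beta); each later count contributes a Poisson
#' term conditional on its predecessor with rate
#' lambda*_ij = lambda_ij + alpha (sigma_ij / sigma_ij-1)(y_ij-1 - lambda_ij-1).
#' ln(y!) is computed via `lgamma` for stability at large counts.
#'
#' @param data An [ad_data] object.
#' @param params An [ad_params] object, or a numeric vector `c(beta, alpha)`.
#' @return The log-likelihood (a finite scalar at any feasible point).
#' @export
ad_loglik <- function(data, params) {
  params <- as_ad_params(params, data$p)
  if (abs(params$alpha) >= 1)
    stop("infeasible point: |alpha| >= 1", call. = FALSE)
  kern <- ad_kernel(data, params)
  if (any(kern$lamstar <= 0))
    stop("infeasible point: conditional mean lambda* <= 0 at the ",
         "evaluation point", call. = FALSE)
  y1 <- data$y[data$first]
  lam1 <- kern$lam[data$first]
  yl <- data$y[data$later]
  sum(y1 * log(lam1) - lam1 - lgamma(y1 + 1)) +
    sum(yl * log(kern$lamstar) - kern$lamstar - lgamma(yl + 1))
}

#' Analytic score (gradient) of the log-likelihood
#'
#' Returns the gradient with respect to `c(beta, alpha)`.  Derived by the
#' chain rule through lambda*_ij; the j = 2 case carries an extra alpha
#' dependence through the 1/sqrt(1 - alpha^2) factor in the sd ratio.
#'
#' @inheritParams ad_loglik
#' @return Numeric vector of length `p + 1`: d l / d beta then d l / d alpha.
#' @export
ad_score <- function(data, params) {
  params <- as_ad_params(params, data$p)
  alpha <- params$alpha
  kern <- ad_kernel(data, params)
  if (any(kern$lamstar <= 0))
    stop("infeasible point: conditional mean lambda* <= 0 at the ",
         "evaluation point", call. = FALSE)
  X <- data$X
  y <- data$y
  first <- data$first; later <- data$later; prev <- data$prev

  # first visits: plain Poisson score
  g_beta <- drop(crossprod(X[first, , drop = FALSE],
                           y[first] - kern$lam[first]))

  # later visits: (y/lam* - 1) dlam*/dtheta
  w <- y[later] / kern$lamstar - 1
  resid_p <- y[prev] - kern$lam_p
  Xj <- X[later, , drop = FALSE]
  Xp <- X[prev, , drop = FALSE]
  # dlam*/dbeta = lam_j x_j + alpha [ (ratio/2)(x_j - x_p) resid_p - ratio lam_p x_p ]
  a1 <- kern$lam_j + alpha * kern$ratio * resid_p / 2     # coefficient on x_j
  a2 <- -alpha * kern$ratio * (resid_p / 2 + kern$lam_p)  # coefficient on x_p
  g_beta <- g_beta + drop(crossprod(Xj, w * a1) + crossprod(Xp, w * a2))

  # dlam*/dalpha = ratio resid_p (1 + 1(j=2) alpha^2/(1-alpha^2))
  fac <- ifelse(data$is_j2, 1 + alpha^2 / (1 - alpha^2), 1)
  g_alpha <- sum(w * kern$ratio * resid_p * fac)

  c(g_beta, g_alpha)
}
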