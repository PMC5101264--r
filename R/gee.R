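#' Poisson regression by iteratively reweighted least squares
#'
#' Independence working model (alpha fixed at 0).  Equivalent to the
#' Poisson MLE; the naive covariance is the inverse Fisher information.
#'
#' @param data An [ad_data] object.
#' @param tol Relative convergence tolerance for the coefficients.
#' @param maxit Iteration cap.
#' @return A list of class `ad_gee`: `beta_hat`, `alpha_hat` (0),
#'   `naive_cov` (p x p), `phi_hat` (Pearson scale Sum z^2 / n),
#'   `loglik` (Poisson log-likelihood), `converged`, `iterations`.
#' @export
fit_poisson <- function(data, tol = 1e-10, maxit = 50L) {
  X <- data$X; y <- data$y
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("singular design: covariate matrix is rank deficient", call. = FALSE)
  beta <- c(log(max(mean(y), 0.1)), rep(0, ncol(X) - 1L))
  converged <- FALSE; it <- 0L
  for (it in seq_len(maxit)) {
    lam <- exp(drop(X %*% beta))
    W <- lam
    z <- drop(X %*% beta) + (y - lam) / lam
    fit <- lm.wfit(X, z, W)
    delta <- max(abs(fit$coefficients - beta)) /
      max(1, max(abs(beta)))
    beta <- fit$coefficients
    if (!all(is.finite(beta)))
      stop("Poisson IRLS diverged", call. = FALSE)
    if (delta < tol) { converged <- TRUE; break }
  }
  lam <- exp(drop(X %*% beta))
  info <- crossprod(X * lam, X)
  structure(list(
    beta_hat = unname(beta), alpha_hat = 0,
    naive_cov = solve(info),
    valpha_naive = NA_real_,
    phi_hat = sum((y - lam)^2 / lam) / length(y),
    loglik = sum(stats::dpois(y, lam, log = TRUE)),
    converged = converged, iterations = it
  ), class = "ad_gee")
}

#' GEE for Poisson means with AR(1) working correlation
#'
#' Re-implementation of the estimator of the `geese`/`geeglm` routines
#' with `corstr = "ar1"` and estimated scale: alternates (a) Fisher
#' scoring for beta with working covariance A^{1/2} R(alpha) A^{1/2}
#' (A = diag of Poisson variances, R = AR(1)); (b) scale
#' phi = Sum z_ij^2 / N from Pearson residuals; (c) alpha solving the
#' all-pairs moment estimating equation
#' Sum_pairs (z_j z_k / phi - alpha^d) d alpha^(d-1) = 0, d the lag.
#' Naive (model-based) covariances: Cov(beta) = phi (Sum D'V^-1 D)^-1 and
#' Var(alpha) = 1 / Sum_pairs (d alpha^(d-1))^2.
#'
#' @param data An [ad_data] object; at least one subject needs 2+ visits.
#' @param tol Convergence tolerance on relative parameter change.
#' @param maxit Outer iteration cap.
#' @return A list of class `ad_gee` with `beta_hat`, `alpha_hat`,
#'   `naive_cov`, `valpha_naive`, `phi_hat`, `converged`, `iterations`.
#' @export
fit_gee_ar1 <- function(data, tol = 1e-8, maxit = 100L) {
  if (length(data$later) == 0L)
    stop("alpha inestimable: no subject has more than one visit",
         call. = FALSE)
  X <- data$X; y <- data$y
  rows <- split(seq_len(data$n_obs), match(data$subject, unique(data$subject)))
  p <- ncol(X)

  # all within-subject pair indices and lags, fixed across iterations
  pr1 <- integer(0); pr2 <- integer(0); lag <- integer(0)
  for (ix in rows) {
    n <- length(ix)
    if (n >= 2L) {
      cmb <- utils::combn(n, 2L)
      pr1 <- c(pr1, ix[cmb[1L, ]]); pr2 <- c(pr2, ix[cmb[2L, ]])
      lag <- c(lag, cmb[2L, ] - cmb[1L, ])
    }
  }

  beta <- fit_poisson(data)$beta_hat
  alpha <- 0; phi <- 1
  converged <- FALSE; it <- 0L
  for (it in seq_len(maxit)) {
    lam <- exp(drop(X %*% beta))
    # (a) one Fisher-scoring step for beta at current alpha
    H <- matrix(0, p, p); u <- numeric(p)
    for (ix in rows) {
      n <- length(ix)
      sl <- sqrt(lam[ix])
      R <- alpha^abs(outer(seq_len(n), seq_len(n), "-"))
      V <- outer(sl, sl) * R
      D <- lam[ix] * X[ix, , drop = FALSE]
      Vi <- solve(V)
      H <- H + crossprod(D, Vi %*% D)
      u <- u + crossprod(D, Vi %*% (y[ix] - lam[ix]))
    }
    beta_new <- beta + drop(solve(H, u))
    lam <- exp(drop(X %*% beta_new))
    z <- (y - lam) / sqrt(lam)
    # (b) scale
    phi <- sum(z^2) / length(z)
    # (c) alpha from all-pairs products scaled by phi
    s <- z[pr1] * z[pr2] / phi
    obj <- function(a) sum((s - a^lag)^2)
    alpha_new <- stats::optimize(obj, c(-0.99, 0.99), tol = 1e-10)$minimum
    step <- max(abs(beta_new - beta) / max(1, max(abs(beta))),
                abs(alpha_new - alpha))
    beta <- beta_new; alpha <- alpha_new
    if (step < tol) { converged <- TRUE; break }
  }
  alpha <- max(min(alpha, 0.99), -0.99)

  lam <- exp(drop(X %*% beta))
  H <- matrix(0, p, p)
  for (ix in rows) {
    n <- length(ix)
    sl <- sqrt(lam[ix])
    R <- alpha^abs(outer(seq_len(n), seq_len(n), "-"))
    V <- outer(sl, sl) * R
    D <- lam[ix] * X[ix, , drop = FALSE]
    H <- H + crossprod(D, solve(V, D))
  }
  drho <- lag * alpha^(lag - 1L)
  structure(list(
    beta_hat = unname(beta), alpha_hat = alpha,
    naive_cov = phi * solve(H),
    valpha_naive = 1 / sum(drho^2),
    phi_hat = phi,
    converged = converged, iterations = it
  ), class = "ad_gee")
}

#' @export
print.ad_gee <- function(x, ...) {
  cat("<ad_gee> Poisson marginal fit",
      if (x$alpha_hat != 0 || !is.na(x$valpha_naive)) "(AR(1) working correlation)"
      else "(independence)", "\n")
  est <- x$beta_hat
  se <- sqrt(diag(x$naive_cov))
  tab <- data.frame(Estimate = est, SE = se, check.names = FALSE)
  print(tab, digits = 4)
  cat("alpha:", format(x$alpha_hat, digits = 4))
  if (!is.na(x$valpha_naive))
    cat("  (naive SE ", format(sqrt(x$valpha_naive), digits = 4), ")", sep = "")
  cat("  phi:", format(x$phi_hat, digits = 4), "\n")
  invisible(x)
}

#' Pearson-residual dispersion diagnostic
#'
#' phi_hat = (1/m) Sum_i Z_i' Z_i / n_i with Pearson residuals
#' z_ij = (y_ij - lambda_ij) / sqrt(lambda_ij) at the supplied
#' coefficients.  Values well above 1 indicate overdispersion relative to
#' the Poisson working model.
#'
#' @param data An [ad_data] object.
#' @param beta_hat Fitted regression coefficients.
#' @return The scalar dispersion estimate (>= 0).
#' @export
dispersion_estimate <- function(data, beta_hat) {
  lam <- exp(drop(data$X %*% beta_hat))
  if (any(lam == 0)) stop("fitted mean of 0", call. = FALSE)
  z2 <- (data$y - lam)^2 / lam
  per <- tapply(z2, match(data$subject, unique(data$subject)), mean)
  mean(per)
}
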