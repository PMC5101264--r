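#' Starting values for the ML fit
#'
#' Tries GEE with AR(1) working correlation first; if the resulting
#' (beta, alpha) violates the validity constraints, the alpha start is
#' halved toward 0 until feasible.  If GEE itself fails (or no subject
#' has repeated visits) the Poisson MLE with alpha = 0 is used.
#'
#' @param data An [ad_data] object.
#' @return An [ad_params] start guaranteed feasible.
#' @export
initial_values <- function(data) {
  gee <- tryCatch(fit_gee_ar1(data), error = function(e) NULL)
  if (is.null(gee)) gee <- fit_poisson(data)
  beta <- gee$beta_hat
  alpha <- gee$alpha_hat
  bound <- alpha_bound(data, beta)
  # keep a margin inside the bound so the barrier has room
  while (alpha != 0 &&
         (!check_constraints(data, ad_params(beta, alpha))$feasible ||
          alpha >= 0.98 * bound)) {
    alpha <- alpha / 2
    if (abs(alpha) < 1e-8) { alpha <- 0; break }
  }
  ad_params(beta, alpha)
}

# barrier objective/gradient helpers (negated for optim minimization)
ad_barrier_fn <- function(theta, data, mu) {
  p <- data$p
  alpha <- theta[p + 1L]
  if (abs(alpha) >= 1) return(Inf)
  params <- list(beta = theta[seq_len(p)], alpha = alpha)
  kern <- ad_kernel(data, params)
  # non-finite values arise when BFGS probes overflow-large beta steps
  if (!all(is.finite(kern$slack)) || !all(is.finite(kern$lamstar)) ||
      any(kern$slack <= 0) || any(kern$lamstar <= 0)) return(Inf)
  y1 <- data$y[data$first]; lam1 <- kern$lam[data$first]
  yl <- data$y[data$later]
  ll <- sum(y1 * log(lam1) - lam1 - lgamma(y1 + 1)) +
    sum(yl * log(kern$lamstar) - kern$lamstar - lgamma(yl + 1))
  -(ll + mu * (sum(log(kern$slack)) + log(1 - alpha^2)))
}

ad_barrier_gr <- function(theta, data, mu) {
  p <- data$p
  alpha <- theta[p + 1L]
  params <- ad_params(theta[seq_len(p)], alpha)
  g <- ad_score(data, params)
  kern <- ad_kernel(data, params)
  # gradient of sum(log slack): slack = lam_j - alpha k sqrt(lam_j lam_p)
  Xj <- data$X[data$later, , drop = FALSE]
  Xp <- data$X[data$prev, , drop = FALSE]
  geo <- sqrt(kern$lam_j * kern$lam_p)
  inv_s <- 1 / kern$slack
  # d slack/d beta = lam_j x_j - alpha k geo (x_j + x_p)/2
  b1 <- kern$lam_j - alpha * kern$k * geo / 2   # on x_j
  b2 <- -alpha * kern$k * geo / 2               # on x_p
  g_b <- drop(crossprod(Xj, inv_s * b1) + crossprod(Xp, inv_s * b2))
  # d slack/d alpha = -geo * (k/(1-alpha^2) for j=2, 1 otherwise)
  dk <- ifelse(data$is_j2, kern$k / (1 - alpha^2), 1)
  g_a <- -sum(inv_s * geo * dk) - 2 * alpha / (1 - alpha^2)
  -(g + mu * c(g_b, g_a))
}

#' Maximum likelihood fit of the antedependent Poisson model
#'
#' Maximizes the joint log-likelihood subject to the validity constraints
#' by a logarithmic-barrier outer loop (barrier on every pair slack and on
#' 1 - alpha^2, weight decreased geometrically) with BFGS inner iterations
#' driven by the analytic score.  The asymptotic covariance is the inverse
#' observed information (negative Hessian) at the optimum.
#'
#' @param data An [ad_data] object.
#' @param start Optional [ad_params] start (default [initial_values]).
#' @param tol Outer convergence tolerance on the log-likelihood change.
#' @param outer_max Maximum barrier (outer) iterations.
#' @return An object of class `ad_fit`: `params_hat` ([ad_params]), `cov`
#'   ((p+1) x (p+1); row/column for alpha is `NA` when alpha is
#'   inestimable), `loglik`, `aic`, `bic`, `wald_table` (data frame:
#'   Estimate, SE, Wald, `Pr(>|W|)`), `converged`, `n_obs`, `iterations`,
#'   `grad_norm`, `alpha_fixed` (TRUE when no repeated visits forced
#'   alpha = 0).
#' @export
fit_ml <- function(data, start = NULL, tol = 1e-8, outer_max = 8L) {
  p <- data$p
  par_names <- c(colnames(data$X), "alpha")

  if (length(data$later) == 0L) {
    # no adjacent pairs: alpha inestimable, plain Poisson ML
    pois <- fit_poisson(data)
    k <- p
    cov <- matrix(NA_real_, p + 1L, p + 1L,
                  dimnames = list(par_names, par_names))
    cov[seq_len(p), seq_len(p)] <- pois$naive_cov
    est <- c(pois$beta_hat, 0)
    se <- sqrt(diag(cov))
    wald <- (est / se)^2
    out <- list(params_hat = ad_params(pois$beta_hat, 0), cov = cov,
                loglik = pois$loglik,
                aic = -2 * pois$loglik + 2 * k,
                bic = -2 * pois$loglik + k * log(data$n_obs),
                wald_table = data.frame(
                  Estimate = est, SE = se, Wald = wald,
                  `Pr(>|W|)` = stats::pchisq(wald, 1, lower.tail = FALSE),
                  row.names = par_names, check.names = FALSE),
                converged = pois$converged, n_obs = data$n_obs,
                iterations = pois$iterations,
                grad_norm = NA_real_, alpha_fixed = TRUE)
    return(structure(out, class = "ad_fit"))
  }

  if (is.null(start)) start <- initial_values(data)
  start <- as_ad_params(start, p)
  if (!check_constraints(data, start)$feasible)
    stop("no feasible start: supplied starting values violate the ",
         "validity constraints", call. = FALSE)

  theta <- c(start$beta, start$alpha)
  ll_prev <- ad_loglik(data, start)
  mu0 <- max(1e-4 * abs(ll_prev), 1e-8)
  converged <- FALSE
  iters <- 0L
  for (t in 0:(outer_max - 1L)) {
    mu <- mu0 * 0.1^t
    opt <- stats::optim(theta, ad_barrier_fn, ad_barrier_gr,
                        data = data, mu = mu, method = "BFGS",
                        control = list(maxit = 200L, reltol = 1e-12))
    theta <- opt$par
    iters <- iters + opt$counts[1L]
    ll <- ad_loglik(data, theta)
    if (abs(ll - ll_prev) < tol) { converged <- TRUE; ll_prev <- ll; break }
    ll_prev <- ll
  }
  params_hat <- as_ad_params(theta, p)
  grad <- ad_score(data, params_hat)

  info <- observed_information(data, params_hat)
  cov <- tryCatch(solve(info), error = function(e)
    stop("singular observed information at the optimum (condition ",
         format(kappa(info)), ")", call. = FALSE))
  cov <- (cov + t(cov)) / 2
  dimnames(cov) <- list(par_names, par_names)

  k <- p + 1L
  est <- c(params_hat$beta, params_hat$alpha)
  se <- sqrt(pmax(diag(cov), 0))
  wald <- (est / se)^2
  ic <- information_criteria(ll_prev, k, data$n_obs)
  out <- list(params_hat = params_hat, cov = cov, loglik = ll_prev,
              aic = ic[["aic"]], bic = ic[["bic"]],
              wald_table = data.frame(
                Estimate = est, SE = se, Wald = wald,
                `Pr(>|W|)` = stats::pchisq(wald, 1, lower.tail = FALSE),
                row.names = par_names, check.names = FALSE),
              converged = converged, n_obs = data$n_obs,
              iterations = as.integer(iters),
              grad_norm = max(abs(grad)), alpha_fixed = FALSE)
  structure(out, class = "ad_fit")
}

#' @export
print.ad_fit <- function(x, ...) {
  cat("Antedependent Poisson ML fit",
      if (!x$converged) "(NOT CONVERGED)", "\n")
  cat("log-likelihood:", format(x$loglik, digits = 7),
      "  AIC:", format(x$aic, digits = 6),
      "  BIC:", format(x$bic, digits = 6), "\n")
  cat("Coefficients:\n")
  p <- length(x$params_hat$beta)
  print(format_wald(x$wald_table[seq_len(p), , drop = FALSE]))
  cat("Correlation parameter:\n")
  print(format_wald(x$wald_table[p + 1L, 1:2, drop = FALSE]))
  if (x$alpha_fixed)
    cat("(alpha fixed at 0: no repeated visits; SE undefined)\n")
  invisible(x)
}

format_wald <- function(tab) {
  out <- tab
  for (j in seq_along(out)) out[[j]] <- signif(out[[j]], 4)
  out
}

#' Observed information matrix
#'
#' Negative Hessian of the log-likelihood, computed by central finite
#' differences of the analytic score with steps scaled to parameter
#' magnitude, then symmetrized.  Steps that would leave the feasible
#' region are shrunk.
#'
#' @param data An [ad_data] object.
#' @param params Feasible interior [ad_params] (or numeric vector).
#' @return Symmetric (p+1) x (p+1) matrix.
#' @export
observed_information <- function(data, params) {
  params <- as_ad_params(params, data$p)
  theta <- c(params$beta, params$alpha)
  q <- length(theta)
  H <- matrix(0, q, q)
  feasible_at <- function(th) {
    a <- th[q]
    if (abs(a) >= 1) return(FALSE)
    kern <- ad_kernel(data, list(beta = th[-q], alpha = a))
    all(kern$slack > 0) && all(kern$lamstar > 0)
  }
  for (k in seq_len(q)) {
    h <- 1e-5 * max(1, abs(theta[k]))
    repeat {
      tp <- theta; tp[k] <- tp[k] + h
      tm <- theta; tm[k] <- tm[k] - h
      if (feasible_at(tp) && feasible_at(tm)) break
      h <- h / 4
      if (h < 1e-12)
        stop("cannot difference the score: point too close to the ",
             "feasible boundary", call. = FALSE)
    }
    gp <- ad_score(data, as_ad_params(tp, data$p))
    gm <- ad_score(data, as_ad_params(tm, data$p))
    H[, k] <- (gp - gm) / (2 * h)
  }
  -(H + t(H)) / 2
}

#' Akaike and Bayesian information criteria
#'
#' aic = -2 loglik + 2k; bic = -2 loglik + k ln(n_obs).  For the ML model
#' k counts the p regression coefficients plus 1 for alpha; for plain
#' Poisson, k = p.  n_obs is the total number of observations (the
#' likelihood is a product over observations).
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters (>= 1).
#' @param n_obs Total observation count (>= 1).
#' @return Named numeric vector `c(aic, bic)`.
#' @export
information_criteria <- function(loglik, k, n_obs) {
  if (k < 1 || n_obs < 1 || k != round(k) || n_obs != round(n_obs))
    stop("k and n_obs must be positive integers", call. = FALSE)
  c(aic = -2 * loglik + 2 * k, bic = -2 * loglik + k * log(n_obs))
}

#' Likelihood ratio test for nested fits
#'
#' @param fit_full,fit_reduced `ad_fit` objects on the same data, the
#'   reduced model nested in the full.
#' @return List with `statistic` (2 * (l_full - l_reduced), clipped at 0),
#'   `df` (parameter-count difference) and `p_value` (chi-square upper
#'   tail).  Warns if the full fit has lower likelihood than the reduced
#'   beyond numerical tolerance.
#' @export
likelihood_ratio_test <- function(fit_full, fit_reduced) {
  if (fit_full$n_obs != fit_reduced$n_obs)
    stop("fits are not on the same data (n_obs differ)", call. = FALSE)
  df <- nrow(fit_full$wald_table) - nrow(fit_reduced$wald_table)
  if (df <= 0) stop("reduced model is not nested in full", call. = FALSE)
  delta <- fit_full$loglik - fit_reduced$loglik
  if (delta < -1e-6)
    warning("full model has lower log-likelihood than reduced; ",
            "check nesting/convergence")
  stat <- max(2 * delta, 0)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
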