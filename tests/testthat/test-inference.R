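test_that("information criteria arithmetic and input checks", {
  ic <- information_criteria(-10, 2, 100)
  expect_equal(ic[["aic"]], 24)
  expect_equal(ic[["bic"]], 20 + 2 * log(100))
  expect_error(information_criteria(-10, 0, 100), "positive integers")
  expect_error(information_criteria(-10, 2, 0), "positive integers")
})

test_that("likelihood ratio test statistic, df and chi-square tail", {
  f1 <- list(loglik = -100, n_obs = 50, wald_table = data.frame(x = 1:3))
  f0 <- list(loglik = -105, n_obs = 50, wald_table = data.frame(x = 1:2))
  lrt <- likelihood_ratio_test(f1, f0)
  expect_equal(lrt$statistic, 10)
  expect_equal(lrt$df, 1)
  expect_equal(lrt$p_value, pchisq(10, 1, lower.tail = FALSE))
  # identical fits: statistic 0, p = 1
  lrt0 <- likelihood_ratio_test(f1, list(loglik = -100, n_obs = 50,
                                         wald_table = data.frame(x = 1:2)))
  expect_equal(lrt0$statistic, 0)
  expect_equal(lrt0$p_value, 1)
  # df = 2 case
  f0b <- list(loglik = -100.5, n_obs = 50, wald_table = data.frame(x = 1))
  expect_equal(likelihood_ratio_test(f1, f0b)$p_value,
               pchisq(1, 2, lower.tail = FALSE))
  # full fit with lower likelihood than the reduced one: flagged
  f_bad <- list(loglik = -110, n_obs = 50, wald_table = data.frame(x = 1:3))
  expect_warning(likelihood_ratio_test(f_bad, f0), "nesting|lower")
})

test_that("observed information recovers known curvature for independent Poisson", {
  # at alpha = 0 the analytic information for beta is X' diag(lambda) X;
  # the finite-difference Hessian must recover it
  inst <- random_instance(m = 12L, seed = 11L, alpha = 0.0)
  dat <- inst$data
  beta <- inst$theta[1:3]
  lam <- exp(drop(dat$X %*% beta))
  H <- observed_information(dat, c(beta, 0))
  expect_equal(H[1:3, 1:3], unname(crossprod(dat$X * lam, dat$X)),
               tolerance = 1e-6)
  # and it matches double finite differences of the log-likelihood
  th <- inst$theta
  q <- length(th)
  H2 <- matrix(NA_real_, q, q)
  hstep <- 1e-4 * pmax(1, abs(th))
  for (a in 1:q) for (b in 1:q) {
    tpp <- th; tpp[a] <- tpp[a] + hstep[a]; tpp[b] <- tpp[b] + hstep[b]
    tpm <- th; tpm[a] <- tpm[a] + hstep[a]; tpm[b] <- tpm[b] - hstep[b]
    tmp <- th; tmp[a] <- tmp[a] - hstep[a]; tmp[b] <- tmp[b] + hstep[b]
    tmm <- th; tmm[a] <- tmm[a] - hstep[a]; tmm[b] <- tmm[b] - hstep[b]
    H2[a, b] <- (ad_loglik(dat, tpp) - ad_loglik(dat, tpm) -
                 ad_loglik(dat, tmp) + ad_loglik(dat, tmm)) /
      (4 * hstep[a] * hstep[b])
  }
  Hi <- observed_information(dat, th)
  expect_equal(Hi, -(H2 + t(H2)) / 2, tolerance = 1e-4)
})

test_that("ML fit at alpha = 0 truth matches the Poisson MLE closely", {
  set.seed(31)
  cfg <- sim_config(m = 120, alpha = 0)
  dat <- sim_counts(sim_covariates(cfg), cfg$beta, 0)
  fit <- fit_ml(dat)
  pois <- fit_poisson(dat)
  expect_true(fit$converged)
  expect_lt(abs(fit$params_hat$alpha), 0.05)
  expect_equal(fit$params_hat$beta, pois$beta_hat, tolerance = 5e-3)
  # optimum is at least as good as the start and (near-)stationary
  expect_gte(fit$loglik, ad_loglik(dat, initial_values(dat)) - 1e-8)
  expect_lt(fit$grad_norm, 0.5)
})

test_that("barrier does not perturb interior solutions beyond tolerance", {
  # small |alpha|: constraints far from active, so the constrained fit
  # must match an unconstrained BFGS optimum
  set.seed(33)
  cfg <- sim_config(m = 80, alpha = 0.2)
  dat <- sim_counts(sim_covariates(cfg), cfg$beta, 0.2)
  fit <- fit_ml(dat)
  free <- optim(c(fit$params_hat$beta, fit$params_hat$alpha),
                function(th) -ad_loglik(dat, th),
                function(th) -ad_score(dat, th),
                method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(fit$loglik, -free$value, tolerance = 1e-7)
  expect_equal(c(fit$params_hat$beta, fit$params_hat$alpha), free$par,
               tolerance = 1e-4)
})

test_that("initial values are always feasible, even when GEE overshoots", {
  set.seed(35)
  cfg <- sim_config(m = 40, alpha = 0.65)
  dat <- sim_counts(sim_covariates(cfg), cfg$beta, 0.65)
  start <- initial_values(dat)
  cc <- check_constraints(dat, start)
  expect_true(cc$feasible)
  expect_lt(start$alpha, cc$alpha_bound)
})

test_that("degenerate datasets are handled", {
  # single visit per subject: alpha fixed at 0, beta is the Poisson MLE
  d <- ad_data(y = c(2L, 3L, 4L), X = matrix(1, 3, 1),
               subject = 1:3, visit = rep(1L, 3))
  fit <- fit_ml(d)
  expect_true(fit$alpha_fixed)
  expect_equal(fit$params_hat$beta, log(3), tolerance = 1e-8)
  expect_true(is.na(fit$wald_table$SE[2]))
  # wald table structure
  expect_named(fit$wald_table, c("Estimate", "SE", "Wald", "Pr(>|W|)"))
  w <- fit$wald_table[1, ]
  expect_equal(w$Wald, (w$Estimate / w$SE)^2)
  expect_equal(w$`Pr(>|W|)`, pchisq(w$Wald, 1, lower.tail = FALSE))
})

test_that("infeasible starts are rejected", {
  d4 <- one_subject(c(1, 2, 1, 3))
  expect_error(fit_ml(d4, start = ad_params(0.5, 0.72)), "feasible")
})
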