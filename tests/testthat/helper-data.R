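# fixtures built in code: tiny deterministic datasets and random feasible
# instances for property-style tests

# single-subject dataset with an intercept-only design
one_subject <- function(y) {
  y <- as.integer(y)
  ad_data(y = y, X = matrix(1, length(y), 1), subject = rep(1L, length(y)),
          visit = seq_along(y))
}

# random feasible instance: m subjects, n visits, p covariates,
# model-simulated counts, and a feasible parameter point to evaluate at
random_instance <- function(m = 8L, n = 4L, seed = 1L, alpha = 0.3) {
  set.seed(seed)
  X1 <- cbind(1, stats::rbinom(m, 1, 0.5), round(stats::runif(m, -1, 1), 2))
  beta <- c(0.5, -0.2, 0.15)
  dat <- sim_counts(X1, beta, alpha, n)
  # evaluation point jittered off the truth but kept feasible
  repeat {
    theta <- c(beta + stats::rnorm(3, 0, 0.05),
               min(max(alpha + stats::rnorm(1, 0, 0.05), 0), 0.6))
    p <- ad_params(theta[1:3], theta[4])
    if (check_constraints(dat, p)$feasible &&
        all(ad_kernel_ok(dat, p))) break
  }
  list(data = dat, theta = theta)
}

# TRUE when every conditional mean is positive at params (needed because
# feasibility constraint (3) is the y = 0 case; a sampled y can still be
# fine while a jittered beta makes some lambda* non-positive)
ad_kernel_ok <- function(dat, params) {
  ok <- tryCatch({ ad_loglik(dat, params); TRUE },
                 error = function(e) FALSE)
  ok
}

# central finite differences of the log-likelihood
fd_score <- function(dat, theta, h0 = 1e-6) {
  sapply(seq_along(theta), function(k) {
    h <- h0 * max(1, abs(theta[k]))
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    (ad_loglik(dat, tp) - ad_loglik(dat, tm)) / (2 * h)
  })
}

# epilepsy seizure data (MASS::epil) in the standard four-period
# parameterisation: treatment, baseline count, age, period 1..4
epil_data <- function(period = TRUE) {
  data(epil, package = "MASS", envir = environment())
  ep <- epil[order(epil$subject, epil$period), ]
  X <- cbind(`(Intercept)` = 1, trt = as.integer(ep$trt == "progabide"),
             base = ep$base, age = ep$age, period = ep$period)
  if (!period) X <- X[, 1:4]
  ad_data(y = ep$y, X = X, subject = ep$subject, visit = ep$period)
}
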