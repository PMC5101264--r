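#' Simulation configuration
#'
#' Defaults reproduce the epilepsy-calibrated design: two equal treatment
#' groups of m/2, 4 equally spaced visits, linear predictor
#' beta0 + beta1 treatment + beta2 baseline + beta3 age with
#' beta = (0.4467, -0.1659, 0.0232, 0.0258), baseline seizure count
#' Poisson with mean 31.22, age truncated normal (mean 28.3, sd 6.261,
#' minimum 18, rounded to whole years).
#'
#' @param m Number of subjects (even; two equal groups of m/2).
#' @param alpha Adjacent correlation, in [0, 1) and strictly below the
#'   design's feasibility bound (0.707 for the default design).
#' @param beta Regression coefficients (intercept, treatment, baseline, age).
#' @param n_per_subject Visits per subject.
#' @param baseline_mean Poisson mean of the baseline count covariate.
#' @param age_mean,age_sd,age_min Truncated-normal age distribution.
#' @param R Number of replicates for [run_study].
#' @param seed Master seed (integer).
#' @return A validated list of class `ad_sim_config`.
#' @export
sim_config <- function(m = 60L, alpha = 0.2,
                       beta = c(0.4467, -0.1659, 0.0232, 0.0258),
                       n_per_subject = 4L,
                       baseline_mean = 31.22,
                       age_mean = 28.3, age_sd = 6.261, age_min = 18,
                       R = 1000L, seed = 1L) {
  if (m < 2 || m %% 2 != 0) stop("m must be even and >= 2", call. = FALSE)
  if (alpha < 0 || alpha >= 1)
    stop("the simulator requires alpha in [0, 1): for alpha < 0 the ",
         "conditional mean can go negative for large previous counts",
         call. = FALSE)
  if (n_per_subject < 1) stop("n_per_subject must be >= 1", call. = FALSE)
  if (baseline_mean <= 0 || age_sd <= 0) stop("invalid covariate scales",
                                              call. = FALSE)
  if (R < 1) stop("R must be >= 1", call. = FALSE)
  structure(list(m = as.integer(m), alpha = alpha, beta = as.numeric(beta),
                 n_per_subject = as.integer(n_per_subject),
                 baseline_mean = baseline_mean, age_mean = age_mean,
                 age_sd = age_sd, age_min = age_min,
                 R = as.integer(R), seed = as.integer(seed)),
            class = "ad_sim_config")
}

#' Simulate subject-level covariates
#'
#' Treatment is 1 for the first m/2 subjects and 0 otherwise (group sizes
#' exact by construction); baseline count is one Poisson draw per subject;
#' age is normal with draws below `age_min` discarded and redrawn, then
#' rounded to a whole number.  Covariates are constant across a subject's
#' visits.
#'
#' @param cfg An [ad_sim_config].
#' @return An m x 4 matrix with columns (Intercept, treatment, baseline, age).
#' @export
sim_covariates <- function(cfg) {
  m <- cfg$m
  trt <- rep(c(1, 0), each = m / 2)
  base <- stats::rpois(m, cfg$baseline_mean)
  age <- numeric(m)
  need <- seq_len(m)
  while (length(need)) {
    draw <- stats::rnorm(length(need), cfg$age_mean, cfg$age_sd)
    ok <- draw >= cfg$age_min
    age[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  age <- round(age)
  cbind(`(Intercept)` = 1, treatment = trt, baseline = base, age = age)
}

#' Simulate antedependent Poisson count series
#'
#' Exactly the likelihood's data-generating process: Y_i1 ~ Poisson(
#' lambda_i1); for j >= 2, Y_ij | Y_ij-1 ~ Poisson(lambda*_ij) with
#' lambda*_ij from [conditional_mean].  Refuses designs that violate
#' validity constraint (3) (which for alpha >= 0 guarantees
#' lambda* > 0 for every attainable previous count).
#'
#' @param X Subject-level covariate matrix (one row per subject), as from
#'   [sim_covariates].
#' @param beta Regression coefficients.
#' @param alpha Adjacent correlation in [0, 1).
#' @param n_per_subject Number of visits.
#' @return An [ad_data] with `n_per_subject` visits per subject.
#' @export
sim_counts <- function(X, beta, alpha, n_per_subject = 4L) {
  if (alpha < 0 || alpha >= 1)
    stop("simulator requires alpha in [0, 1)", call. = FALSE)
  m <- nrow(X)
  n <- as.integer(n_per_subject)
  lam <- exp(drop(X %*% beta))  # covariates constant over visits
  if (n >= 2L && alpha > 0) {
    # constant means within subject: slack is lam (1 - alpha k); k depends on j
    k2 <- 1 / sqrt(1 - alpha^2)
    if (any(lam * (1 - alpha * k2) <= 0) || alpha >= 1)
      stop("design violates validity constraint (3): alpha = ", alpha,
           " is not below the design bound ",
           format(1 / sqrt(2), digits = 4), call. = FALSE)
  }
  Y <- matrix(0L, m, n)
  Y[, 1L] <- stats::rpois(m, lam)
  if (n >= 2L) {
    sd_first <- sqrt(lam)
    sd_later <- sqrt(lam / (1 - alpha^2))
    for (j in 2:n) {
      sd_prev <- if (j == 2L) sd_first else sd_later
      lamstar <- conditional_mean(lam, lam, sd_later, sd_prev,
                                  Y[, j - 1L], alpha)
      Y[, j] <- stats::rpois(m, lamstar)
    }
  }
  idx <- rep(seq_len(m), each = n)
  ad_data(y = as.vector(t(Y)),
          X = X[idx, , drop = FALSE],
          subject = idx,
          visit = rep(seq_len(n), m))
}
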