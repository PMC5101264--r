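test_that("marginal mean is exp(x'beta) and validates dimensions", {
  expect_equal(marginal_mean(c(1, 0, 0, 0), rep(0, 4)), 1)
  expect_equal(marginal_mean(c(1, 2, -3), rep(0, 3)), 1)
  b <- c(0.4467, -0.1659, 0.0232, 0.0258)
  x <- c(1, 1, 31, 28)
  expect_equal(marginal_mean(x, b), exp(sum(x * b)))
  expect_equal(marginal_mean(x, b), exp(1.722), tolerance = 1e-3)
  expect_error(marginal_mean(c(1, 2), c(1, 2, 3)), "same length")
})

test_that("marginal sd handles first vs later visits and rejects |alpha| >= 1", {
  expect_equal(marginal_sd(4, 0.6, is_first_visit = TRUE), 2)
  expect_equal(marginal_sd(4, 0, is_first_visit = FALSE), 2)
  expect_equal(marginal_sd(4, 0.6, is_first_visit = FALSE), 2.5)
  expect_error(marginal_sd(4, 1, FALSE), "alpha")
  expect_error(marginal_sd(-1, 0.2, TRUE), "positive")
})

test_that("conditional mean follows the linear antedependence formula", {
  # alpha = 0 and y_prev = lam_prev both collapse to the marginal mean
  expect_equal(conditional_mean(2, 5, 1.5, 2.5, 7, 0), 2)
  expect_equal(conditional_mean(2, 5, 1.5, 2.5, 5, 0.4), 2)
  # j >= 3 with equal means: sd ratio 1
  expect_equal(conditional_mean(2, 2, 1, 1, 4, 0.5), 3)
  # j = 2: previous visit Poisson, current overdispersed
  sd1 <- marginal_sd(2, 0.5, TRUE)
  sd2 <- marginal_sd(2, 0.5, FALSE)
  expect_equal(conditional_mean(2, 2, sd2, sd1, 0, 0.5),
               2 - 0.5 * 2 / sqrt(0.75), tolerance = 1e-12)
})

test_that("log-likelihood matches hand-computed values", {
  expect_equal(ad_loglik(one_subject(0), c(0, 0)), -1)
  expect_equal(ad_loglik(one_subject(c(1, 1)), c(0, 0)), -2)
  d <- one_subject(c(0, 1))
  lamstar <- 1 - 0.5 / sqrt(0.75)
  expect_equal(ad_loglik(d, c(0, 0.5)), -1 + log(lamstar) - lamstar)
  expect_error(ad_loglik(d, c(0, 1)), "alpha")
})

test_that("at alpha = 0 the log-likelihood is the independent Poisson one", {
  for (seed in 1:4) {
    inst <- random_instance(m = 6L, n = 3L, seed = seed, alpha = 0.4)
    dat <- inst$data
    beta <- inst$theta[1:3]
    lam <- exp(drop(dat$X %*% beta))
    expect_equal(ad_loglik(dat, c(beta, 0)),
                 sum(dpois(dat$y, lam, log = TRUE)))
  }
})

test_that("log-likelihood is invariant to permuting subjects", {
  inst <- random_instance(m = 7L, seed = 5L)
  dat <- inst$data
  set.seed(9)
  perm <- sample(unique(dat$subject))
  ord <- order(match(dat$subject, perm), dat$visit)
  dat2 <- ad_data(dat$y[ord], dat$X[ord, , drop = FALSE],
                  dat$subject[ord], dat$visit[ord])
  expect_equal(ad_loglik(dat2, inst$theta), ad_loglik(dat, inst$theta))
  expect_equal(ad_score(dat2, inst$theta), ad_score(dat, inst$theta))
})

test_that("analytic score agrees with finite differences on random instances", {
  for (seed in 1:6) {
    inst <- random_instance(m = 8L, n = 4L, seed = seed,
                            alpha = c(0.1, 0.3, 0.5)[seed %% 3 + 1])
    g <- ad_score(inst$data, inst$theta)
    fd <- fd_score(inst$data, inst$theta)
    expect_lt(max(abs(g - fd) / pmax(1, abs(fd))), 1e-6)
  }
})

test_that("at alpha = 0 the beta score is the independent Poisson score", {
  inst <- random_instance(m = 10L, seed = 7L)
  dat <- inst$data
  beta <- inst$theta[1:3]
  lam <- exp(drop(dat$X %*% beta))
  g <- ad_score(dat, c(beta, 0))
  expect_equal(g[1:3], drop(crossprod(dat$X, dat$y - lam)))
})

test_that("constraint checking and the feasible-alpha bound", {
  d4 <- one_subject(rep(0, 4))
  # alpha = 0 always feasible with slacks = lambda
  cc <- check_constraints(d4, c(0.3, 0))
  expect_true(cc$feasible)
  expect_equal(unname(cc$slacks), rep(exp(0.3), 3))
  # equal means across 4 visits: bound is 1/sqrt(2)
  expect_equal(alpha_bound(d4, 0), 1 / sqrt(2), tolerance = 1e-9)
  expect_equal(alpha_bound(d4, 1.7), 1 / sqrt(2), tolerance = 1e-9)
  # single pair with means (1, 4): bound solves a/sqrt(1-a^2) = 2
  db <- ad_data(c(0L, 0L), cbind(1, c(0, 1)), c(1, 1), 1:2)
  oracle <- uniroot(function(a) a / sqrt(1 - a^2) - 2, c(0, 0.999),
                    tol = 1e-12)$root
  expect_equal(alpha_bound(db, c(0, log(4))), oracle, tolerance = 1e-9)
  expect_equal(oracle, 2 / sqrt(5), tolerance = 1e-9)
  # infeasible above the bound, feasible below
  expect_false(check_constraints(d4, c(0, 0.71))$feasible)
  expect_true(check_constraints(d4, c(0, 0.70))$feasible)
  # no adjacent pairs: bound is 1
  expect_equal(alpha_bound(one_subject(3), 0), 1)
})

test_that("alpha bound is monotone non-increasing in the mean ratio at j = 2", {
  # means (lam1, 1): increasing lam1/lam2 tightens the bound
  ratios <- c(0.5, 1, 2, 4, 8)
  bounds <- sapply(ratios, function(r) {
    db <- ad_data(c(0L, 0L), cbind(1, c(1, 0)), c(1, 1), 1:2)
    alpha_bound(db, c(0, log(r)))
  })
  expect_true(all(diff(bounds) <= 1e-10))
})

test_that("dataset validation catches malformed input", {
  expect_error(ad_data(c(1, -1), matrix(1, 2, 1), c(1, 1), 1:2),
               "non-negative")
  expect_error(ad_data(c(1, 2.5), matrix(1, 2, 1), c(1, 1), 1:2),
               "integer")
  expect_error(ad_data(c(1L, 2L), matrix(1, 2, 1), c(1, 1), c(1, 3)),
               "consecutive")
  expect_error(ad_data(c(1L, 2L), matrix(1, 2, 1), c(1, 1), c(1, 1)),
               "duplicated")
  expect_error(ad_params(c(0, 1), 1.2), "alpha")
})
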