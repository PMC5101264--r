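#' Check the likelihood validity constraints
#'
#' The constructed likelihood is valid only if (1) every marginal mean is
#' positive (automatic under the log link), (2) |alpha| < 1, and (3) for
#' every adjacent pair the slack
#' lambda_ij - alpha (sigma_ij / sigma_ij-1) lambda_ij-1 is strictly
#' positive (the worst case y_ij-1 = 0 for alpha >= 0).
#'
#' @param data An [ad_data] object.
#' @param params An [ad_params] object or numeric vector `c(beta, alpha)`.
#' @return A list of class `ad_constraints`: `feasible` (logical),
#'   `slacks` (numeric, one per adjacent pair), and `alpha_bound`, the
#'   supremum of non-negative alpha satisfying constraint (3) at this beta
#'   (1 when the dataset has no adjacent pairs).
#' @export
check_constraints <- function(data, params) {
  params <- as_ad_params(params, data$p)
  kern <- ad_kernel(data, params)
  feasible <- abs(params$alpha) < 1 && all(kern$slack > 0)
  structure(list(feasible = feasible, slacks = kern$slack,
                 alpha_bound = alpha_bound(data, params$beta)),
            class = "ad_constraints")
}

#' @export
print.ad_constraints <- function(x, ...) {
  cat("<ad_constraints> feasible:", x$feasible,
      " min slack:", if (length(x$slacks)) format(min(x$slacks)) else NA,
      " alpha bound:", format(x$alpha_bound), "\n")
  invisible(x)
}

#' Supremum of the feasible adjacent correlation
#'
#' Largest alpha in (0, 1) for which constraint (3) holds for every
#' adjacent pair at the given beta.  The minimal slack is continuous and
#' strictly decreasing in alpha on [0, 1), so the bound is found by
#' bisection (tolerance 1e-10).  With equal means at all visits of a
#' 4-visit design the bound is 1/sqrt(2) (the visit-2 pair requires
#' alpha / sqrt(1 - alpha^2) < 1).
#'
#' @param data An [ad_data] object.
#' @param beta Regression coefficient vector.
#' @return The bound in (0, 1]; exactly 1 if no subject has 2+ visits.
#' @export
alpha_bound <- function(data, beta) {
  if (length(data$later) == 0L) return(1)
  lam <- exp(drop(data$X %*% beta))
  lam_j <- lam[data$later]
  lam_p <- lam[data$prev]
  is_j2 <- data$is_j2
  geo <- sqrt(lam_j * lam_p)  # alpha * k * geo is the subtracted term
  min_slack <- function(a) {
    k <- ifelse(is_j2, 1 / sqrt(1 - a^2), 1)
    min(lam_j - a * k * geo)
  }
  if (min_slack(1 - 1e-12) > 0) return(1)
  lo <- 0; hi <- 1 - 1e-12
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (min_slack(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
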