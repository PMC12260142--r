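#' One-sided z-test for a normal effect summary
#'
#' Defines the frequentist test of \eqn{H_0: \theta \le \theta_0} versus
#' \eqn{H_1: \theta > \theta_0} based on the sample mean
#' \eqn{\bar X_n \sim N(\theta, \sigma^2/n)} with known \eqn{\sigma}. The
#' rejection region is \eqn{\{\bar x_n > \theta_0 + \sigma z_{1-\alpha}/\sqrt n\}}.
#' In the log-odds-ratio application \eqn{\sigma^2 = 4}, so that `n` counts the
#' effective number of observations (total events across arms).
#'
#' Only "greater" alternatives are represented; a "less" direction is obtained
#' by flipping the sign of the effect scale before constructing the test.
#'
#' @param theta0 boundary value of the effect scale (default 0).
#' @param alpha one-sided significance level, in (0, 1).
#' @param sigma known per-observation sampling standard deviation (> 0).
#' @return An object of class `"one_sided_test"`.
#' @examples
#' tst <- one_sided_test(theta0 = 0, alpha = 0.05, sigma = 2)
#' test_power(tst, theta = 0.372, n = 500)
#' @export
one_sided_test <- function(theta0 = 0, alpha = 0.05, sigma = 2) {
  if (!is.numeric(theta0) || length(theta0) != 1L || is.na(theta0))
    stop("'theta0' must be a single number", call. = FALSE)
  .check_prob(alpha, "alpha")
  .check_pos_scalar(sigma, "sigma")
  structure(list(theta0 = theta0, alpha = alpha, sigma = sigma),
            class = "one_sided_test")
}

#' @export
print.one_sided_test <- function(x, ...) {
  cat("One-sided z-test: H0: theta <=", x$theta0,
      " vs  H1: theta >", x$theta0, "\n")
  cat(sprintf("  alpha = %g (one-sided), sigma = %g (sigma^2 = %g)\n",
              x$alpha, x$sigma, x$sigma^2))
  invisible(x)
}

.crit <- function(test) qnorm(1 - test$alpha)

#' Power function of the one-sided test
#'
#' \eqn{\eta_n(\theta) = \Phi(\sqrt n (\theta - \theta_0)/\sigma - z_{1-\alpha})},
#' the probability of rejecting \eqn{H_0} when the true effect is `theta`.
#' Equals `alpha` at `theta = theta0` for every `n`.
#'
#' @param test a [one_sided_test()].
#' @param theta effect value(s).
#' @param n sample size(s), positive integer(s); recycled against `theta`.
#' @param sigma optional override of the test's sampling SD (used when a
#'   variance prior supplies per-draw values of \eqn{\sigma}).
#' @return Rejection probabilities in \[0, 1\].
#' @export
test_power <- function(test, theta, n, sigma = NULL) {
  stopifnot(inherits(test, "one_sided_test"))
  n <- .check_n(n)
  s <- if (is.null(sigma)) test$sigma else sigma
  if (any(s <= 0)) stop("'sigma' must be positive", call. = FALSE)
  pnorm(sqrt(n) * (theta - test$theta0) / s - .crit(test))
}

#' Type I error function
#'
#' Defined only on the null region \eqn{\theta \le \theta_0}, where it equals
#' the power function.
#'
#' @inheritParams test_power
#' @export
type1_error <- function(test, theta, n) {
  stopifnot(inherits(test, "one_sided_test"))
  if (any(theta > test$theta0))
    stop("type I error is defined only for theta <= theta0", call. = FALSE)
  test_power(test, theta, n)
}

#' Type II error function
#'
#' Defined only on the alternative \eqn{\theta > \theta_0}, where it equals
#' one minus the power function.
#'
#' @inheritParams test_power
#' @export
type2_error <- function(test, theta, n) {
  stopifnot(inherits(test, "one_sided_test"))
  if (any(theta <= test$theta0))
    stop("type II error is defined only for theta > theta0", call. = FALSE)
  1 - test_power(test, theta, n)
}

#' Expected 0-1 utility of the test decision
#'
#' The probability of choosing the true hypothesis:
#' \eqn{U_n(\theta) = 1 - \eta_n(\theta)} on the null region and
#' \eqn{U_n(\theta) = \eta_n(\theta)} on the alternative. Tends to 1 as
#' \eqn{n \to \infty} for every \eqn{\theta \neq \theta_0} (size-\eqn{\alpha}
#' consistency).
#'
#' @inheritParams test_power
#' @export
expected_utility <- function(test, theta, n, sigma = NULL) {
  eta <- test_power(test, theta, n, sigma = sigma)
  ifelse(theta > test$theta0, eta, 1 - eta)
}

#' Bayes risk from Bayes utility
#'
#' Under 0-1 utility the Bayes risk of the test is the complement of its
#' Bayes utility, \eqn{r_n = 1 - u_n}.
#'
#' @param u Bayes utility value(s) in \[0, 1\].
#' @export
bayes_risk <- function(u) {
  if (!is.numeric(u) || any(is.na(u)) || any(u < 0 | u > 1))
    stop("'u' must lie in [0, 1]", call. = FALSE)
  1 - u
}
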