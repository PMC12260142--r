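#' Default thresholds for the sample-size criteria
#'
#' The application rule sets each threshold to a fraction (80% by default) of
#' the measure's maximum reachable value: \eqn{\varepsilon_u = \varepsilon_b
#' = f} (both measures tend to 1) and \eqn{\varepsilon_a = \varepsilon_c =
#' f\,p_1} (both tend to the prior alternative mass \eqn{p_1}), with
#' \eqn{p_1} computed from the exact prior CDF.
#'
#' @param prior a design prior.
#' @param fraction fraction of the reachable maximum, in (0, 1).
#' @param theta0 null boundary (default 0).
#' @return named list of thresholds `u`, `a`, `b`, `c`.
#' @export
pos_thresholds <- function(prior, fraction = 0.8, theta0 = 0) {
  .check_prob(fraction, "fraction")
  p1 <- 1 - prob_null(prior, theta0)
  list(u = fraction, a = fraction * p1, b = fraction, c = fraction * p1)
}

#' Sample size determination from a PoS measure
#'
#' Finds the minimal integer `n` at which the chosen measure reaches the
#' threshold `epsilon`: \eqn{n^\star = \min\{n : m_n \ge \varepsilon\}}.
#' Feasibility is checked first against the measure's large-sample limit
#' ([pos_limits()]): for measures `a` and `c` a threshold at or above
#' \eqn{p_1} is provably infeasible and no search is run. The search brackets
#' the crossing by doubling `n`, bisects (the quadrature curves are
#' nondecreasing in `n` beyond small `n`), and certifies minimality with a
#' short backward scan. With `method = "mc"` a single common draw set
#' evaluates every `n`, so the estimated curve is smooth and the paired
#' comparisons across `n` are noise-free.
#'
#' @param test a [one_sided_test()].
#' @param prior a design prior.
#' @param measure `"u"`, `"a"`, `"b"` or `"c"`.
#' @param epsilon threshold in (0, 1).
#' @param method `"quadrature"` (default, deterministic) or `"mc"`.
#' @param M,seed Monte Carlo settings for `method = "mc"`.
#' @param n_max search cap (default `1e6`); reaching it yields an
#'   "infeasible at cap" result, distinct from provable infeasibility.
#' @return An object of class `"pos_ssd"`: `n_star` (NA if infeasible),
#'   `value` (measure at `n_star`), `feasible`, `reason`, `limit`, and a
#'   `trace` data frame of every `(n, value)` pair examined.
#' @examples
#' tst <- one_sided_test()
#' pos_ssd(tst, point_prior(0.372), measure = "u", epsilon = 0.8)
#' @export
pos_ssd <- function(test, prior, measure = c("u", "a", "b", "c"), epsilon,
                    method = c("quadrature", "mc"), M = 1e6, seed = NULL,
                    n_max = 1e6) {
  stopifnot(inherits(test, "one_sided_test"), inherits(prior, "design_prior"))
  measure <- match.arg(measure)
  method <- match.arg(method)
  .check_prob(epsilon, "epsilon")
  n_max <- .check_n(n_max, "n_max")

  lim <- pos_limits(test, prior)[[switch(measure, u = "u", a = "e_a",
                                         b = "e_b", c = "e_c")]]
  mk_result <- function(n_star, value, feasible, reason, trace) {
    structure(list(n_star = n_star, value = value, feasible = feasible,
                   reason = reason, limit = lim, epsilon = epsilon,
                   measure = measure, method = method,
                   M = if (method == "mc") M else NA_real_, seed = seed,
                   trace = trace, test = test, prior = prior),
              class = "pos_ssd")
  }
  if (measure %in% c("a", "c") && epsilon >= lim)
    return(mk_result(NA_integer_, NA_real_, FALSE, "limit_infeasible",
                     data.frame(n = numeric(0), value = numeric(0))))

  key <- switch(measure, u = "u", a = "e_a", b = "e_b", c = "e_c")
  if (method == "mc") {
    theta <- simulate(prior, nsim = .check_n(M, "M"), seed = seed)
    f <- function(n) .mc_from_draws(test, theta, n)[[key]]
  } else {
    f <- function(n) {
      if (inherits(prior, "point_prior")) .pos_point(test, prior, n,
                                                    "quadrature", M, NULL)[[key]]
      else .pos_quad(test, prior, n)[[key]]
    }
  }

  trace_n <- numeric(0); trace_v <- numeric(0)
  fm <- function(n) {
    v <- f(n)
    trace_n <<- c(trace_n, n); trace_v <<- c(trace_v, v)
    v
  }

  # exponential bracketing
  n <- 1
  v <- fm(n)
  if (is.na(v)) v <- -Inf
  while (v < epsilon) {
    if (n >= n_max)
      return(mk_result(NA_integer_, NA_real_, FALSE, "cap_reached",
                       data.frame(n = trace_n, value = trace_v)))
    lo <- n
    n <- min(2 * n, n_max)
    v <- fm(n)
    if (is.na(v)) v <- -Inf
  }
  if (n > 1) {
    # bisection: f(hi) >= epsilon, f(lo) < epsilon
    hi <- n; lo <- n %/% 2
    while (hi - lo > 1) {
      mid <- (lo + hi) %/% 2
      vm <- fm(mid)
      if (!is.na(vm) && vm >= epsilon) hi <- mid else lo <- mid
    }
    n <- hi
  }
  # backward scan certifies minimality against local wiggle
  steps <- 0
  while (n > 1 && steps < 64) {
    vprev <- fm(n - 1)
    if (is.na(vprev) || vprev < epsilon) break
    n <- n - 1
    steps <- steps + 1
  }
  mk_result(as.integer(n), f(n), TRUE, "ok",
            data.frame(n = trace_n, value = trace_v))
}

#' @export
print.pos_ssd <- function(x, ...) {
  cat(sprintf("Sample size for measure '%s' at threshold %.4g (%s)\n",
              x$measure, x$epsilon, x$method))
  if (x$feasible)
    cat(sprintf("  n* = %d  (measure = %.4f, limit = %.4f)\n",
                x$n_star, x$value, x$limit))
  else if (x$reason == "limit_infeasible")
    cat(sprintf("  infeasible: threshold %.4g >= limiting value %.4g\n",
                x$epsilon, x$limit))
  else
    cat(sprintf("  not reached below n_max (limit = %.4g)\n", x$limit))
  invisible(x)
}
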