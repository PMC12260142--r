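# Evaluation of the four probability-of-success measures.
#
# Quadrature is the deterministic reference: each prior decomposes into
# smooth components, and each component is integrated separately on the null
# and alternative regions (the utility integrand kinks at theta0), with
# break points at the prior's own scale and at the power function's
# transition scale sigma/sqrt(n) so that very large n stays accurate.

.integrate_region <- function(g, lower, upper, pts, rel.tol = 1e-10) {
  pts <- sort(unique(c(lower, upper, pts[pts > lower & pts < upper])))
  tot <- 0
  for (i in seq_len(length(pts) - 1L)) {
    r <- tryCatch(
      integrate(g, pts[i], pts[i + 1L], rel.tol = rel.tol, abs.tol = 1e-13,
                subdivisions = 400L),
      error = function(e)
        stop(sprintf("quadrature failed on [%g, %g]: %s",
                     pts[i], pts[i + 1L], conditionMessage(e)), call. = FALSE))
    tot <- tot + r$value
  }
  tot
}

# integrals i0 = int_{O0} (1-eta) pi, j0 = int_{O0} eta pi, i1 = int_{O1} eta pi
.quad_measures <- function(test, prior, n) {
  th0 <- test$theta0
  se_n <- test$sigma / sqrt(n)
  i0 <- j0 <- i1 <- 0
  eta <- function(t) test_power(test, t, n)
  for (cmp in .components(prior)) {
    pts <- c(cmp$loc + c(-10, -4, -1, 0, 1, 4, 10) * cmp$scale,
             th0 + c(-40, -3, 3, 40) * se_n)
    if (cmp$lower < th0) {
      lo <- cmp$lower; hi <- min(th0, cmp$upper)
      i0 <- i0 + cmp$w *
        .integrate_region(function(t) (1 - eta(t)) * cmp$dens(t), lo, hi, pts)
      j0 <- j0 + cmp$w *
        .integrate_region(function(t) eta(t) * cmp$dens(t), lo, hi, pts)
    }
    if (cmp$upper > th0) {
      lo <- max(th0, cmp$lower); hi <- cmp$upper
      i1 <- i1 + cmp$w *
        .integrate_region(function(t) eta(t) * cmp$dens(t), lo, hi, pts)
    }
  }
  list(i0 = i0, j0 = j0, i1 = i1)
}

.new_pos <- function(fields) structure(fields, class = "pos")

#' Probability-of-success measures of a planned trial
#'
#' Evaluates, at sample size `n`, the Bayes utility `u` (u-PoS) and the three
#' hybrid measures `e_a`, `e_b`, `e_c` (assurance) of the one-sided test
#' under a design prior, together with the decomposition into the prior null
#' mass `p0` and the conditional Bayes utilities `u0`
#' (\eqn{u_{n0}}, expected correct acceptance under the null-restricted
#' prior) and `u1` (\eqn{u_{n1}}, expected power under the
#' alternative-restricted prior).
#'
#' `method = "quadrature"` integrates the prior density on each side of
#' `theta0` (deterministic; the identities \eqn{e^a = p_1 u_{n1}},
#' \eqn{e^b = u_{n1}}, \eqn{e^c = p_0(1-u_{n0}) + p_1 u_{n1}},
#' \eqn{u = p_0 u_{n0} + p_1 u_{n1}} hold to quadrature accuracy).
#' `method = "mc"` averages over `M` seeded draws from the prior; all four
#' measures use one common draw set, `e_b` uses the ratio estimator with the
#' empirical alternative mass \eqn{\bar p_1}, and Monte Carlo standard errors
#' are returned in `$se`. If no draw lands in the alternative, `e_b` is
#' undefined (`NA`) with a warning.
#'
#' With a `variance_prior` (Monte Carlo only, normal priors only) each draw
#' \eqn{\sigma^{2(r)}} enters both the prior scale and the power function.
#'
#' @param test a [one_sided_test()].
#' @param prior a design prior (see [design_priors]).
#' @param n sample size (positive integer).
#' @param method `"quadrature"` (default) or `"mc"`.
#' @param M number of Monte Carlo draws (default `1e6`).
#' @param seed integer seed for `method = "mc"`, or `NULL`.
#' @param variance_prior optional [inv_gamma_prior()] / [fixed_variance()]
#'   on \eqn{\sigma^2}.
#' @return An object of class `"pos"`; see also [coef.pos()].
#' @examples
#' tst <- one_sided_test()
#' pos(tst, normal_prior(0.198, 46), n = 100)
#' @export
pos <- function(test, prior, n, method = c("quadrature", "mc"),
                M = 1e6, seed = NULL, variance_prior = NULL) {
  stopifnot(inherits(test, "one_sided_test"), inherits(prior, "design_prior"))
  n <- .check_n(n)
  stopifnot(length(n) == 1L)
  method <- match.arg(method)
  if (!is.null(variance_prior)) {
    if (method != "mc")
      stop("a variance prior requires method = \"mc\"", call. = FALSE)
    return(.pos_mc_vprior(test, prior, n, M, seed, variance_prior))
  }
  if (inherits(prior, "point_prior"))
    return(.pos_point(test, prior, n, method, M, seed))
  if (method == "quadrature") .pos_quad(test, prior, n)
  else .pos_mc(test, prior, n, M, seed)
}

.pos_point <- function(test, prior, n, method, M, seed) {
  eta <- test_power(test, prior$theta_d, n)
  in_alt <- prior$theta_d > test$theta0
  p0 <- as.numeric(!in_alt)
  if (in_alt)
    res <- list(u = eta, e_a = eta, e_b = eta, e_c = eta, u0 = NA_real_,
                u1 = eta)
  else
    res <- list(u = 1 - eta, e_a = 0, e_b = NA_real_, e_c = eta, u0 = 1 - eta,
                u1 = NA_real_)
  se <- if (method == "mc") c(u = 0, e_a = 0, e_b = 0, e_c = 0) else NULL
  .new_pos(c(res, list(p0 = p0, p1 = 1 - p0, n = n, method = method,
                       M = if (method == "mc") M else NA_real_, seed = seed,
                       se = se, test = test, prior = prior)))
}

.pos_quad <- function(test, prior, n) {
  q <- .quad_measures(test, prior, n)
  p0 <- prob_null(prior, test$theta0)
  p1 <- 1 - p0
  .new_pos(list(u = q$i0 + q$i1, e_a = q$i1,
                e_b = if (p1 > 0) q$i1 / p1 else NA_real_,
                e_c = q$j0 + q$i1,
                u0 = if (p0 > 0) q$i0 / p0 else NA_real_,
                u1 = if (p1 > 0) q$i1 / p1 else NA_real_,
                p0 = p0, p1 = p1, n = n, method = "quadrature",
                M = NA_real_, seed = NULL, se = NULL,
                test = test, prior = prior))
}

# shared MC reduction used by pos() and by the common-random-numbers SSD path
.mc_from_draws <- function(test, theta, n, sigma = NULL) {
  eta <- test_power(test, theta, n, sigma = sigma)
  I1 <- theta > test$theta0
  M <- length(theta)
  u_r <- ifelse(I1, eta, 1 - eta)
  a_r <- eta * I1
  p1bar <- mean(I1)
  e_a <- mean(a_r)
  e_b <- if (p1bar > 0) e_a / p1bar else NA_real_
  list(u = mean(u_r), e_a = e_a, e_b = e_b, e_c = mean(eta),
       u0 = if (p1bar < 1) mean((1 - eta)[!I1]) else NA_real_,
       u1 = e_b, p1bar = p1bar,
       se = c(u = sd(u_r) / sqrt(M), e_a = sd(a_r) / sqrt(M),
              e_b = if (p1bar > 0)
                sd(a_r - e_b * I1) / (p1bar * sqrt(M)) else NA_real_,
              e_c = sd(eta) / sqrt(M)))
}

.pos_mc <- function(test, prior, n, M, seed) {
  M <- .check_n(M, "M")
  if (M < 2) stop("'M' must be at least 2", call. = FALSE)
  theta <- simulate(prior, nsim = M, seed = seed)
  est <- .mc_from_draws(test, theta, n)
  p0 <- prob_null(prior, test$theta0)
  if (est$p1bar == 0 && p0 < 1)
    warning("no draw fell in the alternative although p1 > 0: ",
            "e_b is undefined for this draw set")
  .new_pos(c(est[c("u", "e_a", "e_b", "e_c", "u0", "u1")],
             list(p0 = p0, p1 = 1 - p0, p1bar = est$p1bar, n = n,
                  method = "mc", M = M, seed = seed, se = est$se,
                  test = test, prior = prior)))
}

.pos_mc_vprior <- function(test, prior, n, M, seed, vprior) {
  M <- .check_n(M, "M")
  jd <- sample_joint(prior, vprior, M, seed)
  est <- .mc_from_draws(test, jd$theta, n, sigma = sqrt(jd$sigma2))
  # with sigma random the exact p0 is itself an expectation; report the
  # empirical mass from the same draws
  p0 <- 1 - est$p1bar
  .new_pos(c(est[c("u", "e_a", "e_b", "e_c", "u0", "u1")],
             list(p0 = p0, p1 = est$p1bar, p1bar = est$p1bar, n = n,
                  method = "mc", M = M, seed = seed, se = est$se,
                  test = test, prior = prior, variance_prior = vprior)))
}

#' @export
print.pos <- function(x, digits = 3, ...) {
  cat(sprintf("Probability of success at n = %d (%s%s)\n", as.integer(x$n),
              x$method,
              if (x$method == "mc") sprintf(", M = %g", x$M) else ""))
  v <- coef(x)
  print(round(v, digits))
  invisible(x)
}

#' Extract the four PoS measures
#'
#' @param object a `"pos"` result.
#' @param ... unused.
#' @return named numeric vector `c(u, e_a, e_b, e_c)`.
#' @export
coef.pos <- function(object, ...)
  c(u = object$u, e_a = object$e_a, e_b = object$e_b, e_c = object$e_c)

#' @export
summary.pos <- function(object, ...) {
  structure(object, class = c("summary.pos", "pos"))
}

#' @export
print.summary.pos <- function(x, digits = 4, ...) {
  print.pos(x, digits = digits)
  cat(sprintf("\nDecomposition: p0 = %.4g, p1 = %.4g, u_n0 = %.4g, u_n1 = %.4g\n",
              x$p0, x$p1, x$u0, x$u1))
  if (!is.null(x$se)) {
    cat("Monte Carlo standard errors:\n")
    print(signif(x$se, 3))
  }
  invisible(x)
}

#' Closed-form assurance under a conventional normal design prior
#'
#' For a normal prior \eqn{N(\theta_d, \sigma^2/n_d)} the assurance has the
#' closed form
#' \deqn{e^c_n = 1 - \Phi\!\left(\frac{\theta_0 - \theta_d +
#'   (\sigma/\sqrt n)\, z_{1-\alpha}}{\xi_d}\right),\qquad
#'   \xi_d = \sigma\sqrt{1/n_d + 1/n}.}
#' As \eqn{n_d \to \infty} this reduces to the frequentist power at
#' \eqn{\theta_d}.
#'
#' @param test a [one_sided_test()].
#' @param prior a [normal_prior()] (other priors signal an error).
#' @param n sample size(s).
#' @return assurance value(s).
#' @export
enc_closed_form <- function(test, prior, n) {
  stopifnot(inherits(test, "one_sided_test"))
  if (!inherits(prior, "normal_prior"))
    stop("closed-form assurance is available for normal priors only",
         call. = FALSE)
  n <- .check_n(n)
  xi <- sqrt(prior$omega^2 + test$sigma^2 / n)
  1 - pnorm((test$theta0 - prior$theta_d +
               test$sigma / sqrt(n) * .crit(test)) / xi)
}

#' Large-sample limits of the PoS measures
#'
#' Under size-\eqn{\alpha} consistency, \eqn{u_n \to 1} and
#' \eqn{e^b_n \to 1} for every proper design prior, while
#' \eqn{e^a_n, e^c_n \to p_1}: thresholds for the `a`/`c` criteria above
#' \eqn{p_1} are infeasible.
#'
#' @param test a [one_sided_test()].
#' @param prior a design prior.
#' @return An object of class `"pos_limits"`: list with `u`, `e_a`, `e_b`,
#'   `e_c`, `p0`, `p1`.
#' @export
pos_limits <- function(test, prior) {
  p0 <- prob_null(prior, test$theta0)
  structure(list(u = 1, e_a = 1 - p0,
                 e_b = if (p0 < 1) 1 else NA_real_, e_c = 1 - p0,
                 p0 = p0, p1 = 1 - p0),
            class = "pos_limits")
}

#' @export
print.pos_limits <- function(x, ...) {
  cat("Limiting values as n -> Inf (p1 =", format(x$p1, digits = 4), "):\n")
  print(unlist(x[c("u", "e_a", "e_b", "e_c")]))
  invisible(x)
}
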