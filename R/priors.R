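#' Design priors on the treatment effect
#'
#' Constructors for the design-prior family used at the planning stage of a
#' superiority trial: a point mass, a conventional normal, a skew normal, a
#' truncated normal, and a two-component normal mixture. The normal-family
#' priors are parameterised by a location `theta_d` (the anticipated effect)
#' and a *design prior sample size* `n_d`, giving scale
#' \eqn{\omega = \sigma/\sqrt{n_d}}: larger `n_d` means a more concentrated
#' prior, and \eqn{n_d \to \infty} recovers the point mass. For the skew
#' normal, \eqn{\sigma^2/n_d} is the squared *scale* (not the variance of the
#' law) and `lambda` is the shape: density
#' \eqn{(2/\omega)\,\phi((\theta-\theta_d)/\omega)\,\Phi(\lambda(\theta-\theta_d)/\omega)},
#' CDF \eqn{\Phi(z) - 2T(z,\lambda)} with [owens_t()].
#'
#' All priors expose [prior_density()], [prior_cdf()], [prob_null()],
#' [conditional_prior()] and a [simulate()][simulate.design_prior] method.
#'
#' @param theta_d prior location (point-mass value for `point_prior`).
#' @param n_d design prior sample size (> 0).
#' @param sigma sampling SD shared with the test (default 2, i.e.
#'   \eqn{\sigma^2 = 4} on the log odds ratio scale).
#' @param lambda skew-normal shape parameter.
#' @param lower,upper truncation bounds, `lower < upper` (`upper = Inf`
#'   allowed).
#' @param w0 mixture weight of the first component, in \[0, 1\].
#' @param comp0,comp1 [normal_prior()] components of a mixture.
#' @return An object inheriting from class `"design_prior"`.
#' @examples
#' pri <- normal_prior(theta_d = 0.198, n_d = 46)
#' prob_null(pri)                    # design-prior mass on H0
#' simulate(pri, nsim = 3, seed = 1) # seeded effect draws
#' @name design_priors
NULL

.new_prior <- function(type, fields) {
  structure(c(list(type = type), fields),
            class = c(paste0(type, "_prior"), "design_prior"))
}

#' @rdname design_priors
#' @export
point_prior <- function(theta_d) {
  if (!is.numeric(theta_d) || length(theta_d) != 1L || is.na(theta_d))
    stop("'theta_d' must be a single number", call. = FALSE)
  .new_prior("point", list(theta_d = theta_d))
}

#' @rdname design_priors
#' @export
normal_prior <- function(theta_d, n_d, sigma = 2) {
  .check_pos_scalar(n_d, "n_d"); .check_pos_scalar(sigma, "sigma")
  .new_prior("normal", list(theta_d = theta_d, n_d = n_d, sigma = sigma,
                            omega = sigma / sqrt(n_d)))
}

#' @rdname design_priors
#' @export
skew_normal_prior <- function(theta_d, n_d, lambda, sigma = 2) {
  .check_pos_scalar(n_d, "n_d"); .check_pos_scalar(sigma, "sigma")
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda))
    stop("'lambda' must be a single number", call. = FALSE)
  .new_prior("skew_normal", list(theta_d = theta_d, n_d = n_d,
                                 lambda = lambda, sigma = sigma,
                                 omega = sigma / sqrt(n_d)))
}

#' @rdname design_priors
#' @export
trunc_normal_prior <- function(theta_d, n_d, lower, upper = Inf, sigma = 2) {
  .check_pos_scalar(n_d, "n_d"); .check_pos_scalar(sigma, "sigma")
  if (!(lower < upper)) stop("'lower' must be < 'upper'", call. = FALSE)
  omega <- sigma / sqrt(n_d)
  plo <- pnorm(lower, theta_d, omega)
  phi <- pnorm(upper, theta_d, omega)
  if (phi - plo <= 0)
    stop("truncation interval carries no prior mass", call. = FALSE)
  .new_prior("trunc_normal",
             list(theta_d = theta_d, n_d = n_d, sigma = sigma, omega = omega,
                  lower = lower, upper = upper, plo = plo, phi = phi))
}

#' @rdname design_priors
#' @export
mixture_prior <- function(w0, comp0, comp1) {
  .check_prob(w0, "w0", open = FALSE)
  if (!inherits(comp0, "normal_prior") || !inherits(comp1, "normal_prior"))
    stop("'comp0' and 'comp1' must be normal_prior objects", call. = FALSE)
  .new_prior("mixture", list(w0 = w0, comp0 = comp0, comp1 = comp1,
                             theta_d = comp1$theta_d))
}

#' @export
print.design_prior <- function(x, ...) {
  lab <- switch(x$type,
    point = sprintf("Point-mass design prior at theta_d = %g", x$theta_d),
    normal = sprintf("Normal design prior: theta_d = %g, n_d = %g (scale %.4g)",
                     x$theta_d, x$n_d, x$omega),
    skew_normal = sprintf(
      "Skew-normal design prior: theta_d = %g, n_d = %g, lambda = %g",
      x$theta_d, x$n_d, x$lambda),
    trunc_normal = sprintf(
      "Truncated-normal design prior: theta_d = %g, n_d = %g on [%g, %g]",
      x$theta_d, x$n_d, x$lower, x$upper),
    mixture = sprintf(
      "Mixture design prior: %g * N(%g, s^2/%g) + %g * N(%g, s^2/%g)",
      x$w0, x$comp0$theta_d, x$comp0$n_d,
      1 - x$w0, x$comp1$theta_d, x$comp1$n_d),
    sprintf("Conditional design prior (side %d at theta0 = %g)",
            x$side, x$theta0))
  cat(lab, "\n")
  invisible(x)
}

# ---- density / cdf -------------------------------------------------------

#' Density, CDF and null mass of a design prior
#'
#' `prob_null()` returns the exact prior probability \eqn{p_0} of the null
#' region \eqn{\{\theta \le \theta_0\}} (the boundary belongs to the null),
#' computed from the CDF, never by sampling.
#'
#' @param prior a design prior.
#' @param theta numeric vector of effect values.
#' @param theta0 null boundary (default 0).
#' @return numeric vector (`prob_null`: a single probability).
#' @export
prior_density <- function(prior, theta) UseMethod("prior_density")

#' @export
prior_density.point_prior <- function(prior, theta)
  ifelse(theta == prior$theta_d, Inf, 0)

#' @export
prior_density.normal_prior <- function(prior, theta)
  dnorm(theta, prior$theta_d, prior$omega)

#' @export
prior_density.skew_normal_prior <- function(prior, theta) {
  z <- (theta - prior$theta_d) / prior$omega
  2 / prior$omega * dnorm(z) * pnorm(prior$lambda * z)
}

#' @export
prior_density.trunc_normal_prior <- function(prior, theta)
  ifelse(theta >= prior$lower & theta <= prior$upper,
         dnorm(theta, prior$theta_d, prior$omega) / (prior$phi - prior$plo), 0)

#' @export
prior_density.mixture_prior <- function(prior, theta)
  prior$w0 * prior_density(prior$comp0, theta) +
    (1 - prior$w0) * prior_density(prior$comp1, theta)

#' @rdname prior_density
#' @export
prior_cdf <- function(prior, theta) UseMethod("prior_cdf")

#' @export
prior_cdf.point_prior <- function(prior, theta)
  as.numeric(theta >= prior$theta_d)

#' @export
prior_cdf.normal_prior <- function(prior, theta)
  pnorm(theta, prior$theta_d, prior$omega)

#' @export
prior_cdf.skew_normal_prior <- function(prior, theta) {
  z <- (theta - prior$theta_d) / prior$omega
  pmin(1, pmax(0, pnorm(z) - 2 * owens_t(z, prior$lambda)))
}

#' @export
prior_cdf.trunc_normal_prior <- function(prior, theta) {
  p <- (pnorm(theta, prior$theta_d, prior$omega) - prior$plo) /
    (prior$phi - prior$plo)
  pmin(1, pmax(0, p))
}

#' @export
prior_cdf.mixture_prior <- function(prior, theta)
  prior$w0 * prior_cdf(prior$comp0, theta) +
    (1 - prior$w0) * prior_cdf(prior$comp1, theta)

#' @rdname prior_density
#' @export
prob_null <- function(prior, theta0 = 0) {
  stopifnot(inherits(prior, "design_prior"))
  prior_cdf(prior, theta0)
}

# quadrature decomposition: weighted smooth components with their supports
# and a location/scale used to place integration break points
.components <- function(prior) UseMethod(".components")

.components.normal_prior <- function(prior)
  list(list(w = 1, dens = function(t) prior_density(prior, t),
            lower = -Inf, upper = Inf,
            loc = prior$theta_d, scale = prior$omega))

.components.skew_normal_prior <- .components.normal_prior

.components.trunc_normal_prior <- function(prior)
  list(list(w = 1, dens = function(t) prior_density(prior, t),
            lower = prior$lower, upper = prior$upper,
            loc = prior$theta_d, scale = prior$omega))

.components.mixture_prior <- function(prior) {
  c0 <- .components(prior$comp0)[[1]]; c0$w <- prior$w0
  c1 <- .components(prior$comp1)[[1]]; c1$w <- 1 - prior$w0
  list(c0, c1)
}

.components.conditional_prior <- function(prior) {
  lapply(.components(prior$parent), function(cmp) {
    if (prior$side == 1L) cmp$lower <- max(cmp$lower, prior$theta0)
    else cmp$upper <- min(cmp$upper, prior$theta0)
    cmp$dens_parent <- cmp$dens
    cmp$dens <- local({
      f <- cmp$dens_parent; p <- prior$p
      function(t) f(t) / p
    })
    cmp
  })
}

# ---- conditional (restricted) priors ------------------------------------

#' Design prior restricted to one side of the null boundary
#'
#' Returns \eqn{\tilde\pi_i(\theta) = \pi(\theta) I_{\Omega_i}(\theta)/p_i},
#' the parent prior conditioned on the null region (`side = 0`,
#' \eqn{\theta \le \theta_0}) or the alternative (`side = 1`,
#' \eqn{\theta > \theta_0}). Fails if the requested side carries no prior
#' mass. Sampling from the result uses rejection from the parent, so its cost
#' grows like \eqn{1/p_i}.
#'
#' @param prior a (continuous) design prior.
#' @param side 0 or 1.
#' @param theta0 null boundary (default 0).
#' @export
conditional_prior <- function(prior, side, theta0 = 0) {
  stopifnot(inherits(prior, "design_prior"))
  if (inherits(prior, "point_prior"))
    stop("conditioning a point-mass prior is not supported", call. = FALSE)
  side <- as.integer(side)
  if (!side %in% c(0L, 1L)) stop("'side' must be 0 or 1", call. = FALSE)
  p0 <- prob_null(prior, theta0)
  p <- if (side == 0L) p0 else 1 - p0
  if (p <= 0)
    stop(sprintf("prior mass on side %d is zero: conditional is degenerate",
                 side), call. = FALSE)
  structure(list(type = "conditional", parent = prior, side = side,
                 theta0 = theta0, p = p),
            class = c("conditional_prior", "design_prior"))
}

#' @export
prior_density.conditional_prior <- function(prior, theta) {
  ind <- if (prior$side == 1L) theta > prior$theta0 else theta <= prior$theta0
  ifelse(ind, prior_density(prior$parent, theta) / prior$p, 0)
}

#' @export
prior_cdf.conditional_prior <- function(prior, theta) {
  Fp <- prior_cdf(prior$parent, theta)
  F0 <- prior_cdf(prior$parent, prior$theta0)
  if (prior$side == 0L) pmin(Fp, F0) / prior$p
  else pmin(1, pmax(0, (Fp - F0) / prior$p))
}

# ---- sampling ------------------------------------------------------------

#' Draw effects from a design prior
#'
#' Seeded, reproducible sampling. Truncated-normal priors use inverse-CDF
#' sampling (cost independent of the truncation mass); skew-normal priors use
#' the half-normal representation; conditional priors use rejection from
#' their parent.
#'
#' @param object a design prior.
#' @param nsim number of draws.
#' @param seed integer seed, or `NULL` to use (and advance) the global RNG
#'   stream. When non-`NULL`, the caller's RNG state is restored afterwards.
#' @param ... unused.
#' @return numeric vector of `nsim` effect draws.
#' @export
simulate.design_prior <- function(object, nsim = 1, seed = NULL, ...) {
  nsim <- .check_n(nsim, "nsim")
  .with_seed(seed, .sample_prior(object, nsim))
}

.sample_prior <- function(prior, M) UseMethod(".sample_prior")

.sample_prior.point_prior <- function(prior, M) rep(prior$theta_d, M)

.sample_prior.normal_prior <- function(prior, M)
  rnorm(M, prior$theta_d, prior$omega)

.sample_prior.skew_normal_prior <- function(prior, M) {
  delta <- prior$lambda / sqrt(1 + prior$lambda^2)
  z <- delta * abs(rnorm(M)) + sqrt(1 - delta^2) * rnorm(M)
  prior$theta_d + prior$omega * z
}

.sample_prior.trunc_normal_prior <- function(prior, M) {
  u <- runif(M, prior$plo, prior$phi)
  qnorm(u, prior$theta_d, prior$omega)
}

.sample_prior.mixture_prior <- function(prior, M) {
  from0 <- runif(M) < prior$w0
  out <- numeric(M)
  out[from0] <- .sample_prior(prior$comp0, sum(from0))
  out[!from0] <- .sample_prior(prior$comp1, sum(!from0))
  out
}

.sample_prior.conditional_prior <- function(prior, M) {
  out <- numeric(0)
  keep <- function(x) if (prior$side == 1L) x[x > prior$theta0]
                      else x[x <= prior$theta0]
  # expected number of parent draws per acceptance is 1/p
  batch <- max(1000L, ceiling(1.5 * M / prior$p))
  while (length(out) < M) out <- c(out, keep(.sample_prior(prior$parent, batch)))
  out[seq_len(M)]
}

# ---- variance priors -----------------------------------------------------

#' Priors on the sampling variance
#'
#' `inv_gamma_prior(shape, scale)` is the inverse-gamma law with density
#' proportional to \eqn{x^{-a-1} e^{-b/x}} and mean \eqn{b/(a-1)} (shape
#' \eqn{a > 1} required for the mean to exist). `IG(16, 60)` has mean 4 and
#' SD \eqn{\approx 1.07}, the unknown-variance scenario of the application.
#' `fixed_variance(sigma2)` is the degenerate prior used to recover the
#' known-variance analysis as a special case.
#'
#' @param shape,scale inverse-gamma hyperparameters (both > 0; `shape > 1`).
#' @param sigma2 fixed variance value.
#' @return An object of class `"variance_prior"`.
#' @export
inv_gamma_prior <- function(shape, scale) {
  .check_pos_scalar(shape, "shape"); .check_pos_scalar(scale, "scale")
  if (shape <= 1)
    stop("'shape' must exceed 1 for the prior mean of sigma^2 to exist",
         call. = FALSE)
  structure(list(type = "inv_gamma", shape = shape, scale = scale),
            class = c("inv_gamma_prior", "variance_prior"))
}

#' @rdname inv_gamma_prior
#' @export
fixed_variance <- function(sigma2) {
  .check_pos_scalar(sigma2, "sigma2")
  structure(list(type = "fixed", sigma2 = sigma2),
            class = c("fixed_variance_prior", "variance_prior"))
}

#' @export
mean.inv_gamma_prior <- function(x, ...) x$scale / (x$shape - 1)

#' @export
mean.fixed_variance_prior <- function(x, ...) x$sigma2

.sample_variance <- function(vprior, M) {
  switch(vprior$type,
         inv_gamma = 1 / rgamma(M, shape = vprior$shape, rate = vprior$scale),
         fixed = rep(vprior$sigma2, M))
}

#' Joint draws of (variance, effect) under a variance prior
#'
#' Draws \eqn{\sigma^{2(r)}} from the variance prior and then
#' \eqn{\theta^{(r)} \mid \sigma^{2(r)} \sim N(\theta_d, \sigma^{2(r)}/n_d)}:
#' the drawn variance enters the prior scale (and, downstream in [pos()],
#' the power function).
#'
#' @param prior a [normal_prior()].
#' @param vprior a [inv_gamma_prior()] or [fixed_variance()].
#' @param M number of joint draws.
#' @param seed integer seed or `NULL`.
#' @return list with numeric components `sigma2` and `theta`, each of length `M`.
#' @export
sample_joint <- function(prior, vprior, M, seed = NULL) {
  if (!inherits(prior, "normal_prior"))
    stop("variance priors are supported for normal design priors only",
         call. = FALSE)
  stopifnot(inherits(vprior, "variance_prior"))
  M <- .check_n(M, "M")
  .with_seed(seed, {
    s2 <- .sample_variance(vprior, M)
    th <- rnorm(M, prior$theta_d, sqrt(s2 / prior$n_d))
    list(sigma2 = s2, theta = th)
  })
}
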