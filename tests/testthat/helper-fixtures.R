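# Shared fixtures: the log-odds-ratio application test (theta0 = 0,
# one-sided alpha = 0.05, sigma^2 = 4) and the design-prior scenarios
# used throughout the application tables.

ztest <- function() one_sided_test(theta0 = 0, alpha = 0.05, sigma = 2)

# the full unimodal + mixture scenario set (Table-1/5 style)
scenario_priors <- function() {
  out <- list()
  for (thd in c(0.198, 0.372, 0.545))
    for (nd in c(15, 46, 165))
      out[[sprintf("normal_%g_%d", thd, nd)]] <- normal_prior(thd, nd)
  for (nd in c(15, 46, 165)) {
    out[[sprintf("skew_%d", nd)]] <- skew_normal_prior(0.198, nd, lambda = 1)
    out[[sprintf("trunc_%d", nd)]] <- trunc_normal_prior(0.198, nd, lower = 0)
  }
  for (w0 in c(0.25, 0.5, 0.75))
    out[[sprintf("mix_%g", w0)]] <-
      mixture_prior(w0, normal_prior(0, 165), normal_prior(0.545, 46))
  out
}

# numeric integral of a prior density over the whole support
integrate_density <- function(prior, lower = -Inf, upper = Inf) {
  stats::integrate(function(t) prior_density(prior, t), lower, upper,
                   rel.tol = 1e-9)$value
}
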