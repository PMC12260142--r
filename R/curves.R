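#' Measure-versus-n curves
#'
#' Evaluates the four PoS measures on a grid of sample sizes, alongside the
#' point-mass power curve \eqn{\eta_n(\theta_d)} at the prior's location,
#' for plotting or export. With `method = "mc"` one common draw set is used
#' for the whole grid.
#'
#' @param test a [one_sided_test()].
#' @param prior a design prior.
#' @param n vector of sample sizes.
#' @param method `"quadrature"` (default) or `"mc"`.
#' @param M,seed Monte Carlo settings.
#' @return A data frame of class `"pos_curve"` with columns `n`, `eta`,
#'   `u`, `e_a`, `e_b`, `e_c`.
#' @export
pos_curve <- function(test, prior, n, method = c("quadrature", "mc"),
                      M = 1e6, seed = NULL) {
  stopifnot(inherits(test, "one_sided_test"), inherits(prior, "design_prior"))
  n <- .check_n(n)
  method <- match.arg(method)
  theta_d <- prior$theta_d
  if (method == "mc")
    theta <- simulate(prior, nsim = .check_n(M, "M"), seed = seed)
  rows <- lapply(n, function(ni) {
    est <- if (method == "mc") .mc_from_draws(test, theta, ni)
           else pos(test, prior, ni)
    data.frame(n = ni,
               eta = if (is.null(theta_d)) NA_real_
                     else test_power(test, theta_d, ni),
               u = est$u, e_a = est$e_a, e_b = est$e_b, e_c = est$e_c)
  })
  out <- do.call(rbind, rows)
  attr(out, "test") <- test
  attr(out, "prior") <- prior
  attr(out, "method") <- method
  class(out) <- c("pos_curve", "data.frame")
  out
}

#' @export
plot.pos_curve <- function(x, ...) {
  cols <- c(eta = "grey50", u = "black", e_a = "tomato3",
            e_b = "steelblue4", e_c = "darkgreen")
  matplot(x$n, as.matrix(x[, names(cols)]), type = "l", lty = c(2, 1, 1, 1, 1),
          col = cols, xlab = "n (effective observations)",
          ylab = "probability of success", ylim = c(0, 1), ...)
  legend("bottomright",
         legend = c(expression(eta[n](theta[d])), "u (u-PoS)",
                    expression(e^a), expression(e^b),
                    expression(e^c ~ "(assurance)")),
         lty = c(2, 1, 1, 1, 1), col = cols, bty = "n")
  invisible(x)
}
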