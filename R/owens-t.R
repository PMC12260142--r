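#' Owen's T function
#'
#' \eqn{T(h, a) = \frac{1}{2\pi}\int_0^a \frac{e^{-h^2(1+x^2)/2}}{1+x^2}\,dx},
#' the auxiliary bivariate-normal integral used for the skew-normal CDF.
#' Evaluated by adaptive quadrature of the defining integral, exploiting the
#' symmetries \eqn{T(-h,a)=T(h,a)} and \eqn{T(h,-a)=-T(h,a)}. No R package in
#' scope provides this primitive, hence the in-house implementation; it is
#' validated against the closed identities \eqn{T(h,1)=\Phi(h)(1-\Phi(h))/2}
#' and \eqn{T(0,a)=\arctan(a)/(2\pi)}.
#'
#' @param h numeric vector.
#' @param a numeric vector, recycled against `h`. `Inf` is allowed
#'   (\eqn{T(h,\infty) = (1-\Phi(|h|))/2}).
#' @return numeric vector of the same length as `h`.
#' @export
owens_t <- function(h, a) {
  k <- max(length(h), length(a))
  h <- rep_len(h, k); a <- rep_len(a, k)
  out <- numeric(k)
  for (i in seq_len(k)) {
    hi <- abs(h[i]); ai <- a[i]
    sgn <- sign(ai)
    ai <- abs(ai)
    v <- if (ai == 0) {
      0
    } else if (is.infinite(ai)) {
      (1 - pnorm(hi)) / 2
    } else {
      integrate(function(x) exp(-hi^2 * (1 + x^2) / 2) / (1 + x^2),
                0, ai, rel.tol = 1e-12, abs.tol = 1e-14)$value / (2 * pi)
    }
    out[i] <- sgn * v
  }
  out
}
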