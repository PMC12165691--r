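# Inverse-Gaussian (Wald) distribution: density, CDF, quantile and
# closed-form maximum-likelihood fit.  Used to model the per-epoch maximum
# of squared voltage when screening for artifactual epochs.

#' Inverse-Gaussian density
#' @param x quantiles (> 0).
#' @param mu mean parameter (> 0).
#' @param lambda shape parameter (> 0).
#' @return density values.
#' @export
dinvgauss <- function(x, mu, lambda) {
  out <- numeric(length(x))
  ok <- x > 0
  out[ok] <- sqrt(lambda / (2 * pi * x[ok]^3)) *
    exp(-lambda * (x[ok] - mu)^2 / (2 * mu^2 * x[ok]))
  out
}

#' Inverse-Gaussian cumulative distribution function
#' @inheritParams dinvgauss
#' @param q quantiles.
#' @return P(X <= q).
#' @export
pinvgauss <- function(q, mu, lambda) {
  out <- numeric(length(q))
  ok <- q > 0
  x <- q[ok]
  a <- sqrt(lambda / x)
  # second term computed on the log scale: exp(2*lambda/mu) overflows for
  # large shape, while the product with the tiny normal tail is finite
  term2 <- exp(2 * lambda / mu +
                 stats::pnorm(-a * (x / mu + 1), log.p = TRUE))
  out[ok] <- stats::pnorm(a * (x / mu - 1)) + term2
  pmin(pmax(out, 0), 1)
}

#' Inverse-Gaussian quantile function
#' @inheritParams dinvgauss
#' @param p probabilities.
#' @return quantiles such that `pinvgauss(q) = p`.
#' @export
qinvgauss <- function(p, mu, lambda) {
  vapply(p, function(pp) {
    if (pp <= 0) return(0)
    if (pp >= 1) return(Inf)
    # bracket the root around the mean, expanding upward as needed
    upper <- mu
    while (pinvgauss(upper, mu, lambda) < pp) upper <- upper * 2
    stats::uniroot(function(x) pinvgauss(x, mu, lambda) - pp,
                   lower = .Machine$double.xmin, upper = upper,
                   tol = .Machine$double.eps^0.5)$root
  }, numeric(1))
}

#' Closed-form maximum-likelihood fit of an inverse-Gaussian
#'
#' mu-hat is the sample mean; the shape estimate is
#' n / sum(1/x_i - 1/mu-hat).  No iterative optimisation is involved.
#'
#' @param x positive observations.
#' @return list with elements `mu` and `lambda`.
#' @export
fit_invgauss <- function(x) {
  if (any(x <= 0)) stop("inverse-Gaussian fit requires positive data")
  mu <- mean(x)
  denom <- sum(1 / x - 1 / mu)
  if (denom <= 0) stop("degenerate sample: zero dispersion")
  list(mu = mu, lambda = length(x) / denom)
}
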