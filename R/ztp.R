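#' Zero-truncated Poisson probability mass function
#'
#' The law of observed barcode family sizes under uniform amplification and
#' random subsampling: counts are Poisson (a binomial approximation), but
#' families of size zero are unobservable, so the distribution is
#' conditioned on being at least 1:
#' \deqn{P(k) = \frac{\lambda^k e^{-\lambda}}{k!\,(1 - e^{-\lambda})}, \quad k \ge 1.}
#'
#' @param k Integer family sizes (values `< 1` have probability 0).
#' @param lambda Poisson rate, `> 0`.  Under subsampling of a uniformly
#'   amplified pool this equals the sample ratio.
#' @return Vector of probabilities.
#' @examples
#' ztp_pmf(1, 1)                 # exp(-1)/(1 - exp(-1))
#' sum(ztp_pmf(1:200, 5))        # 1
#' @export
ztp_pmf <- function(k, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0)
    stopf("`lambda` must be a single positive number")
  p <- dpois(k, lambda) / (1 - exp(-lambda))
  p[k < 1 | k != floor(k)] <- 0
  p
}

#' Moments of the zero-truncated Poisson
#'
#' Closed-form mean, variance and coefficient of variation:
#' mean \eqn{\lambda/(1-e^{-\lambda})}, second moment
#' \eqn{(\lambda + \lambda^2)/(1-e^{-\lambda})}.
#'
#' @param lambda Poisson rate, `> 0`.
#' @return A list with elements `mean`, `variance` and `cv`.
#' @examples
#' ztp_moments(1)$mean   # 1.582
#' @export
ztp_moments <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0)
    stopf("`lambda` must be a single positive number")
  z <- 1 - exp(-lambda)
  m <- lambda / z
  v <- (lambda + lambda^2) / z - m^2
  list(mean = m, variance = v, cv = sqrt(v) / m)
}

#' Draw from a zero-truncated Poisson
#'
#' Exact inversion sampler: uniforms are drawn from the conditional range
#' `(P(X = 0), 1]` of the untruncated CDF and inverted with [qpois()].
#'
#' @param n Number of draws.
#' @param lambda Poisson rate, `> 0`.
#' @param seed Optional integer seed.
#' @return Integer vector of draws, all `>= 1`.
#' @export
rztpois <- function(n, lambda, seed = NULL) {
  if (lambda <= 0) stopf("`lambda` must be positive")
  p0 <- dpois(0, lambda)
  with_seed_maybe(seed, qpois(p0 + runif(n) * (1 - p0), lambda))
}
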