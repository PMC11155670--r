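#' Draw ex-Gaussian reaction times
#'
#' The ex-Gaussian distribution (the sum of a normal and an independent
#' exponential variate) is the standard descriptive model for response-time
#' data: `mu` and `sigma` describe the roughly symmetric body of the RT
#' distribution and `tau` its long right tail. Its mean is `mu + tau` and its
#' variance `sigma^2 + tau^2`.
#'
#' `sigma = 0` and/or `tau = 0` are allowed and drop the corresponding
#' component, so `rexgauss(n, mu, 0, 0)` returns `mu` exactly `n` times —
#' useful for noise-free checks.
#'
#' @param n number of draws.
#' @param mu normal component mean, in ms.
#' @param sigma normal component SD, in ms (`>= 0`).
#' @param tau exponential component mean, in ms (`>= 0`).
#' @return numeric vector of `n` draws, in ms.
#' @examples
#' set.seed(1)
#' mean(rexgauss(1e4, 450, 50, 100)) # close to 550
#' rexgauss(3, 450, 0, 0)            # exactly 450 450 450
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  stopifnot(n >= 0, sigma >= 0, tau >= 0)
  x <- rep.int(mu, n)
  if (sigma > 0) x <- x + rnorm(n, 0, sigma)
  if (tau > 0) x <- x + rexp(n, rate = 1 / tau)
  x
}
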