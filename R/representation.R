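#' Gaussian stimulus-representation activation
#'
#' The CS representation is a Gaussian radial basis function of the
#' accumulator state, centred on the timing threshold:
#' \deqn{x(\Psi) = \exp\!\left(-\frac{(\Psi-\theta)^2}{2\sigma^2}\right).}
#' It can be read as the receptive field of time-sensitive units tuned to the
#' threshold: activation peaks at exactly 1 when \eqn{\Psi = \theta}, i.e. at
#' the remembered target time, and falls off symmetrically on either side.
#' Because the accumulator keeps rising past \eqn{\theta}, activation also
#' declines after the expected reinforcement time.
#'
#' @param psi Accumulator value(s) \eqn{\Psi}; vectorised.
#' @param theta Centre (the timing threshold, > 0).
#' @param sigma Width \eqn{\sigma} (> 0, in accumulator units).
#' @return Activation in (0, 1], same length as `psi`.
#' @examples
#' activation(1, sigma = 0.3)            # 1 at the threshold
#' activation(1 - 0.3, sigma = 0.3)      # exp(-1/2)
#' @export
activation <- function(psi, theta = 1, sigma) {
  stopifnot(is.numeric(sigma), all(sigma > 0), all(theta > 0))
  exp(-(psi - theta)^2 / (2 * sigma^2))
}

#' One step of Gaussian-width adaptation
#'
#' Linear-operator sharpening of the representation width toward an
#' asymptotic value, used to model the gradual tuning of a preexposed
#' stimulus' temporal receptive field:
#' \deqn{\sigma(n+1) = \sigma(n) + \alpha_\sigma\,(\sigma_\infty - \sigma(n)).}
#' Applied once per trial when width adaptation is enabled (by default only
#' the latent-inhibition design enables it, starting at \eqn{\sigma(1)=0.6}
#' with \eqn{\alpha_\sigma = 0.025} and asymptote 0.35).
#'
#' @param sigma Current width(s).
#' @param rate Adaptation rate \eqn{\alpha_\sigma} in (0, 1).
#' @param target Asymptotic width (default 0.35).
#' @return Updated width.
#' @export
width_update <- function(sigma, rate, target = 0.35) {
  stopifnot(rate > 0, rate < 1, target > 0)
  sigma + rate * (target - sigma)
}

#' One step of a leaky-integrator stimulus trace
#'
#' A first-order leaky integrator,
#' \deqn{x(t+1) = x(t) + \tfrac{1}{\tau}\,(I - x(t)),}
#' where `I` indicates stimulus presence. It rises toward 1 while the
#' stimulus is on and decays toward 0 after offset. Offered as an optional
#' early-training representation (before timing is expressed, responding
#' tracks mere stimulus presence); the package exposes it behind a
#' configuration flag and does not impose a rule for when an organism
#' switches from trace to Gaussian representation.
#'
#' @param x Current activation(s) (>= 0).
#' @param input Presence indicator `I` (0 or 1, or any drive level).
#' @param tau Time constant (> 0, in steps).
#' @return Updated activation.
#' @export
leaky_step <- function(x, input, tau) {
  stopifnot(tau > 0)
  x + (input - x) / tau
}
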