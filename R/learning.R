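#' Time-scaled asymptote of associative learning
#'
#' The asymptote \eqn{\lambda} of the Rescorla-Wagner update is set by the
#' US's motivational magnitude spread over the signalled delay (hyperbolic
#' delay discounting): \eqn{\lambda = H/t^*}. Substituting the internal time
#' estimate \eqn{t^* = \Psi(t^*)/A} gives the value actually used,
#' \deqn{\lambda = \frac{H\,A}{\Psi(t^*)}.}
#' With a converged timer (\eqn{\Psi(t^*) \approx \theta = 1}) this is
#' \eqn{H A_\infty = H/t^*}. `H = 0` encodes US absence (extinction), giving
#' \eqn{\lambda = 0}.
#'
#' @param H US motivational magnitude (>= 0).
#' @param slope Timer slope \eqn{A} (per second); vectorised.
#' @param psi_at_target Accumulation \eqn{\Psi(t^*)} at the US (or offset)
#'   time; must be > 0.
#' @return The asymptote \eqn{\lambda} (per-second units of H/t).
#' @export
us_asymptote <- function(H, slope, psi_at_target) {
  stopifnot(all(H >= 0), all(slope > 0))
  if (any(!is.finite(psi_at_target)) || any(psi_at_target <= 0))
    stop("psi_at_target must be positive (degenerate accumulation at the target time)")
  H * slope / psi_at_target
}

#' Rescorla-Wagner update of associative strengths
#'
#' One trial's update for all representations present, using the activations
#' current at the end of the trial:
#' \deqn{\Delta V_i = \alpha_V\,\Big(\lambda_i - \sum_j V_j x_j\Big)\, x_i.}
#' The summation term pools the prediction of every representation present,
#' which is what lets the rule express cue competition (blocking,
#' conditioned inhibition, overexpectation). Each representation carries its
#' own asymptote \eqn{\lambda_i = H A_i/\Psi_i(t^*)}; when the elements of a
#' compound time different durations their asymptotes differ, and the
#' steady-state system is inconsistent - associative strengths then drift
#' apart without bound under prolonged compound training, a structural
#' property of the model (it underlies both duration-dependent blocking and
#' the inhibitory solution in the reversed-duration arrangement).
#'
#' @param V Numeric vector of current associative strengths.
#' @param x Activations \eqn{x_i(\Psi_i)} at the update time (same length).
#' @param lambda Asymptote(s): scalar or per-representation vector.
#' @param alpha_v Learning rate(s) in (0, 1): scalar or per-representation.
#' @return Updated `V`.
#' @examples
#' rw_update(V = 0, x = 1, lambda = 1, alpha_v = 0.1)  # 0.1
#' @export
rw_update <- function(V, x, lambda, alpha_v) {
  stopifnot(length(V) == length(x), all(alpha_v > 0), all(alpha_v < 1))
  prediction <- sum(V * x)
  V + alpha_v * (lambda - prediction) * x
}

#' Real-time conditioned response
#'
#' Responding to a representation is the product of its associative strength
#' and current activation, \eqn{CR(t) = V\,x(\Psi)}. Reported behaviour is
#' floored at zero: associative strength may be negative (conditioned
#' inhibition) but response output cannot be; inhibition expresses through
#' the summation term instead.
#'
#' @param V Associative strength(s).
#' @param x Activation(s); vectorised with `V`.
#' @param floor If `TRUE` (default) negative products are reported as 0.
#' @return CR value(s).
#' @export
cr_response <- function(V, x, floor = TRUE) {
  r <- V * x
  if (floor) pmax(r, 0) else r
}

#' Pearce-Hall prediction error
#'
#' The signed error between the time-scaled US asymptote and the pooled
#' prediction, \eqn{\delta = \lambda - V x}, that drives learning-rate
#' adaptation in the Pearce-Hall extension.
#'
#' @inheritParams us_asymptote
#' @param V Associative strength(s).
#' @param x Activation(s) at the target time.
#' @return \eqn{\delta}.
#' @export
ph_error <- function(H, slope, psi_at_target, V, x) {
  us_asymptote(H, slope, psi_at_target) - sum(V * x)
}

#' Pearce-Hall learning-rate update
#'
#' Tracks the absolute prediction error:
#' \deqn{\alpha_V(n+1) = \alpha_V(n) + \gamma\,(|\delta| - \alpha_V(n)).}
#' Repeated zero-error trials (e.g. nonreinforced preexposure of a neutral
#' stimulus) decay the rate geometrically toward 0, producing latent
#' inhibition when reinforcement later begins; surprising outcomes raise it
#' again.
#'
#' @param alpha Current adaptive rate \eqn{\alpha_V(n)} (>= 0).
#' @param delta Prediction error \eqn{\delta} for the trial.
#' @param gamma Adaptation rate \eqn{\gamma} in (0, 1).
#' @return Updated rate (always >= 0).
#' @export
ph_rate_update <- function(alpha, delta, gamma) {
  stopifnot(all(alpha >= 0), gamma > 0, gamma < 1)
  alpha + gamma * (abs(delta) - alpha)
}

#' Steady-state associative strength
#'
#' Setting \eqn{\Delta V = 0} in the single-CS update gives the expected
#' plateau of the acquisition curve,
#' \deqn{V_\infty = \frac{H\,A_\infty\,x(\Psi_{t^*})}{\Psi(t^*)},}
#' an expected-value approximation: \eqn{\Psi(t^*)} is a random variable, so
#' the simulated plateau fluctuates around (and with accumulator noise sits
#' slightly above) this value. With a converged timer and maximal activation
#' it reduces to \eqn{H/t^*} - the inverse scaling of response strength with
#' the reinforcement delay that produces the ISI effect.
#'
#' @param H US magnitude (>= 0).
#' @param slope Converged slope \eqn{A_\infty} (per second).
#' @param x_at_target Activation at the target time (default 1, its maximum).
#' @param psi_at_target Accumulation at the target time (default `theta` = 1).
#' @return The asymptotic associative strength.
#' @examples
#' steady_state_v(H = 5, slope = 1/5)   # 1
#' @export
steady_state_v <- function(H, slope, x_at_target = 1, psi_at_target = 1) {
  stopifnot(all(H >= 0), all(slope > 0), all(psi_at_target > 0),
            all(x_at_target >= 0))
  H * slope * x_at_target / psi_at_target
}
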