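#' Create a drift-diffusion interval timer
#'
#' The timing core of the RWDDM is a noisy linear accumulator \eqn{\Psi(t)}
#' with adaptive drift (slope) \eqn{A}. The accumulator starts at stimulus
#' onset and rises at rate \eqn{A} per unit time; an interval is "timed" when
#' \eqn{\Psi} crosses the fixed threshold \eqn{\theta}. Intervals of different
#' lengths are accommodated not by moving the threshold but by adapting the
#' slope, so that \eqn{1/A} comes to encode an exponential moving harmonic
#' average of the experienced intervals.
#'
#' All times are in seconds and slopes in 1/seconds throughout the package
#' (the arithmetic is unit-consistent, so a user working in, say,
#' milliseconds need only supply `slope` and `dt` in matching units).
#'
#' @param slope Initial accumulation rate \eqn{A(1)} (> 0, per second). The
#'   default `1e-3` deliberately *over*-estimates novel stimulus durations;
#'   the slope-adaptation rule then converges to \eqn{\theta/t^*} within a
#'   few trials.
#' @param theta Accumulation threshold \eqn{\theta} (> 0, dimensionless).
#' @param m Noise factor \eqn{m} (>= 0, dimensionless). Controls the
#'   coefficient of variation of threshold-crossing times, \eqn{m/\sqrt\theta}.
#' @param alpha_t Slope adaptation rate \eqn{\alpha_t} in (0, 1).
#' @return An object of class `rwddm_timer`: a list with elements `slope`,
#'   `theta`, `m`, `alpha_t`, `psi` (current accumulation, 0 at creation) and
#'   `running` (FALSE at creation).
#' @seealso [timer_step()], [slope_update()], [crossing_cv()]
#' @examples
#' tm <- timer_state(slope = 1/5, m = 0)
#' tm <- timer_start(tm)
#' for (i in 1:500) tm <- timer_step(tm, dt = 0.01)
#' tm$psi          # 1: crosses threshold exactly at t = theta/A = 5 s
#' time_estimate(tm)
#' @export
timer_state <- function(slope = 1e-3, theta = 1, m = 0.15, alpha_t = 0.1) {
  stopifnot(is.numeric(slope), length(slope) == 1L, slope > 0,
            is.numeric(theta), length(theta) == 1L, theta > 0,
            is.numeric(m), length(m) == 1L, m >= 0,
            is.numeric(alpha_t), length(alpha_t) == 1L,
            alpha_t > 0, alpha_t < 1)
  structure(list(slope = slope, theta = theta, m = m, alpha_t = alpha_t,
                 psi = 0, running = FALSE),
            class = "rwddm_timer")
}

#' Start a timer
#'
#' Marks the timer as running (the owning stimulus has come on). The
#' accumulation is left at 0; use [timer_reset()] at stimulus offset.
#'
#' @param timer An `rwddm_timer`.
#' @return The timer with `running = TRUE`.
#' @export
timer_start <- function(timer) {
  timer$running <- TRUE
  timer
}

#' Advance a running timer by one time step
#'
#' Applies one accumulator increment. With the default diffusion-scaled
#' noise the increment is
#' \deqn{\Delta\Psi = A\,\Delta t + m\sqrt{A\,\Delta t}\; z,\qquad z\sim N(0,1),}
#' which makes \eqn{\Psi(t)} a discretised Wiener process with drift \eqn{A}
#' and infinitesimal variance \eqn{m^2 A}; its threshold-crossing times are
#' then inverse-Gaussian with coefficient of variation \eqn{m/\sqrt\theta}
#' independent of the interval timed (timescale invariance). The alternative
#' `noise = "linear"` uses the literal-linear term \eqn{m A \Delta t\, z},
#' provided for sensitivity checks; it does not preserve the closed-form CV.
#'
#' Accumulation is not capped: \eqn{\Psi} may rise past \eqn{\theta}.
#'
#' @param timer A running `rwddm_timer`.
#' @param dt Time step (> 0, seconds).
#' @param noise A standard-normal draw. Defaults to `rnorm(1)`; pass a value
#'   to make the step deterministic.
#' @param noise_form `"diffusion"` (default) or `"linear"`.
#' @return The timer with `psi` incremented.
#' @export
timer_step <- function(timer, dt, noise = NULL,
                       noise_form = c("diffusion", "linear")) {
  if (!isTRUE(timer$running))
    stop("timer_step() called on a non-running timer; call timer_start() first")
  stopifnot(dt > 0)
  noise_form <- match.arg(noise_form)
  if (is.null(noise)) noise <- stats::rnorm(1L)
  drift <- timer$slope * dt
  scale <- if (noise_form == "diffusion") sqrt(drift) else drift
  timer$psi <- timer$psi + drift + timer$m * scale * noise
  timer
}

#' Stop and reset a timer
#'
#' Called at stimulus offset: the accumulation is cleared and the timer
#' stops, but the learned slope persists across trials (it is the memory for
#' the timed interval).
#'
#' @param timer An `rwddm_timer`.
#' @return The timer with `psi = 0` and `running = FALSE`; `slope` unchanged.
#' @export
timer_reset <- function(timer) {
  timer$psi <- 0
  timer$running <- FALSE
  timer
}

#' Adapt the timer slope from the accumulation at the target time
#'
#' The slope update applied once per occurrence of the timed interval, at the
#' target time \eqn{t^*} (US delivery on reinforced trials, stimulus offset
#' otherwise):
#' \deqn{\Delta A = \alpha_t\, A\, \frac{\theta - \Psi(t^*)}{\Psi(t^*)}.}
#' It is the gradient-descent step on the squared slope error
#' \eqn{(\theta/t^* - A)^2} with the physical \eqn{t^*} replaced by the
#' internal estimate \eqn{\Psi(t^*)/A}. Its fixed point is
#' \eqn{A = \theta/t^*}; with \eqn{\theta = 1}, iterating it over a sequence
#' of intervals makes \eqn{1/A} an exponential moving harmonic average of
#' those intervals.
#'
#' @param timer An `rwddm_timer`.
#' @param psi_at_target Accumulation \eqn{\Psi(t^*)} observed at the target
#'   time. Must be > 0 (the rule divides by it); the protocol engine guards
#'   degenerate values before calling.
#' @return The timer with its `slope` updated.
#' @export
slope_update <- function(timer, psi_at_target) {
  if (!is.numeric(psi_at_target) || length(psi_at_target) != 1L ||
      !is.finite(psi_at_target) || psi_at_target <= 0)
    stop("psi_at_target must be a single positive number (degenerate accumulation)")
  timer$slope <- timer$slope +
    timer$alpha_t * timer$slope * (timer$theta - psi_at_target) / psi_at_target
  timer
}

#' Internal time estimate of a timer
#'
#' The psychological estimate of elapsed physical time: the current
#' accumulator reading divided by the current slope, \eqn{\Psi/A}.
#'
#' @param timer An `rwddm_timer`.
#' @return Estimated elapsed time (seconds).
#' @export
time_estimate <- function(timer) {
  stopifnot(timer$slope > 0)
  timer$psi / timer$slope
}

#' Closed-form coefficient of variation of threshold-crossing times
#'
#' For the diffusion-scaled accumulator the first-passage time of threshold
#' `theta` has CV \eqn{m/\sqrt\theta}, independent of the interval timed:
#' the analytic statement of timescale invariance used as the oracle for
#' Monte-Carlo checks.
#'
#' @param theta Threshold (> 0).
#' @param m Noise factor (>= 0).
#' @return The coefficient of variation.
#' @export
crossing_cv <- function(theta, m) {
  stopifnot(is.numeric(theta), all(theta > 0), is.numeric(m), all(m >= 0))
  m / sqrt(theta)
}

# Vectorised accumulator path: cumulative Psi after each of n_steps increments.
# One rnorm(n_steps) call, so traces are reproducible given the RNG state.
psi_path <- function(slope, m, dt, n_steps, noise_form = "diffusion") {
  if (n_steps <= 0L) return(numeric(0))
  drift <- slope * dt
  scale <- if (identical(noise_form, "linear")) drift else sqrt(drift)
  inc <- drift + m * scale * stats::rnorm(n_steps)
  cumsum(inc)
}

#' Simulate first threshold-crossing times of the accumulator
#'
#' Runs `n` independent accumulator realisations at fixed slope and returns
#' the time at which each first reaches `theta`. Used for Monte-Carlo checks
#' of the crossing-time distribution against [crossing_cv()].
#'
#' @param slope Accumulation rate (> 0, per second).
#' @param theta Threshold (> 0).
#' @param m Noise factor.
#' @param dt Step size in seconds (crossing times are resolved to `dt`).
#' @param n Number of realisations.
#' @param max_time Give up after this long; realisations that have not
#'   crossed are returned as `NA` (with `m` small this does not occur).
#' @return Numeric vector of length `n` of first-crossing times (seconds).
#' @export
crossing_times <- function(slope, theta = 1, m = 0.15, dt = 0.01,
                           n = 1000L, max_time = 5 * theta / slope) {
  stopifnot(slope > 0, theta > 0, m >= 0, dt > 0, n >= 1L)
  n_steps <- ceiling(max_time / dt)
  out <- numeric(n)
  done <- 0L
  chunk <- max(1L, floor(2e6 / n_steps))
  while (done < n) {
    k <- min(chunk, n - done)
    drift <- slope * dt
    inc <- matrix(drift + m * sqrt(drift) * stats::rnorm(n_steps * k),
                  nrow = n_steps, ncol = k)
    psi <- apply(inc, 2L, cumsum)
    if (n_steps == 1L) psi <- matrix(psi, nrow = 1L)
    running_max <- apply(psi, 2L, cummax)
    if (n_steps == 1L) running_max <- matrix(running_max, nrow = 1L)
    idx <- colSums(running_max < theta) + 1L
    t_cross <- ifelse(idx > n_steps, NA_real_, idx * dt)
    out[(done + 1L):(done + k)] <- t_cross
    done <- done + k
  }
  out
}
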