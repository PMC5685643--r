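#' Average the recorded response curves of selected trials
#'
#' Reduces a simulation trace to the standard summary of conditioning
#' experiments: response strength averaged pointwise over trials, as a
#' function of time within the trial.
#'
#' @param trace An `rwddm_trace` from [run_experiment()].
#' @param type Keep only trials of this type (`"reinforced"`,
#'   `"extinction"`, `"peak"`), if given.
#' @param stimuli Keep only trials whose stimulus set matches (labels joined
#'   by `+` in alphabetical order, e.g. `"A"` or `"A+B"`), if given.
#' @param phase Keep only trials from this phase, if given.
#' @param trials Explicit trial indices (applied after the other filters).
#' @param last_n Keep only the last `n` matching trials (e.g. average over
#'   the final 50 training trials).
#' @return An `rwddm_curve`: list with `time` (seconds, one point per step),
#'   `cr` (mean response) and `n_trials`.
#' @export
average_curve <- function(trace, type = NULL, stimuli = NULL, phase = NULL,
                          trials = NULL, last_n = NULL) {
  stopifnot(inherits(trace, "rwddm_trace"))
  tt <- trace$trials
  keep <- tt$recorded
  if (!is.null(type)) keep <- keep & tt$type %in% type
  if (!is.null(stimuli)) keep <- keep & tt$stimuli %in% stimuli
  if (!is.null(phase)) keep <- keep & tt$phase %in% phase
  if (!is.null(trials)) keep <- keep & tt$trial %in% trials
  idx <- tt$trial[keep]
  if (!is.null(last_n)) idx <- utils::tail(idx, last_n)
  if (length(idx) == 0L)
    stop("no recorded trials match the filter")
  lens <- lengths(trace$curves[idx])
  if (length(unique(lens)) != 1L)
    stop("selected trials have different durations; restrict the filter")
  m <- do.call(cbind, trace$curves[idx])
  new_curve(time = trace$dt * seq_len(nrow(m)),
            cr = rowMeans(m), n_trials = length(idx))
}

new_curve <- function(time, cr, n_trials = 1L) {
  stopifnot(length(time) == length(cr))
  structure(list(time = time, cr = cr, n_trials = n_trials),
            class = "rwddm_curve")
}

#' @export
print.rwddm_curve <- function(x, ...) {
  cat(sprintf("<rwddm_curve> %d points over %.4g s, mean of %d trial(s), max %.4g\n",
              length(x$time), max(x$time), x$n_trials, max(x$cr)))
  invisible(x)
}

#' @export
plot.rwddm_curve <- function(x, ..., xlab = "time (s)", ylab = "CR") {
  plot(x$time, x$cr, type = "l", xlab = xlab, ylab = ylab, ...)
}

#' Normalize a response curve for superimposition analysis
#'
#' Rescales response to proportion of the maximum and time to proportion of
#' a reference interval (the trained interval, or the curve's own peak
#' time). Timescale invariance predicts that curves from different
#' intervals superimpose after this normalization.
#'
#' @param curve An `rwddm_curve`.
#' @param reference_time Time divisor (seconds). Defaults to the curve's
#'   peak time.
#' @param smooth_window Smoothing used when the default reference (peak
#'   time) is computed; see [peak_time()].
#' @return The normalized `rwddm_curve` (max response 1).
#' @export
normalize_curve <- function(curve, reference_time = NULL, smooth_window = 1) {
  stopifnot(inherits(curve, "rwddm_curve"))
  mx <- max(curve$cr)
  if (mx <= 0) stop("cannot normalize an all-zero curve")
  if (is.null(reference_time))
    reference_time <- peak_time(curve, smooth_window = smooth_window)
  stopifnot(reference_time > 0)
  new_curve(curve$time / reference_time, curve$cr / mx, curve$n_trials)
}

#' Time of maximum response
#'
#' The peak time of a response curve, optionally after smoothing with a
#' centred moving average (raw stochastic curves are jagged; the default
#' 1-s window matches the resolution at which peak times are read off
#' empirical curves). Ties take the earliest time.
#'
#' @param curve An `rwddm_curve`.
#' @param smooth_window Width of the moving-average window in seconds;
#'   0 disables smoothing.
#' @return Peak time in the curve's time unit.
#' @export
peak_time <- function(curve, smooth_window = 1) {
  stopifnot(inherits(curve, "rwddm_curve"), length(curve$cr) >= 1L)
  y <- curve$cr
  if (smooth_window > 0 && length(y) > 3L) {
    dt <- curve$time[2L] - curve$time[1L]
    k <- max(1L, round(smooth_window / dt))
    if (k %% 2L == 0L) k <- k + 1L
    if (k > 1L && k <= length(y)) {
      y <- stats::filter(y, rep(1 / k, k), sides = 2)
      y[is.na(y)] <- -Inf
    }
  }
  curve$time[which.max(y)]
}

#' Trials needed to reach a criterion fraction of asymptote
#'
#' Operationalizes acquisition speed: the first trial on which associative
#' strength reaches `criterion` times its asymptote. Used to compare
#' acquisition with reacquisition (the model reacquires faster because the
#' timing memory survives extinction).
#'
#' @param v Numeric vector of per-trial associative strengths.
#' @param criterion Fraction of asymptote to reach (default 0.5).
#' @param asymptote The asymptotic strength; defaults to the mean of the
#'   last 10 values of `v`.
#' @return Integer trial index, or `NA` if the criterion is never reached.
#' @export
trials_to_criterion <- function(v, criterion = 0.5, asymptote = NULL) {
  stopifnot(length(v) >= 1L, criterion > 0)
  if (is.null(asymptote)) asymptote <- mean(utils::tail(v, 10L))
  hit <- which(v >= criterion * asymptote)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Early-window extinction measure
#'
#' The within-trial response measure used to compare extinction courses
#' across changed CS durations: the per-step CR is summed over the first
#' `window` seconds of each trial, the per-trial sums are averaged in
#' adjacent pairs (trial 1-2, 3-4, ...), and the pair means are divided by
#' `divisor` to rescale. A trailing unpaired trial is dropped.
#'
#' @param trace An `rwddm_trace`.
#' @param window Window length from trial onset, seconds (default 10).
#' @param divisor Rescaling divisor (default 100).
#' @param ... Trial filters passed to [average_curve()]'s selection
#'   (`type`, `stimuli`, `phase`, `trials`).
#' @return Numeric vector, one value per trial pair.
#' @export
first_window_rate <- function(trace, window = 10, divisor = 100, ...) {
  stopifnot(inherits(trace, "rwddm_trace"), window > 0, divisor > 0)
  tt <- trace$trials
  keep <- tt$recorded
  filt <- list(...)
  if (!is.null(filt$type)) keep <- keep & tt$type %in% filt$type
  if (!is.null(filt$stimuli)) keep <- keep & tt$stimuli %in% filt$stimuli
  if (!is.null(filt$phase)) keep <- keep & tt$phase %in% filt$phase
  if (!is.null(filt$trials)) keep <- keep & tt$trial %in% filt$trials
  idx <- tt$trial[keep]
  if (length(idx) == 0L) stop("no recorded trials match the filter")
  k <- round(window / trace$dt)
  sums <- vapply(trace$curves[idx], function(cr) {
    if (k > length(cr)) stop("window exceeds trial duration")
    sum(cr[seq_len(k)])
  }, numeric(1))
  n_pairs <- length(sums) %/% 2L
  if (n_pairs == 0L) stop("need at least two trials to pair-average")
  sums <- sums[seq_len(2L * n_pairs)]
  pair_means <- (sums[c(TRUE, FALSE)] + sums[c(FALSE, TRUE)]) / 2
  pair_means / divisor
}

#' Empirical coefficient of variation
#'
#' Standard deviation divided by the mean, using the population (1/n)
#' standard deviation. Applied to threshold-crossing or peak times across
#' replications, it estimates the timing CV whose analytic value is
#' [crossing_cv()].
#'
#' @param x Numeric vector (>= 2 values, positive mean).
#' @return The coefficient of variation.
#' @export
empirical_cv <- function(x) {
  stopifnot(length(x) >= 2L)
  mu <- mean(x)
  if (mu == 0) stop("mean is zero; CV undefined")
  sqrt(mean((x - mu)^2)) / mu
}

#' Superimposition error between two normalized response curves
#'
#' Quantifies "the curves roughly superimpose": both curves are normalized
#' (response to proportion of maximum, time to proportion of the reference
#' interval), linearly interpolated onto a common grid of `n_grid` points
#' spanning relative time 0 to `span` (clipped to the shorter curve), and
#' compared by root-mean-square error.
#'
#' @param curve1,curve2 `rwddm_curve` objects.
#' @param reference1,reference2 Time references for normalization (default:
#'   each curve's peak time).
#' @param n_grid Number of grid points (default 100).
#' @param span Upper end of the relative-time grid (default 2).
#' @return The RMSE between the normalized curves.
#' @export
superimposition_rmse <- function(curve1, curve2,
                                 reference1 = NULL, reference2 = NULL,
                                 n_grid = 100L, span = 2) {
  n1 <- normalize_curve(curve1, reference1)
  n2 <- normalize_curve(curve2, reference2)
  hi <- min(max(n1$time), max(n2$time), span)
  grid <- seq(0, hi, length.out = n_grid)
  y1 <- stats::approx(n1$time, n1$cr, xout = grid, rule = 2)$y
  y2 <- stats::approx(n2$time, n2$cr, xout = grid, rule = 2)$y
  sqrt(mean((y1 - y2)^2))
}

#' Harmonic mean of a set of intervals
#'
#' The slope-adaptation rule stores (with threshold 1) a moving harmonic
#' average of experienced intervals, so the non-moving harmonic mean of a
#' schedule's possible intervals is the analytic reference for the
#' remembered duration - e.g. 27.1 s for intervals drawn uniformly from the
#' integers 15 to 45 s.
#'
#' @param x Positive intervals.
#' @return `length(x) / sum(1/x)`.
#' @export
harmonic_mean <- function(x) {
  stopifnot(all(x > 0))
  length(x) / sum(1 / x)
}
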