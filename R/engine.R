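#' Choose the representation that drives responding in a synchronous compound
#'
#' When two independently trained stimuli that signal the same reinforcement
#' time are compounded, their timers run in parallel with slightly different
#' slopes (trial-to-trial noise in slope adaptation). Responding on the
#' compound trial is guided by the *faster* timer - the one with the larger
#' current slope - which is why averaged compound response curves are
#' left-shifted relative to single-stimulus curves (disinhibition of delay).
#' Ties break deterministically by lexicographic stimulus label.
#'
#' @param slope Numeric vector of the compound elements' current slopes.
#' @param label Their stimulus labels.
#' @return The index (into `slope`/`label`) of the chosen representation.
#' @export
select_compound_timer <- function(slope, label) {
  stopifnot(length(slope) == length(label), length(slope) >= 1L)
  order(-slope, label)[1L]
}

#' Combine two trained timers into a temporal-averaging compound
#'
#' On cross-modal compound probes the model assumes the two component
#' memories are only partially retrieved and fused into a single
#' representation: one rate and one strength. The default is the half-rate
#' combination
#' \deqn{A_{comp} = A_{low}/2 + A_{high}/2,\quad V_{comp} = V_{low}/2 + V_{high}/2,}
#' which places the compound peak at the harmonic mean of the two trained
#' intervals (e.g. 10 s and 20 s combine to \eqn{1/A_{comp}} = 13.33 s).
#' `weighting = "v_weighted"` instead weights each rate by its associative
#' strength, \eqn{A_{comp} = \frac{V_{low}}{V_{low}+V_{high}} A_{low} +
#' \frac{V_{high}}{V_{low}+V_{high}} A_{high}} (a weighted harmonic average
#' of the intervals), and weights V the same way.
#'
#' @param A_low,A_high Trained slopes of the long (low-rate) and short
#'   (high-rate) components.
#' @param V_low,V_high Their associative strengths.
#' @param weighting `"equal"` (default) or `"v_weighted"`.
#' @return List with the combined `A` and `V`.
#' @export
combine_temporal_average <- function(A_low, A_high, V_low, V_high,
                                     weighting = c("equal", "v_weighted")) {
  weighting <- match.arg(weighting)
  stopifnot(A_low > 0, A_high > 0)
  if (weighting == "equal") {
    list(A = (A_low + A_high) / 2, V = (V_low + V_high) / 2)
  } else {
    w <- V_low / (V_low + V_high)
    list(A = w * A_low + (1 - w) * A_high, V = w * V_low + (1 - w) * V_high)
  }
}

# -- model state ------------------------------------------------------------

init_state <- function(design) {
  p <- design$params
  reps <- design$reps
  n <- nrow(reps)
  state <- list(
    params = p,
    reps = data.frame(
      rep = reps$rep, cs = reps$cs,
      A = rep(p$A1, n), V = rep(0, n),
      sigma = rep(if (is.null(p$adaptive_width)) p$sigma
                  else p$adaptive_width$sigma0, n),
      alpha_v = rep(if (is.null(p$ph)) p$alpha_v else p$ph$alpha_novel, n),
      stringsAsFactors = FALSE))
  state
}

#' Run a single trial of the protocol engine
#'
#' Steps every timer belonging to a stimulus present in the trial from its
#' onset, evaluates the Gaussian representations at each time step, combines
#' them into a CR time series according to the trial's compound rule, and -
#' on non-probe trials - applies the end-of-trial updates: the
#' Rescorla-Wagner association update at the US (or, with H = 0, at
#' stimulus offset on extinction trials) followed by the timer slope update
#' at the same target time. Peak (probe) trials apply no updates. For a
#' stimulus with multiple representations (mixed-interval schedules) credit
#' is assigned to the representation maximally active at the target time,
#' and responding at each step is guided by the momentarily most active one.
#'
#' The per-step noise is drawn from the current RNG stream; use
#' [run_experiment()] for seeded full protocols.
#'
#' @param state Model state as produced by [run_experiment()]'s
#'   initialisation (parameters plus the per-representation table).
#' @param trial An `rwddm_trial` from [trial_spec()].
#' @return A list: `state` (updated), `cr` (per-step CR, length
#'   `duration/dt`), `records` (one row per participating representation
#'   with end-of-trial A, V, \eqn{\Psi(t^*)}, activation, \eqn{\lambda},
#'   \eqn{\alpha_V}, \eqn{\sigma}), and `chosen` (label of the compound
#'   element guiding responding, if the faster-timer rule applied).
#' @export
run_trial <- function(state, trial) {
  p <- state$params
  dt <- p$dt
  n_steps <- as.integer(round(trial$duration / dt))
  stim <- trial$stimuli
  reps <- state$reps

  unknown <- setdiff(stim$cs, reps$cs)
  if (length(unknown))
    stop("trial references unknown stimulus: ", paste(unknown, collapse = ", "))

  if (identical(trial$rule, "averaged")) {
    return(run_averaged_trial(state, trial, n_steps))
  }

  active <- which(reps$cs %in% stim$cs)
  k <- length(active)
  on_idx <- integer(k); n_on <- integer(k)
  x_mat <- matrix(0, nrow = n_steps, ncol = k)
  psi_end <- numeric(k)   # Psi at each rep's own target time
  for (j in seq_len(k)) {
    r <- active[j]
    s <- stim[match(reps$cs[r], stim$cs), ]
    o <- as.integer(round(s$onset / dt))
    non <- min(as.integer(round(s$duration / dt)), n_steps - o)
    psi <- psi_path(reps$A[r], p$m, dt, non, p$noise_form)
    x_mat[o + seq_len(non), j] <- activation(psi, p$theta, reps$sigma[r])
    on_idx[j] <- o; n_on[j] <- non
    # target time: US delivery if reinforced, stimulus offset otherwise
    t_idx <- if (trial$type == "reinforced")
      as.integer(round((trial$us_time - s$onset) / dt)) else non
    psi_end[j] <- if (t_idx >= 1L && t_idx <= non) psi[t_idx] else NA_real_
  }

  cs_of <- reps$cs[active]
  lab <- reps$rep[active]

  # per-CS contribution: multi-representation stimuli are expressed through
  # their momentarily most active representation
  contrib <- matrix(0, nrow = n_steps, ncol = length(unique(cs_of)))
  colnames(contrib) <- unique(cs_of)
  guide <- integer(0)  # which rep column guides each CS at the target time
  for (cs in unique(cs_of)) {
    cols <- which(cs_of == cs)
    if (length(cols) == 1L) {
      contrib[, cs] <- reps$V[active[cols]] * x_mat[, cols]
    } else {
      best <- max.col(x_mat[, cols, drop = FALSE], ties.method = "first")
      vx <- x_mat[, cols, drop = FALSE] *
        rep(reps$V[active[cols]], each = n_steps)
      contrib[, cs] <- vx[cbind(seq_len(n_steps), best)]
    }
  }

  chosen <- NA_character_
  if (identical(trial$rule, "faster_timer") && length(unique(cs_of)) > 1L) {
    pick <- select_compound_timer(reps$A[active], lab)
    chosen <- cs_of[pick]
    cr_raw <- contrib[, chosen]
  } else {
    cr_raw <- rowSums(contrib)
  }
  cr <- if (isTRUE(p$cr_floor)) pmax(cr_raw, 0) else cr_raw

  records <- NULL
  if (trial$type != "peak") {
    x_end <- vapply(seq_len(k), function(j) {
      if (is.na(psi_end[j])) NA_real_
      else activation(psi_end[j], p$theta, reps$sigma[active[j]])
    }, numeric(1))

    # credit assignment: one representation per multi-representation CS
    credited <- rep(TRUE, k)
    for (cs in unique(cs_of)) {
      cols <- which(cs_of == cs)
      if (length(cols) > 1L) {
        xe <- x_end[cols]
        xe[is.na(xe)] <- -Inf
        credited[cols] <- FALSE
        credited[cols[which.max(xe)]] <- TRUE
      }
    }
    # degenerate accumulation guard: skip updates where Psi(t*) is
    # nonpositive/negligible (activation there is ~0 anyway)
    usable <- credited & !is.na(psi_end) & (psi_end > p$psi_floor * p$theta)

    H_trial <- if (trial$type == "reinforced") p$H else 0
    lambda <- ifelse(usable & H_trial > 0,
                     H_trial * reps$A[active] / psi_end, 0)
    pred <- sum(reps$V[active][usable] * x_end[usable])

    dV <- numeric(k)
    dV[usable] <- reps$alpha_v[active][usable] *
      (lambda[usable] - pred) * x_end[usable]
    delta <- lambda - pred

    idx <- active[usable]
    reps$V[idx] <- reps$V[idx] + dV[usable]
    reps$A[idx] <- reps$A[idx] +
      p$alpha_t * reps$A[idx] * (p$theta - psi_end[usable]) / psi_end[usable]
    if (!is.null(p$ph)) {
      reps$alpha_v[idx] <- ph_rate_update(reps$alpha_v[idx],
                                          delta[usable], p$ph$gamma)
    }
    if (!is.null(p$adaptive_width)) {
      reps$sigma[active] <- width_update(reps$sigma[active],
                                         p$adaptive_width$rate,
                                         p$adaptive_width$target)
    }

    records <- data.frame(
      rep = lab, cs = cs_of,
      A = reps$A[active], V = reps$V[active],
      psi_target = psi_end, x_target = x_end, lambda = lambda,
      alpha_v = reps$alpha_v[active], sigma = reps$sigma[active],
      credited = usable, stringsAsFactors = FALSE)
  } else {
    records <- data.frame(
      rep = lab, cs = cs_of,
      A = reps$A[active], V = reps$V[active],
      psi_target = NA_real_, x_target = NA_real_, lambda = NA_real_,
      alpha_v = reps$alpha_v[active], sigma = reps$sigma[active],
      credited = FALSE, stringsAsFactors = FALSE)
  }

  state$reps <- reps
  list(state = state, cr = cr, records = records, chosen = chosen)
}

# temporal-averaging compound probe: a single virtual representation built
# by fractional retrieval of the component memories
run_averaged_trial <- function(state, trial, n_steps) {
  p <- state$params
  reps <- state$reps
  active <- which(reps$cs %in% trial$stimuli$cs)
  stopifnot(length(active) == 2L)
  lo <- active[which.min(reps$A[active])]
  hi <- active[which.max(reps$A[active])]
  comb <- combine_temporal_average(reps$A[lo], reps$A[hi],
                                   reps$V[lo], reps$V[hi],
                                   p$averaging_weighting)
  sigma <- mean(reps$sigma[active])
  psi <- psi_path(comb$A, p$m, p$dt, n_steps, p$noise_form)
  x <- activation(psi, p$theta, sigma)
  cr_raw <- comb$V * x
  cr <- if (isTRUE(p$cr_floor)) pmax(cr_raw, 0) else cr_raw
  records <- data.frame(
    rep = "compound", cs = paste(sort(unique(reps$cs[active])), collapse = "+"),
    A = comb$A, V = comb$V, psi_target = NA_real_, x_target = NA_real_,
    lambda = NA_real_, alpha_v = NA_real_, sigma = sigma,
    credited = FALSE, stringsAsFactors = FALSE)
  list(state = state, cr = cr, records = records, chosen = NA_character_)
}

#' Run a full experimental protocol
#'
#' Executes every phase of a design in order, carrying model state (timer
#' slopes, associative strengths, adaptive rates and widths) across phases.
#' All randomness - trial shuffling, interval sampling and accumulator
#' noise - flows from the single `seed`, so identical calls give
#' bit-identical traces.
#'
#' @param design An `rwddm_design` from [build_design()], or a preset name.
#' @param seed Integer seed. `NULL` uses the current RNG state.
#' @param overrides Passed to [build_design()] when `design` is a name.
#' @return An `rwddm_trace`: list with
#'   \describe{
#'     \item{trials}{per-trial `data.frame`: `trial`, `phase`, `type`,
#'       `stimuli` (labels joined by `+`), `duration`, `us_time`, `rule`,
#'       `chosen` (faster-timer choice), `recorded`.}
#'     \item{reps}{per-(trial, representation) `data.frame` of end-of-trial
#'       `A`, `V`, `psi_target`, `x_target`, `lambda`, `alpha_v`, `sigma`.}
#'     \item{curves}{list of per-step CR vectors (`NULL` for unrecorded
#'       trials); `curves[[i]]` matches `trials$trial == i`.}
#'     \item{dt, seed, design, params}{run metadata.}
#'   }
#' @examples
#' d <- build_design("isi_effect", overrides = list(n_trials = 5, m = 0))
#' tr <- run_experiment(d, seed = 1)
#' tail(subset(tr$reps, TRUE, c(trial, A, V)), 3)
#' @export
run_experiment <- function(design, seed = NULL, overrides = list()) {
  if (is.character(design)) design <- build_design(design, overrides)
  stopifnot(inherits(design, "rwddm_design"))
  if (!is.null(seed)) set.seed(as.integer(seed))

  state <- init_state(design)
  trial_rows <- list(); rep_rows <- list(); curves <- list()
  i <- 0L
  for (ph in design$phases) {
    trials <- ph$make()
    if (length(trials) != ph$n)
      stop("phase '", ph$name, "' generated ", length(trials),
           " trials, expected ", ph$n)
    for (tr in trials) {
      i <- i + 1L
      out <- run_trial(state, tr)
      state <- out$state
      trial_rows[[i]] <- data.frame(
        trial = i, phase = ph$name, type = tr$type,
        stimuli = paste(sort(unique(tr$stimuli$cs)), collapse = "+"),
        duration = tr$duration, us_time = tr$us_time, rule = tr$rule,
        chosen = out$chosen, recorded = isTRUE(tr$record),
        stringsAsFactors = FALSE)
      rr <- out$records
      rr$trial <- i
      rr$phase <- ph$name
      rep_rows[[i]] <- rr
      curves[[i]] <- if (isTRUE(tr$record)) out$cr else NULL
    }
  }
  structure(list(
    trials = do.call(rbind, trial_rows),
    reps = do.call(rbind, rep_rows),
    curves = curves,
    dt = design$params$dt,
    seed = seed,
    design = design$name,
    params = design$params,
    state = state), class = "rwddm_trace")
}

#' @export
print.rwddm_trace <- function(x, ...) {
  cat("<rwddm_trace>", x$design, "-", nrow(x$trials), "trials, dt =", x$dt,
      "s, seed =", if (is.null(x$seed)) "NULL" else x$seed, "\n")
  print(utils::head(x$trials, 3))
  invisible(x)
}
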