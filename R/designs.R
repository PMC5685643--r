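#' Construct a trial specification
#'
#' A trial is the atomic unit the protocol engine executes: a set of
#' stimuli (each with an onset and duration within the trial), an optional
#' US, and a response-combination rule for compounds.
#'
#' @param stimuli `data.frame` with columns `cs` (label), `onset` and
#'   `duration` (seconds within the trial).
#' @param duration Total trial duration (seconds). Defaults to the latest
#'   stimulus offset.
#' @param us_time Time of US delivery (seconds), or `NA` for non-reinforced
#'   trials. Must not exceed `duration`.
#' @param type `"reinforced"`, `"extinction"` (stimulus presented without
#'   the US, association and timing updates applied at offset with H = 0) or
#'   `"peak"` (long non-reinforced probe: no updates of any kind).
#' @param rule How compound responding is combined: `"sum"` (summing
#'   junction over all present representations), `"faster_timer"` (the CS
#'   whose timer currently has the larger slope drives responding alone) or
#'   `"averaged"` (a single virtual representation formed by half-rate
#'   combination; see [combine_temporal_average()]).
#' @param record Whether to keep the per-step CR curve for this trial.
#' @return A list of class `rwddm_trial`.
#' @export
trial_spec <- function(stimuli, duration = NULL, us_time = NA_real_,
                       type = c("reinforced", "extinction", "peak"),
                       rule = c("sum", "faster_timer", "averaged"),
                       record = TRUE) {
  type <- match.arg(type)
  rule <- match.arg(rule)
  stopifnot(is.data.frame(stimuli),
            all(c("cs", "onset", "duration") %in% names(stimuli)),
            nrow(stimuli) >= 1L,
            all(stimuli$duration > 0), all(stimuli$onset >= 0))
  if (is.null(duration)) duration <- max(stimuli$onset + stimuli$duration)
  if (type == "peak" && !is.na(us_time))
    stop("peak trials carry no US")
  if (type == "reinforced" && is.na(us_time))
    stop("reinforced trials need a us_time")
  if (!is.na(us_time) && us_time > duration + 1e-9)
    stop("us_time exceeds trial duration")
  structure(list(stimuli = stimuli, duration = duration, us_time = us_time,
                 type = type, rule = rule, record = record),
            class = "rwddm_trial")
}

# -- small builders used by the presets ------------------------------------

delay_trial <- function(cs, fi, record = TRUE) {
  trial_spec(data.frame(cs = cs, onset = 0, duration = fi),
             us_time = fi, type = "reinforced", record = record)
}

csonly_trial <- function(cs, dur, record = TRUE) {
  trial_spec(data.frame(cs = cs, onset = 0, duration = dur),
             type = "extinction", record = record)
}

peak_trial <- function(cs, dur, rule = "sum", record = TRUE) {
  trial_spec(data.frame(cs = cs, onset = 0, duration = dur),
             type = "peak", rule = rule, record = record)
}

compound_trial <- function(css, durations, us_time, type = "reinforced",
                           rule = "sum", record = TRUE) {
  # co-terminating compound: all elements end at the US (or trial end)
  end <- max(durations)
  trial_spec(data.frame(cs = css, onset = end - durations,
                        duration = durations),
             us_time = if (type == "reinforced") us_time else NA_real_,
             type = type, rule = rule, record = record)
}

shuffled <- function(trials) trials[sample.int(length(trials))]

rep_trials <- function(n, f) lapply(seq_len(n), function(i) f())

phase <- function(name, n, make) list(name = name, n = n, make = make)

default_params <- function() {
  list(theta = 1, m = 0.15, sigma = 0.3, alpha_t = 0.1, alpha_v = 0.1,
       H = 5, dt = 0.01, A1 = 1e-3, noise_form = "diffusion",
       cr_floor = TRUE, psi_floor = 1e-3,
       ph = NULL,             # list(alpha_novel=, gamma=) enables Pearce-Hall
       adaptive_width = NULL, # list(sigma0=, rate=, target=) enables Eq-24 widths
       averaging_weighting = "equal")
}

# representation table template: one timer+representation+V per row
rep_table <- function(rep, cs) data.frame(rep = rep, cs = cs,
                                          stringsAsFactors = FALSE)

#' Preset experimental designs
#'
#' Returns the catalogue of the ten built-in conditioning designs, with a
#' one-line account of phase structure and the default parameter set
#' (`m`, `theta`, `sigma`, `alpha_t`, `alpha_v`, `H`) each uses.
#'
#' @return A `data.frame` with columns `name`, `phases`, `parameters` and
#'   `options` (the design-specific override names accepted by
#'   [build_design()]).
#' @export
list_designs <- function() {
  info <- lapply(design_names(), function(nm) {
    d <- build_design(nm)
    ph <- paste(vapply(d$phases, function(p) sprintf("%s(%d)", p$name, p$n),
                       character(1)), collapse = " -> ")
    pars <- d$params
    data.frame(
      name = nm,
      phases = ph,
      parameters = sprintf("m=%g, theta=%g, sigma=%s, alpha_t=%g, alpha_v=%g, H=%g",
                           pars$m, pars$theta,
                           if (is.null(pars$adaptive_width)) sprintf("%g", pars$sigma)
                           else sprintf("%g->%g (adaptive)",
                                        pars$adaptive_width$sigma0,
                                        pars$adaptive_width$target),
                           pars$alpha_t, pars$alpha_v, pars$H),
      options = paste(names(d$args), collapse = ", "),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, info)
}

design_names <- function() {
  c("acquisition_extinction_reacquisition", "extinction_duration_change",
    "isi_effect", "vi_vs_fi", "mixed_fi", "latent_inhibition",
    "blocking_durations", "disinhibition_compound_peak",
    "conditioned_inhibition", "temporal_averaging")
}

#' Build a preset experimental design
#'
#' Assembles one of the ten built-in designs: its phase structure (trial
#' counts, stimulus durations, US times, interval distributions and probe
#' mixing), its default model parameters, and the representation table
#' (which stimuli carry one timer and which - mixed-interval stimuli -
#' carry two). Trial *orders* and sampled intervals within "mixed" phases
#' are drawn when the design is run, from the seeded generator of
#' [run_experiment()], so a design object is a reproducible recipe.
#'
#' Overrides may name any model parameter (`m`, `theta`, `sigma`,
#' `alpha_t`, `alpha_v`, `H`, `dt`, `A1`, `noise_form`, ...) or any
#' design-specific option listed by [list_designs()] (e.g. `fi` and
#' `n_trials` for `"isi_effect"`; `group` for `"latent_inhibition"` and
#' `"blocking_durations"`; `variant` for `"disinhibition_compound_peak"`;
#' `schedule` for `"vi_vs_fi"`; `weighting` for `"temporal_averaging"`).
#'
#' @param name One of the preset names from [list_designs()].
#' @param overrides Named list of parameter/option overrides.
#' @return A list of class `rwddm_design` with elements `name`, `params`,
#'   `args`, `reps` and `phases`.
#' @examples
#' d <- build_design("isi_effect", overrides = list(fi = 10, n_trials = 5))
#' d$phases[[1]]$n
#' @export
build_design <- function(name, overrides = list()) {
  if (length(name) != 1L || !name %in% design_names())
    stop("unknown design '", paste(name, collapse = ", "),
         "'; available presets: ", paste(design_names(), collapse = ", "))
  stopifnot(is.list(overrides))
  builder <- switch(name,
    acquisition_extinction_reacquisition = design_acq_ext_reacq,
    extinction_duration_change = design_ext_duration,
    isi_effect = design_isi,
    vi_vs_fi = design_vi_fi,
    mixed_fi = design_mixed_fi,
    latent_inhibition = design_latent_inhibition,
    blocking_durations = design_blocking,
    disinhibition_compound_peak = design_disinhibition,
    conditioned_inhibition = design_conditioned_inhibition,
    temporal_averaging = design_temporal_averaging)
  d <- builder()
  # split overrides into model parameters and design options
  for (nm in names(overrides)) {
    if (nm %in% names(d$args)) d$args[[nm]] <- overrides[[nm]]
    else if (nm %in% names(d$params)) d$params[[nm]] <- overrides[[nm]]
    else stop("unknown override '", nm, "' for design '", name,
              "'; parameters: ", paste(names(d$params), collapse = ", "),
              "; options: ", paste(names(d$args), collapse = ", "))
  }
  d <- builder(d$params, d$args)
  validate_design(d)
  d
}

validate_design <- function(d) {
  p <- d$params
  stopifnot(p$theta > 0, p$m >= 0, p$sigma > 0,
            p$alpha_t > 0, p$alpha_t < 1, p$alpha_v > 0, p$alpha_v < 1,
            p$H >= 0, p$dt > 0, p$A1 > 0)
  stopifnot(all(vapply(d$phases, function(ph) ph$n >= 0, logical(1))))
  invisible(d)
}

new_design <- function(name, params, args, reps, phases) {
  structure(list(name = name, params = params, args = args,
                 reps = reps, phases = phases),
            class = "rwddm_design")
}

#' @export
print.rwddm_design <- function(x, ...) {
  cat("<rwddm_design>", x$name, "\n")
  for (ph in x$phases) cat(sprintf("  %s: %d trials\n", ph$name, ph$n))
  invisible(x)
}

# -- the ten presets --------------------------------------------------------
# Each builder can be called with no arguments (defaults) or with
# (params, args) after overrides have been merged.

design_acq_ext_reacq <- function(params = NULL, args = NULL) {
  if (is.null(params)) {
    params <- utils::modifyList(default_params(),
      list(m = 0.15, sigma = 0.3, alpha_t = 0.1, alpha_v = 0.1, H = 5))
    args <- list(cs_duration = 5, n_acq = 80, n_ext = 100, n_reacq = 80)
  }
  a <- args
  new_design("acquisition_extinction_reacquisition", params, args,
    rep_table("A", "A"),
    list(
      phase("acquisition", a$n_acq,
            function() rep_trials(a$n_acq, function() delay_trial("A", a$cs_duration))),
      phase("extinction", a$n_ext,
            function() rep_trials(a$n_ext, function() csonly_trial("A", a$cs_duration))),
      phase("reacquisition", a$n_reacq,
            function() rep_trials(a$n_reacq, function() delay_trial("A", a$cs_duration)))))
}

design_ext_duration <- function(params = NULL, args = NULL) {
  if (is.null(params)) {
    params <- utils::modifyList(default_params(),
      list(m = 0.25, sigma = 0.35, alpha_t = 0.08, alpha_v = 0.09, H = 30))
    args <- list(acq_duration = 20, ext_duration = 40, n_acq = 150, n_ext = 150)
  }
  a <- args
  new_design("extinction_duration_change", params, args,
    rep_table("A", "A"),
    list(
      phase("acquisition", a$n_acq,
            function() rep_trials(a$n_acq, function() delay_trial("A", a$acq_duration))),
      phase("extinction", a$n_ext,
            function() rep_trials(a$n_ext, function() csonly_trial("A", a$ext_duration)))))
}

design_isi <- function(params = NULL, args = NULL) {
  if (is.null(params)) {
    params <- utils::modifyList(default_params(),
      list(m = 0.15, sigma = 0.3, alpha_t = 0.2, alpha_v = 0.1, H = 5))
    args <- list(fi = 5, n_trials = 150)
  }
  a <- args
  new_design("isi_effect", params, args,
    rep_table("A", "A"),
    list(phase("acquisition", a$n_trials,
               function() rep_trials(a$n_trials, function() delay_trial("A", a$fi)))))
}

design_vi_fi <- function(params = NULL, args = NULL) {
  if (is.null(params)) {
    params <- utils::modifyList(default_params(),
      list(m = 0.2, sigma = 0.3, alpha_t = 0.1, alpha_v = 0.1, H = 40))
    args <- list(schedule = "vi", vi_min = 15, vi_max = 45, fi = 30,
                 peak_duration = 135)
  }
  a <- args
  stopifnot(a$schedule %in% c("vi", "fi"))
  n_plus <- if (a$schedule == "vi") 1500L else 500L
  n_peak <- if (a$schedule == "vi") 375L else 125L
  make <- function() {
    plus <- rep_trials(n_plus, function() {
      fi <- if (a$schedule == "vi")
        sample(a$vi_min:a$vi_max, 1L) else a$fi
      delay_trial("A", fi, record = FALSE)
    })
    peaks <- rep_trials(n_peak, function() peak_trial("A", a$peak_duration))
    shuffled(c(plus, peaks))
  }
  new_design("vi_vs_fi", params, args, rep_table("A", "A"),
             list(phase("training", n_plus + n_peak, make)))
}

design_mixed_fi <- function(params = NULL, args = NULL) {
  if (is.null(params)) {
    params <- utils::modifyList(default_params(),
      list(m = 0.2, sigma = 0.425, alpha_t = 0.2, alpha_v = 0.1, H = 30))
    args <- list(short = 15, long = 75, n_short = 200, n_long = 200)
  }
  a <- args
  make <- function() {
    shuffled(c(rep_trials(a$n_short, function() delay_trial("A", a$short)),
               rep_trials(a$n_long, function() delay_trial("A", a$long))))
  }
  new_design("mixed_fi", params, args,
    rep_table(c("A.short", "A.long"), c("A", "A")),
    list(phase("training", a$n_short + a$n_long, make)))
}

design_latent_inhibition <- function(params = NULL, args = NULL) {
  if (is.null(params)) {
    params <- utils::modifyList(default_params(),
      list(m = 0.2, alpha_t = 0.1, alpha_v = 0.08, H = 4, sigma = 0.6,
           ph = list(alpha_novel = 0.4, gamma = 0.03),
           adaptive_width = list(sigma0 = 0.6, rate = 0.025, target = 0.35)))
    args <- list(group = "preexposed", cs_duration = 5,
                 n_preexposure = 80, n_conditioning = 250)
  }
  a <- args
  stopifnot(a$group %in% c("preexposed", "control"))
  n_pre <- if (a$group == "preexposed") a$n_preexposure else 0L
  new_design("latent_inhibition", params, args, rep_table("A", "A"),
    list(
      phase("preexposure", n_pre,
            function() rep_trials(n_pre, function() csonly_trial("A", a$cs_duration))),
      phase("conditioning", a$n_conditioning,
            function() rep_trials(a$n_conditioning,
                                  function() delay_trial("A", a$cs_duration)))))
}

design_blocking <- function(params = NULL, args = NULL) {
  if (is.null(params)) {
    params <- utils::modifyList(default_params(),
      list(m = 0.2, sigma = 0.35, alpha_t = 0.2, alpha_v = 0.1, H = 10))
    args <- list(group = "blocking", blocking_duration = 15,
                 blocked_duration = 10, n_pretraining = 120, n_compound = 60)
  }
  a <- args
  stopifnot(a$group %in% c("blocking", "control"))
  # blocking group: pretrained A then co-terminating A+X compound;
  # control group: the same compound with a novel C in place of A.
  first <- if (a$group == "blocking") "A" else "C"
  n_pre <- if (a$group == "blocking") a$n_pretraining else 0L
  us <- max(a$blocking_duration, a$blocked_duration)
  new_design("blocking_durations", params, args,
    rep_table(c(first, "X"), c(first, "X")),
    list(
      phase("pretraining", n_pre,
            function() rep_trials(n_pre,
              function() delay_trial(first, a$blocking_duration))),
      phase("compound", a$n_compound,
            function() rep_trials(a$n_compound,
              function() compound_trial(c(first, "X"),
                                        c(a$blocking_duration, a$blocked_duration),
                                        us_time = us)))))
}

design_disinhibition <- function(params = NULL, args = NULL) {
  if (is.null(params)) {
    params <- utils::modifyList(default_params(),
      list(m = 0.25, sigma = 0.18, alpha_t = 0.75, alpha_v = 0.1, H = 5))
    args <- list(variant = "compound_peak", fi = NULL, peak_duration = 100,
                 n_pre = 100, n_single = 300, n_compound = 100,
                 n_single_peak = 100)
  }
  a <- args
  stopifnot(a$variant %in% c("compound_peak", "disinhibition"))
  fi <- if (is.null(a$fi)) { if (a$variant == "compound_peak") 50 else 30 } else a$fi
  phase1 <- function() {
    if (a$variant == "compound_peak")
      shuffled(c(rep_trials(a$n_pre, function() delay_trial("A", fi, record = FALSE)),
                 rep_trials(a$n_pre, function() delay_trial("B", fi, record = FALSE))))
    else
      shuffled(c(rep_trials(a$n_pre, function() delay_trial("A", fi, record = FALSE)),
                 rep_trials(a$n_pre, function() csonly_trial("B", fi, record = FALSE))))
  }
  phase2 <- function() {
    rec1 <- a$variant == "disinhibition"  # response curves of singles are compared
    singles <- c(rep_trials(a$n_single, function() delay_trial("A", fi, record = rec1)),
                 rep_trials(a$n_single, function() delay_trial("B", fi, record = rec1)))
    if (a$variant == "compound_peak") {
      comp <- rep_trials(a$n_compound,
        function() compound_trial(c("A", "B"), c(a$peak_duration, a$peak_duration),
                                  us_time = NA, type = "peak",
                                  rule = "faster_timer"))
      spk <- c(rep_trials(a$n_single_peak %/% 2L,
                          function() peak_trial("A", a$peak_duration)),
               rep_trials(a$n_single_peak - a$n_single_peak %/% 2L,
                          function() peak_trial("B", a$peak_duration)))
      shuffled(c(singles, comp, spk))
    } else {
      comp <- rep_trials(a$n_compound,
        function() compound_trial(c("A", "B"), c(fi, fi), us_time = fi,
                                  rule = "faster_timer"))
      shuffled(c(singles, comp))
    }
  }
  n2 <- 2L * a$n_single + a$n_compound +
    if (a$variant == "compound_peak") a$n_single_peak else 0L
  new_design("disinhibition_compound_peak", params, args,
    rep_table(c("A", "B"), c("A", "B")),
    list(phase("training", 2L * a$n_pre, phase1),
         phase("testing", n2, phase2)))
}

design_conditioned_inhibition <- function(params = NULL, args = NULL) {
  if (is.null(params)) {
    params <- utils::modifyList(default_params(),
      list(m = 0.16, sigma = 0.35, alpha_t = 0.09, alpha_v = 0.06, H = 30))
    args <- list(short = 10, long = 30, n_phase1 = 300, n_phase2 = 300,
                 n_peak = 100, peak_duration = 90)
  }
  a <- args
  phase1 <- function() {
    shuffled(c(
      rep_trials(a$n_phase1, function() delay_trial("E1", a$short, record = FALSE)),
      rep_trials(a$n_phase1, function() delay_trial("E2", a$long, record = FALSE)),
      rep_trials(a$n_phase1, function()
        compound_trial(c("E1", "I1"), c(a$short, a$short), us_time = NA,
                       type = "extinction", record = FALSE)),
      rep_trials(a$n_phase1, function()
        compound_trial(c("E2", "I2"), c(a$long, a$long), us_time = NA,
                       type = "extinction", record = FALSE))))
  }
  phase2 <- function() {
    shuffled(c(rep_trials(a$n_phase2, function() delay_trial("E3", a$short, record = FALSE)),
               rep_trials(a$n_phase2, function() delay_trial("E3", a$long, record = FALSE))))
  }
  phase3 <- function() {
    shuffled(c(
      rep_trials(a$n_peak, function()
        compound_trial(c("E3", "I1"), c(a$peak_duration, a$peak_duration),
                       us_time = NA, type = "peak")),
      rep_trials(a$n_peak, function()
        compound_trial(c("E3", "I2"), c(a$peak_duration, a$peak_duration),
                       us_time = NA, type = "peak")),
      rep_trials(a$n_peak, function() peak_trial("E3", a$peak_duration))))
  }
  new_design("conditioned_inhibition", params, args,
    rep_table(c("E1", "E2", "I1", "I2", "E3.short", "E3.long"),
              c("E1", "E2", "I1", "I2", "E3", "E3")),
    list(phase("inhibition_training", 4L * a$n_phase1, phase1),
         phase("transfer_training", 2L * a$n_phase2, phase2),
         phase("summation_test", 3L * a$n_peak, phase3)))
}

design_temporal_averaging <- function(params = NULL, args = NULL) {
  if (is.null(params)) {
    params <- utils::modifyList(default_params(),
      list(m = 0.2, sigma = 0.35, alpha_t = 0.2, alpha_v = 0.1, H = 30))
    args <- list(short = 10, long = 20, n_reinforced = 700, n_peak = 154,
                 peak_duration = 60, weighting = "equal")
  }
  a <- args
  stopifnot(a$weighting %in% c("equal", "v_weighted"))
  params$averaging_weighting <- a$weighting
  make <- function() {
    shuffled(c(
      rep_trials(a$n_reinforced, function() delay_trial("S", a$short, record = FALSE)),
      rep_trials(a$n_reinforced, function() delay_trial("L", a$long, record = FALSE)),
      rep_trials(a$n_peak, function() peak_trial("S", a$peak_duration)),
      rep_trials(a$n_peak, function() peak_trial("L", a$peak_duration)),
      rep_trials(a$n_peak, function()
        compound_trial(c("S", "L"), c(a$peak_duration, a$peak_duration),
                       us_time = NA, type = "peak", rule = "averaged"))))
  }
  new_design("temporal_averaging", params, args,
    rep_table(c("S", "L"), c("S", "L")),
    list(phase("training", 2L * a$n_reinforced + 3L * a$n_peak, make)))
}
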