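#' Create a run configuration
#'
#' A run configuration names a preset design, parameter/option overrides, a
#' seed, and a replication count. It serializes losslessly to YAML
#' ([write_run_config()]/[read_run_config()]) and drives
#' [run_from_config()], which is also what the `exec/rwddm` command-line
#' front-end calls.
#'
#' @param design Preset name (see [list_designs()]).
#' @param overrides Named list of overrides, as in [build_design()].
#' @param seed Integer master seed; replication `i` runs with `seed + i - 1`.
#' @param reps Number of independent replications.
#' @param out_dir Output directory (optional; may also be given at run time).
#' @return A list of class `rwddm_config`.
#' @export
run_config <- function(design, overrides = list(), seed = 1L, reps = 1L,
                       out_dir = NULL) {
  stopifnot(is.character(design), length(design) == 1L,
            is.list(overrides),
            length(seed) == 1L, is.finite(seed),
            length(reps) == 1L, reps >= 1L)
  # validate design name and overrides eagerly
  invisible(build_design(design, overrides))
  structure(list(design = design, overrides = overrides,
                 seed = as.integer(seed), reps = as.integer(reps),
                 out_dir = out_dir),
            class = "rwddm_config")
}

#' @rdname run_config
#' @param path File path of a YAML configuration.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  need <- "design"
  if (!all(need %in% names(raw)))
    stop("config file must name a 'design'")
  run_config(design = raw$design,
             overrides = if (is.null(raw$overrides)) list() else raw$overrides,
             seed = if (is.null(raw$seed)) 1L else raw$seed,
             reps = if (is.null(raw$reps)) 1L else raw$reps,
             out_dir = raw$out_dir)
}

#' @rdname run_config
#' @param config An `rwddm_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "rwddm_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the experiment(s) described by a configuration
#'
#' Runs `reps` independent replications of the configured design, each with
#' its derived sub-seed, and writes per-replication trace files plus a
#' pooled summary. Outputs are plain text (CSV/JSON/YAML) and are
#' byte-reproducible for a given configuration.
#'
#' Files written under `out_dir`:
#' \describe{
#'   \item{`config.yaml`}{the configuration as run.}
#'   \item{`metadata.json`}{seed, design, package version, config MD5.}
#'   \item{`rep-<i>/trials.csv`, `rep-<i>/reps.csv`}{per-trial and
#'     per-representation records.}
#'   \item{`rep-<i>/curves.csv`}{long-format recorded CR curves
#'     (`trial`, `step`, `time`, `cr`).}
#'   \item{`summary.json`}{per-replication and pooled averaged-curve peak
#'     statistics from [summarize_trace()].}
#' }
#'
#' @param config An `rwddm_config` (or path to one).
#' @param out_dir Output directory; overrides the config's.
#' @return Invisibly, the list of `rwddm_trace` objects.
#' @export
run_from_config <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "rwddm_config"))
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("no output directory given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cfg_path <- file.path(out_dir, "config.yaml")
  write_run_config(config, cfg_path)

  traces <- vector("list", config$reps)
  summaries <- vector("list", config$reps)
  for (i in seq_len(config$reps)) {
    tr <- run_experiment(config$design, seed = config$seed + i - 1L,
                         overrides = config$overrides)
    rep_dir <- file.path(out_dir, sprintf("rep-%d", i))
    write_trace(tr, rep_dir)
    traces[[i]] <- tr
    s <- summarize_trace(tr)
    s$rep <- i
    summaries[[i]] <- s
  }
  all_s <- do.call(rbind, summaries)
  pooled <- NULL
  if (nrow(all_s)) {
    key <- interaction(all_s$phase, all_s$type, all_s$stimuli, drop = TRUE)
    pooled <- do.call(rbind, lapply(split(all_s, key), function(g) {
      data.frame(phase = g$phase[1], type = g$type[1], stimuli = g$stimuli[1],
                 reps = nrow(g),
                 mean_peak_time = mean(g$peak_time),
                 sd_peak_time = stats::sd(g$peak_time),
                 mean_max_cr = mean(g$max_cr),
                 stringsAsFactors = FALSE)
    }))
    rownames(pooled) <- NULL
  }
  jsonlite::write_json(
    list(per_rep = all_s, pooled = pooled),
    file.path(out_dir, "summary.json"),
    dataframe = "rows", digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(design = config$design, seed = config$seed, reps = config$reps,
         package_version = as.character(utils::packageVersion("rwddm")),
         config_md5 = unname(tools::md5sum(cfg_path))),
    file.path(out_dir, "metadata.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(traces)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trace to CSV files
#'
#' @param trace An `rwddm_trace`.
#' @param dir Directory for `trials.csv`, `reps.csv` and `curves.csv`.
#' @return Invisibly, `dir`.
#' @export
write_trace <- function(trace, dir) {
  stopifnot(inherits(trace, "rwddm_trace"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(trace$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  utils::write.csv(trace$reps, file.path(dir, "reps.csv"), row.names = FALSE)
  rec <- which(trace$trials$recorded)
  if (length(rec)) {
    long <- do.call(rbind, lapply(rec, function(i) {
      cr <- trace$curves[[i]]
      data.frame(trial = i, step = seq_along(cr),
                 time = trace$dt * seq_along(cr), cr = cr)
    }))
    utils::write.csv(long, file.path(dir, "curves.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a trace back from its CSV files
#'
#' Reconstructs an `rwddm_trace` (sufficient for the analysis layer) from a
#' directory written by [write_trace()]/[run_from_config()].
#'
#' @param dir Directory containing `trials.csv`, `reps.csv` and
#'   (optionally) `curves.csv`.
#' @param dt Time step of the run (seconds); defaults to the spacing found
#'   in `curves.csv`.
#' @return An `rwddm_trace`.
#' @export
read_trace <- function(dir, dt = NULL) {
  trials <- utils::read.csv(file.path(dir, "trials.csv"),
                            stringsAsFactors = FALSE)
  reps <- utils::read.csv(file.path(dir, "reps.csv"), stringsAsFactors = FALSE)
  curves <- vector("list", max(trials$trial))
  cpath <- file.path(dir, "curves.csv")
  if (file.exists(cpath)) {
    long <- utils::read.csv(cpath)
    if (is.null(dt)) dt <- long$time[1]
    for (g in split(long, long$trial)) curves[[g$trial[1]]] <- g$cr
  }
  structure(list(trials = trials, reps = reps, curves = curves,
                 dt = dt %||% 0.01, seed = NULL, design = "read_trace",
                 params = list(dt = dt %||% 0.01)), class = "rwddm_trace")
}

#' Peak statistics of a trace's averaged curves
#'
#' Groups the recorded trials by (phase, type, stimulus set), averages each
#' group's curves and reports peak time and height - the per-run numbers
#' the protocol analyses are built from.
#'
#' @param trace An `rwddm_trace`.
#' @param smooth_window Smoothing for [peak_time()] (seconds).
#' @return `data.frame` with one row per group.
#' @export
summarize_trace <- function(trace, smooth_window = 1) {
  tt <- trace$trials[trace$trials$recorded, , drop = FALSE]
  if (!nrow(tt)) return(data.frame())
  key <- interaction(tt$phase, tt$type, tt$stimuli, drop = TRUE)
  out <- lapply(split(tt, key), function(g) {
    # groups can mix durations (e.g. VI reinforced trials); use only the
    # modal duration so curves can be averaged
    dur <- as.numeric(names(which.max(table(g$duration))))
    g <- g[g$duration == dur, , drop = FALSE]
    cv <- average_curve(trace, trials = g$trial)
    data.frame(phase = g$phase[1], type = g$type[1], stimuli = g$stimuli[1],
               n_trials = nrow(g), duration = dur,
               peak_time = peak_time(cv, smooth_window),
               max_cr = max(cv$cr), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Miniature deterministic fixtures
#'
#' Small (<= 10 trial) schedules for fast closed-form checks and examples:
#' \describe{
#'   \item{`"fi_noiseless"`}{three reinforced 5-s FI trials with `m = 0`;
#'     every quantity on the trace has a closed form.}
#'   \item{`"vi_seeded"`}{eight reinforced trials with durations drawn from
#'     the discrete uniform 15-45 s; reproducible given `seed`.}
#'   \item{`"compound_unequal"`}{four 5-s A+ and four 10-s B+ trials
#'     followed by one AB probe under the faster-timer rule, exercising
#'     compound selection and the tie-break.}
#' }
#'
#' @param kind Fixture name.
#' @param seed Seed used to resolve the schedule.
#' @param path Optional file path; if given, the resolved schedule (one row
#'   per stimulus presentation) is written there as CSV.
#' @return List with the `design` (an `rwddm_design`) and the resolved
#'   `schedule` data.frame.
#' @export
make_fixture <- function(kind = c("fi_noiseless", "vi_seeded",
                                  "compound_unequal"),
                         seed = 1L, path = NULL) {
  kind <- match.arg(kind)
  design <- switch(kind,
    fi_noiseless = build_design("isi_effect",
                                overrides = list(n_trials = 3L, m = 0, fi = 5)),
    vi_seeded = {
      params <- utils::modifyList(default_params(), list(m = 0.2, H = 40))
      args <- list(vi_min = 15, vi_max = 45, n_trials = 8L)
      new_design("vi_fixture", params, args, rep_table("A", "A"),
        list(phase("training", args$n_trials, function()
          rep_trials(args$n_trials, function()
            delay_trial("A", sample(args$vi_min:args$vi_max, 1L))))))
    },
    compound_unequal = {
      # fast adaptation so both timers are tuned within the 4 trials each
      params <- utils::modifyList(default_params(),
                                  list(m = 0.05, alpha_t = 0.5))
      args <- list(fi_a = 5, fi_b = 10)
      new_design("compound_fixture", params, args,
        rep_table(c("A", "B"), c("A", "B")),
        list(
          phase("training", 8L, function()
            shuffled(c(rep_trials(4L, function() delay_trial("A", args$fi_a)),
                       rep_trials(4L, function() delay_trial("B", args$fi_b))))),
          phase("probe", 1L, function()
            list(compound_trial(c("A", "B"), c(20, 20), us_time = NA,
                                type = "peak", rule = "faster_timer")))))
    })
  set.seed(as.integer(seed))
  rows <- list(); i <- 0L
  for (ph in design$phases) {
    for (tr in ph$make()) {
      i <- i + 1L
      rows[[i]] <- data.frame(trial = i, phase = ph$name, type = tr$type,
                              cs = tr$stimuli$cs, onset = tr$stimuli$onset,
                              duration = tr$stimuli$duration,
                              us_time = tr$us_time,
                              trial_duration = tr$duration,
                              stringsAsFactors = FALSE)
    }
  }
  schedule <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(schedule, path, row.names = FALSE)
  list(design = design, schedule = schedule)
}
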