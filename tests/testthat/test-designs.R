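test_that("the preset catalogue lists ten designs with their phase structure", {
  cat <- list_designs()
  expect_equal(nrow(cat), 10L)
  expect_setequal(cat$name,
    c("acquisition_extinction_reacquisition", "extinction_duration_change",
      "isi_effect", "vi_vs_fi", "mixed_fi", "latent_inhibition",
      "blocking_durations", "disinhibition_compound_peak",
      "conditioned_inhibition", "temporal_averaging"))
  expect_true(all(nzchar(cat$phases)))
  expect_true(all(grepl("m=", cat$parameters)))
})

test_that("unknown names and overrides give enumerated errors", {
  expect_error(build_design("peak_procedure"), "available presets")
  expect_error(build_design("isi_effect", list(nonsense = 1)), "unknown override")
})

test_that("preset phase counts and generated trials match their designs", {
  counts <- list(
    acquisition_extinction_reacquisition = c(80, 100, 80),
    extinction_duration_change = c(150, 150),
    isi_effect = 150,
    vi_vs_fi = 1875,
    mixed_fi = 400,
    latent_inhibition = c(80, 250),
    blocking_durations = c(120, 60),
    disinhibition_compound_peak = c(200, 800),
    conditioned_inhibition = c(1200, 600, 300),
    temporal_averaging = 1862)
  set.seed(5)
  for (nm in names(counts)) {
    d <- build_design(nm)
    expect_equal(vapply(d$phases, function(p) p$n, numeric(1)),
                 unname(counts[[nm]]), label = nm)
    # trial-count conservation: generators emit exactly the declared counts
    for (p in d$phases) expect_length(p$make(), p$n)
  }
})

test_that("overrides reshape trial counts and parameters", {
  d <- build_design("isi_effect", overrides = list(n_trials = 5, fi = 10, m = 0))
  expect_equal(d$phases[[1]]$n, 5)
  expect_equal(d$params$m, 0)
  set.seed(1)
  tr <- d$phases[[1]]$make()[[1]]
  expect_equal(tr$us_time, 10)
})

test_that("the VI schedule draws integer intervals from 15-45 s with 1:4 peak mixing", {
  d <- build_design("vi_vs_fi")
  set.seed(9)
  trials <- d$phases[[1]]$make()
  types <- vapply(trials, function(t) t$type, character(1))
  expect_equal(sum(types == "reinforced"), 1500L)
  expect_equal(sum(types == "peak"), 375L)
  fis <- vapply(trials[types == "reinforced"], function(t) t$us_time, numeric(1))
  expect_true(all(fis %in% 15:45))
  expect_gt(length(unique(fis)), 20)  # genuinely variable
  expect_true(all(vapply(trials[types == "peak"], function(t) t$duration,
                         numeric(1)) == 135))
  # the analytic reference for the remembered interval
  expect_equal(harmonic_mean(15:45), 27.1, tolerance = 0.005)
})

test_that("blocking preset builds co-terminating compounds in both duration orders", {
  set.seed(2)
  d <- build_design("blocking_durations")  # A(15) blocks X(10)
  comp <- d$phases[[2]]$make()[[1]]
  expect_equal(comp$us_time, 15)
  expect_equal(comp$stimuli$onset[comp$stimuli$cs == "X"], 5)
  rev <- build_design("blocking_durations",
                      list(blocking_duration = 10, blocked_duration = 15))
  comp2 <- rev$phases[[2]]$make()[[1]]
  expect_equal(comp2$stimuli$onset[comp2$stimuli$cs == "A"], 5)
  ctl <- build_design("blocking_durations", list(group = "control"))
  expect_equal(ctl$phases[[1]]$n, 0L)       # no pretraining
  expect_setequal(ctl$phases[[2]]$make()[[1]]$stimuli$cs, c("C", "X"))
})

test_that("a zero-trial phase is an identity on model state", {
  ctl <- run_experiment("latent_inhibition", seed = 3,
                        overrides = list(group = "control",
                                         n_conditioning = 2))
  first <- ctl$reps[ctl$reps$trial == 1, ]
  # state entering conditioning is pristine: novel slope, V built from 0
  expect_false("preexposure" %in% ctl$trials$phase[ctl$trials$type != "none"])
  expect_lt(first$A, 0.05)
  expect_lt(abs(first$V), 0.2)
})

test_that("trial_spec validates its contracts", {
  st <- data.frame(cs = "A", onset = 0, duration = 5)
  expect_error(trial_spec(st, us_time = 6, type = "reinforced"), "exceeds")
  expect_error(trial_spec(st, us_time = 5, type = "peak"), "no US")
  expect_error(trial_spec(st, type = "reinforced"), "us_time")
  ok <- trial_spec(st, us_time = 5)
  expect_s3_class(ok, "rwddm_trial")
  expect_equal(ok$duration, 5)
})
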