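test_that("identical seeds give bit-identical traces", {
  d <- build_design("isi_effect", overrides = list(n_trials = 10))
  a <- run_experiment(d, seed = 7)
  b <- run_experiment(d, seed = 7)
  expect_identical(a$reps, b$reps)
  expect_identical(a$curves, b$curves)
  c2 <- run_experiment(d, seed = 8)
  expect_false(identical(a$curves, c2$curves))
})

test_that("a noiseless run reproduces the closed-form trial-by-trial arithmetic", {
  fx <- make_fixture("fi_noiseless")
  tr <- run_experiment(fx$design, seed = 1)
  p <- tr$params
  # independent hand iteration of the update equations (m = 0, 5-s CS)
  A <- p$A1; V <- 0
  for (n in 1:3) {
    psi <- A * 5
    x <- exp(-(psi - 1)^2 / (2 * p$sigma^2))
    lam <- p$H * A / psi
    V_new <- V + p$alpha_v * (lam - V * x) * x
    A_new <- A + p$alpha_t * A * (1 - psi) / psi
    rec <- tr$reps[tr$reps$trial == n, ]
    expect_equal(rec$psi_target, psi, tolerance = 1e-9)
    expect_equal(rec$V, V_new, tolerance = 1e-9)
    expect_equal(rec$A, A_new, tolerance = 1e-9)
    V <- V_new; A <- A_new
  }
  # recorded CR curve on trial 3 equals V(2) * x(A(2)*t) exactly
  rec2 <- tr$reps[tr$reps$trial == 2, ]
  t_grid <- tr$dt * seq_len(round(5 / tr$dt))
  expect_equal(tr$curves[[3]],
               pmax(rec2$V * exp(-(rec2$A * t_grid - 1)^2 / (2 * p$sigma^2)), 0),
               tolerance = 1e-9)
})

test_that("faster-timer selection picks the larger slope with a label tie-break", {
  expect_equal(select_compound_timer(c(0.1, 0.2), c("A", "B")), 2L)
  expect_equal(select_compound_timer(c(0.2, 0.2), c("B", "A")), 2L)  # 'A' wins ties
  # engine end-to-end: the compound fixture trains A to 1/5 and B to 1/10,
  # so A (faster) guides the probe
  fx <- make_fixture("compound_unequal")
  tr <- run_experiment(fx$design, seed = 1)
  probe <- tr$trials[tr$trials$phase == "probe", ]
  expect_equal(probe$chosen, "A")
  a_end <- tr$reps[tr$reps$trial == max(tr$reps$trial), ]
  expect_gt(a_end$A[a_end$rep == "A"], a_end$A[a_end$rep == "B"])
  cv <- average_curve(tr, phase = "probe")
  expect_lt(peak_time(cv), 7.5)  # responding is timed by A's 5-s memory
})

test_that("temporal-averaging combination has the printed arithmetic", {
  eq <- combine_temporal_average(A_low = 1/20, A_high = 1/10,
                                 V_low = 1, V_high = 1)
  expect_equal(1 / eq$A, 40/3, tolerance = 1e-12)  # 13.33-s compound peak
  expect_equal(eq$V, 1)
  # v-weighting with equal strengths is identical to equal weighting
  vw <- combine_temporal_average(1/20, 1/10, 2, 2, weighting = "v_weighted")
  expect_equal(vw$A, eq$A)
  # V_low = 2 V_high: A = (2/3) A_low + (1/3) A_high
  vw2 <- combine_temporal_average(1/20, 1/10, 2, 1, weighting = "v_weighted")
  expect_equal(vw2$A, (2/3) * (1/20) + (1/3) * (1/10))
})

test_that("mixed-interval credit goes to the representation active at reinforcement", {
  d <- build_design("mixed_fi", overrides = list(m = 0))
  st <- rwddm:::init_state(d)
  # tune the two representations to 15 s and 75 s
  st$reps$A <- c(1/15, 1/75)
  st$reps$V <- c(1, 1)
  out15 <- run_trial(st, rwddm:::delay_trial("A", 15))
  expect_equal(out15$records$credited, c(TRUE, FALSE))
  out75 <- run_trial(st, rwddm:::delay_trial("A", 75))
  expect_equal(out75$records$credited, c(FALSE, TRUE))
  # the uncredited representation is untouched
  expect_equal(out75$state$reps$A[1], 1/15)
  expect_equal(out75$state$reps$V[1], 1)
})

test_that("a full mixed-FI run yields two peaks of decreasing height near 15 and 75 s", {
  tr <- run_experiment("mixed_fi", seed = 2)
  long <- tr$trials[tr$trials$type == "reinforced" & tr$trials$duration == 75, ]
  cv <- average_curve(tr, trials = utils::tail(long$trial, 50))
  early <- cv$time >= 5 & cv$time <= 35
  late <- cv$time >= 55 & cv$time <= 75
  p1 <- cv$time[early][which.max(cv$cr[early])]
  p2 <- cv$time[late][which.max(cv$cr[late])]
  expect_lt(abs(p1 - 15), 5)
  expect_lt(abs(p2 - 75), 6)
  expect_gt(max(cv$cr[early]), max(cv$cr[late]))       # decreasing heights
  expect_gt(min(max(cv$cr[early]), max(cv$cr[late])),
            min(cv$cr[cv$time > 30 & cv$time < 55]))   # a trough between peaks
})

test_that("peak trials probe without updating, extinction updates timing but not with the US", {
  d <- build_design("isi_effect", overrides = list(n_trials = 30, fi = 5))
  tr <- run_experiment(d, seed = 3)
  st <- tr$state
  before <- st$reps
  pk <- run_trial(st, rwddm:::peak_trial("A", 15))
  expect_equal(pk$state$reps, before)                  # no updates on probes
  expect_length(pk$cr, round(15 / d$params$dt))
  ext <- run_trial(st, rwddm:::csonly_trial("A", 10))  # duration change 5 -> 10
  expect_lt(ext$state$reps$A, before$A)                # timing tracks the new duration
  expect_lt(abs(ext$state$reps$V), abs(before$V))      # V decays (lambda = 0)
  expect_equal(ext$records$lambda, 0)
})

test_that("slope tracks a duration change during extinction", {
  tr <- run_experiment("extinction_duration_change", seed = 4,
                       overrides = list(n_acq = 60, n_ext = 80))
  acq <- tr$reps[tr$reps$phase == "acquisition", ]
  ext <- tr$reps[tr$reps$phase == "extinction", ]
  expect_equal(1 / mean(utils::tail(acq$A, 10)), 20, tolerance = 0.12)
  expect_equal(1 / mean(utils::tail(ext$A, 10)), 40, tolerance = 0.15)
})

test_that("trials referencing unknown stimuli are configuration errors", {
  d <- build_design("isi_effect", overrides = list(n_trials = 2))
  st <- rwddm:::init_state(d)
  expect_error(run_trial(st, rwddm:::delay_trial("Z", 5)), "unknown stimulus")
})

test_that("phase generators that miscount are caught", {
  d <- build_design("isi_effect", overrides = list(n_trials = 3))
  d$phases[[1]]$make <- function() list(rwddm:::delay_trial("A", 5))
  expect_error(run_experiment(d, seed = 1), "expected 3")
})
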