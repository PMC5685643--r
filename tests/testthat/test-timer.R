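test_that("noiseless stepping is exactly linear accumulation", {
  # unit-agnostic: same arithmetic in ms units...
  tm <- timer_state(slope = 0.0002, m = 0, alpha_t = 0.1)
  tm <- timer_start(tm)
  tm <- timer_step(tm, dt = 10)
  expect_equal(tm$psi, 0.002)
  # ...and in seconds: crossing at theta/A after t*/dt steps
  tm <- timer_start(timer_state(slope = 1/5, m = 0))
  for (i in 1:500) tm <- timer_step(tm, dt = 0.01)
  expect_equal(tm$psi, 1, tolerance = 1e-12)
  expect_equal(time_estimate(tm), 5)
})

test_that("stepping a non-running timer is a contract violation", {
  tm <- timer_state()
  expect_error(timer_step(tm, dt = 0.01), "non-running")
})

test_that("reset clears accumulation but keeps the learned slope", {
  tm <- timer_start(timer_state(slope = 0.0002, m = 0.2))
  set.seed(1)
  for (i in 1:50) tm <- timer_step(tm, 0.01)
  tm <- timer_reset(tm)
  expect_identical(tm$psi, 0)
  expect_false(tm$running)
  expect_equal(tm$slope, 0.0002)
  # reset -> start reproduces a fresh timer's noiseless trajectory
  a <- timer_start(timer_reset(timer_start(timer_state(slope = 0.1, m = 0))))
  b <- timer_start(timer_state(slope = 0.1, m = 0))
  for (i in 1:20) { a <- timer_step(a, 0.05); b <- timer_step(b, 0.05) }
  expect_identical(a$psi, b$psi)
})

test_that("slope update matches the closed form and has its fixed point at theta", {
  tm <- timer_state(slope = 1e-6, alpha_t = 0.1)
  # psi at 5000 time units with A = 1e-6: 0.005; delta A = 0.1*1e-6*0.995/0.005
  up <- slope_update(tm, psi_at_target = 0.005)
  expect_equal(up$slope - 1e-6, 1.99e-5, tolerance = 1e-12)
  # fixed point: psi at threshold leaves the slope untouched
  fx <- slope_update(timer_state(slope = 0.2, theta = 1), 1)
  expect_equal(fx$slope, 0.2)
  expect_error(slope_update(tm, 0), "positive")
  expect_error(slope_update(tm, -0.1), "positive")
})

test_that("iterated noiseless slope updates converge monotonically to theta/t*", {
  tm <- timer_state(slope = 1e-6, theta = 1, alpha_t = 0.1)
  t_star <- 5
  slopes <- numeric(500)
  for (i in 1:500) {
    tm <- slope_update(tm, psi_at_target = tm$slope * t_star)
    slopes[i] <- tm$slope
  }
  expect_equal(tm$slope, 1 / t_star, tolerance = 1e-9)
  # monotone approach from below once past the first update
  expect_true(all(diff(slopes) >= -1e-15))
  expect_true(all(slopes <= 1 / t_star + 1e-12))
})

test_that("1/slope is the exponential moving harmonic average of intervals", {
  # independent oracle: closed-form geometric sum for the rate EMA
  # A_n = (1-a)^n A1 + a * sum_k (1-a)^(n-k) / t_k
  a <- 0.3
  A1 <- 1e-3
  set.seed(11)
  ts <- sample(c(4, 8, 15, 30), 40, replace = TRUE)
  oracle <- (1 - a)^length(ts) * A1 +
    a * sum((1 - a)^(length(ts) - seq_along(ts)) / ts)
  tm <- timer_state(slope = A1, theta = 1, alpha_t = a)
  for (t_k in ts) tm <- slope_update(tm, psi_at_target = tm$slope * t_k)
  expect_equal(tm$slope, oracle, tolerance = 1e-12)
})

test_that("crossing-time CV matches the m/sqrt(theta) closed form", {
  expect_equal(crossing_cv(1, 0), 0)
  expect_equal(crossing_cv(1, 0.15), 0.15)
  expect_equal(crossing_cv(4, 0.3), 0.15)
  expect_error(crossing_cv(0, 0.1))
  set.seed(21)
  ct <- crossing_times(slope = 1/5, theta = 1, m = 0.15, dt = 0.005, n = 3000)
  expect_false(anyNA(ct))
  cv <- empirical_cv(ct)
  se <- cv / sqrt(2 * length(ct))
  expect_lt(abs(cv - 0.15), 3 * se + 0.003)  # small discretisation allowance
  expect_equal(mean(ct), 5, tolerance = 0.02)
})

test_that("the literal-linear noise switch suppresses crossing-time variability", {
  set.seed(4)
  tm <- timer_start(timer_state(slope = 1/5, m = 0.2))
  psi_lin <- replicate(200, {
    t2 <- tm
    for (i in 1:10) t2 <- timer_step(t2, 0.01, noise_form = "linear")
    t2$psi
  })
  psi_dif <- replicate(200, {
    t2 <- tm
    for (i in 1:10) t2 <- timer_step(t2, 0.01, noise_form = "diffusion")
    t2$psi
  })
  expect_lt(stats::sd(psi_lin), stats::sd(psi_dif) / 5)
})

test_that("time_estimate divides accumulation by slope", {
  tm <- timer_state(slope = 1e-4)
  tm$psi <- 0.5
  expect_equal(time_estimate(tm), 5000)
  tm$psi <- 0
  expect_equal(time_estimate(tm), 0)
})
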