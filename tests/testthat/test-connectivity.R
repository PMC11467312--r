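alpha <- band_spec("alpha")

test_that("ciplv matches hand-computed complex-mean values", {
  expect_equal(ciplv(rep(pi / 2, 10)), 1, tolerance = 1e-12)
  expect_equal(suppressMessages(ciplv(rep(0, 10))), 0)
  # 4 trials {pi/2, pi/2, pi/2, 0}: C = 0.25 + 0.75i
  expect_equal(ciplv(c(pi / 2, pi / 2, pi / 2, 0)),
               0.75 / sqrt(1 - 0.0625), tolerance = 1e-12)
  expect_equal(ciplv(c(pi / 2, pi / 2, pi / 2, 0)), 0.7745967,
               tolerance = 1e-6)
  expect_error(ciplv(0.3), "at least 2")
})

test_that("analytic phase advances at the oscillation frequency", {
  fs <- 250
  t <- seq(1 / fs, 2, by = 1 / fs)
  rec <- make_recording(matrix(sin(2 * pi * 10 * t), 1), fs = fs,
                        labels = "Cz")
  pt <- analytic_phase(rec, alpha)
  step <- diff(pt$phase[1, , 1])
  step <- atan2(sin(step), cos(step))  # wrapped increments
  ok <- !pt$guard[-1]
  expect_lt(max(abs(step[ok] - 2 * pi * 10 / fs)), 0.05)
})

test_that("identical channels have zero phase difference", {
  set.seed(10)
  x <- rnorm(500)
  rec <- make_recording(rbind(x, x), labels = c("C3", "C4"))
  pt <- analytic_phase(rec, alpha)
  dphi <- pt$phase[1, !pt$guard, 1] - pt$phase[2, !pt$guard, 1]
  expect_equal(max(abs(dphi)), 0, tolerance = 1e-10)
})

test_that("a quarter-cycle delay shows as a pi/2 mean phase difference", {
  fs <- 250
  t <- seq(1 / fs, 2, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  y <- sin(2 * pi * 10 * t - pi / 2)  # delayed by quarter cycle of 10 Hz
  rec <- make_recording(rbind(x, y), fs = fs, labels = c("C3", "C4"))
  pt <- analytic_phase(rec, alpha)
  dphi <- pt$phase[1, !pt$guard, 1] - pt$phase[2, !pt$guard, 1]
  dphi <- atan2(sin(dphi), cos(dphi))
  expect_equal(mean(dphi), pi / 2, tolerance = 0.05)
})

test_that("band too low for the epoch length errors", {
  rec <- make_recording(matrix(rnorm(100), 1), fs = 250, labels = "Cz")
  expect_error(analytic_phase(rec, band_spec("delta", 1, 3)), "too short")
})

test_that("ciplv is invariant to a common per-trial phase offset", {
  set.seed(11)
  dphi <- runif(40, -pi, pi)
  base_x <- runif(40, -pi, pi)
  offset <- runif(40, -pi, pi)
  # phase difference is unchanged when both channels shift together
  v1 <- ciplv((base_x + dphi) - base_x)
  v2 <- ciplv((base_x + offset + dphi) - (base_x + offset))
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("zero-lag mixtures stay within the trial-count null band", {
  # y = x + eps * z: instantaneous mixing, no consistent lag
  sp <- study_spec(n_subjects = c(a = 1),
                   channels = c("F3", "F4", "Cz"), n_trials = 60, seed = 17)
  rec <- generate_coupled_epochs(sp)[[1]]
  for (eps in c(0.3, 1, 3)) {
    mixed <- rec
    mixed$data[2, , ] <- rec$data[1, , ] + eps * rec$data[2, , ]
    cm <- connectivity_matrix(mixed, alpha)
    null95 <- quantile(mc_ciplv_null(200, 60), 0.95)
    expect_lt(cm$values["F3", "F4"], null95)
  }
})

test_that("connectivity matrices are symmetric, bounded and deterministic", {
  sp <- study_spec(n_subjects = c(a = 1), channels = c("F3", "F4", "C3", "C4"),
                   n_trials = 20, seed = 23)
  rec <- generate_coupled_epochs(sp)[[1]]
  cm <- connectivity_matrix(rec, alpha)
  expect_equal(cm$values, t(cm$values))
  expect_true(all(diag(cm$values) == 0))
  expect_true(all(cm$values >= 0 & cm$values <= 1))
  cm2 <- connectivity_matrix(rec, alpha)
  expect_identical(cm$values, cm2$values)
})

test_that("ciplv stays in bounds on random phase inputs", {
  set.seed(12)
  for (i in 1:50) {
    v <- ciplv(runif(sample(2:30, 1), -pi, pi))
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
})

test_that("trial selection filters by label and enforces the minimum", {
  sp <- study_spec(n_subjects = c(a = 1), channels = c("F3", "F4", "Cz"),
                   n_trials = 10, seed = 3)
  rec <- generate_coupled_epochs(sp)[[1]]
  rec$trial_labels <- rep(c("NoGo-CR", "NoGo-FA"), 5)
  cm <- connectivity_matrix(rec, alpha, trial_selector = "NoGo-CR")
  expect_equal(cm$n_trials, 5)
  rec$trial_labels <- c("NoGo-CR", rep("NoGo-FA", 9))
  expect_error(connectivity_matrix(rec, alpha, trial_selector = "NoGo-CR"),
               "fewer than 2")
})
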