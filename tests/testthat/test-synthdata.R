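alpha <- band_spec("alpha")

small_study <- function(seed, strength = 1, lag = pi / 2, n_trials = 100,
                        channels = c("Fp1", "F3", "Fz", "F4", "C3", "Cz",
                                     "C4", "Pz")) {
  coup <- if (strength > 0) {
    list(a = list(coupling_spec(c("F3", "F4"), alpha, phase_lag = lag,
                                strength = strength)))
  } else list()
  study_spec(n_subjects = c(a = 1), channels = channels, n_trials = n_trials,
             coupling = coup, seed = seed)
}

test_that("generator output is a pure function of spec and seed", {
  r1 <- generate_coupled_epochs(small_study(4, n_trials = 10))
  r2 <- generate_coupled_epochs(small_study(4, n_trials = 10))
  expect_identical(r1[[1]]$data, r2[[1]]$data)
  r3 <- generate_coupled_epochs(small_study(5, n_trials = 10))
  expect_false(identical(r1[[1]]$data, r3[[1]]$data))
})

test_that("generated epochs have the spec'd shape and window", {
  sp <- study_spec(n_subjects = c(subacute = 2, chronic = 1), n_trials = 7)
  recs <- generate_coupled_epochs(sp)
  expect_length(recs, 3)
  expect_equal(dim(recs[[1]]$data), c(32, 200, 7))  # 800 ms at 250 Hz
  expect_equal(recs[[1]]$window, c(-300, 500))
  expect_equal(vapply(recs, attr, "", "group"),
               c(sub01 = "subacute", sub02 = "subacute", sub03 = "chronic"))
})

test_that("coupling channels must exist in the montage", {
  expect_error(
    study_spec(n_subjects = c(a = 1),
               coupling = list(a = list(coupling_spec(c("F3", "NOPE"))))),
    "NOPE")
})

test_that("full-strength quarter-cycle coupling yields high ciPLV", {
  rec <- generate_coupled_epochs(small_study(21))[[1]]
  cm <- connectivity_matrix(rec, alpha)
  expect_gt(cm$values["F3", "F4"], 0.8)
})

test_that("zero-lag coupling is invisible to ciPLV despite full strength", {
  # ciPLV of a perfectly zero-lag-coupled pair collapses to chance scale
  # (~1/sqrt(n_trials)), nowhere near the > 0.8 of a lagged pair
  rec <- generate_coupled_epochs(small_study(22, lag = 0))[[1]]
  cm <- connectivity_matrix(rec, alpha)
  expect_lt(cm$values["F3", "F4"], 0.15)
})

test_that("coupled pair dominates every uncoupled pair across seeds", {
  for (seed in 1:10) {
    rec <- generate_coupled_epochs(small_study(seed, n_trials = 60))[[1]]
    cm <- connectivity_matrix(rec, alpha)
    v <- cm$values
    coupled <- v["F3", "F4"]
    v["F3", "F4"] <- v["F4", "F3"] <- 0
    expect_gt(coupled, max(v[upper.tri(v)]))
  }
})

test_that("uncoupled ciPLV values match the Monte-Carlo null distribution", {
  set.seed(99)
  null_sample <- mc_ciplv_null(300, 60)
  for (seed in c(31, 32)) {
    rec <- generate_coupled_epochs(small_study(seed, strength = 0,
                                               n_trials = 60))[[1]]
    cm <- connectivity_matrix(rec, alpha)
    vals <- cm$values[upper.tri(cm$values)]
    ks <- suppressWarnings(ks.test(vals, null_sample))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("behavior simulator respects the task design", {
  log <- generate_behavior(seed = 8)
  expect_equal(nrow(log), 300)
  expect_equal(sum(log$stimulus == "Go"), 225)
  expect_equal(sum(log$stimulus == "NoGo"), 75)
  expect_true(all(table(log$block) == 60))
  # per-block composition 45/15
  comp <- tapply(log$stimulus == "Go", log$block, sum)
  expect_true(all(comp == 45))
  expect_true(all(log$isi_ms %in% c(800, 1000, 1200)))
  # pseudo-randomization: never more than 3 consecutive No-Go within a block
  for (b in unique(log$block)) {
    r <- rle(log$stimulus[log$block == b])
    expect_true(all(r$lengths[r$values == "NoGo"] <= 3))
  }
})

test_that("behavior simulator honors extreme response probabilities", {
  log <- generate_behavior(subject = list(hit_p = 1, fa_p = 0,
                                          rt_median_ms = 400, rt_sdlog = 0.2),
                           seed = 2)
  expect_true(all(log$responded[log$stimulus == "Go"]))
  expect_false(any(log$responded[log$stimulus == "NoGo"]))
  expect_true(all(log$rt_ms[log$responded] > 0))
  expect_true(all(is.na(log$rt_ms[!log$responded])))
})

test_that("behavior simulator is deterministic and validates probabilities", {
  expect_identical(generate_behavior(seed = 6), generate_behavior(seed = 6))
  expect_error(generate_behavior(subject = list(hit_p = 1.2, fa_p = 0,
                                                rt_median_ms = 400,
                                                rt_sdlog = 0.2)),
               "hit_p")
})
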