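test_that("bundled cohort matches its published structure", {
  coh <- load_reference_cohort()
  expect_s3_class(coh, "cohort_table")
  expect_equal(nrow(coh), 27)
  expect_equal(sum(coh$group == "subacute"), 13)
  expect_equal(sum(coh$group == "chronic"), 14)
  expect_equal(sum(is.na(coh$lesion_volume_mm3)), 5)
  expect_equal(sum(!is.na(coh$lesion_volume_mm3) & coh$group == "subacute"), 9)
  expect_equal(sum(!is.na(coh$lesion_volume_mm3) & coh$group == "chronic"), 13)
  # first subject as printed
  expect_equal(coh$age[1], 60)
  expect_equal(coh$sex[1], "M")
  expect_equal(coh$lesion_age_weeks[1], 8)
  expect_true(is.na(coh$lesion_volume_mm3[1]))
  expect_equal(coh$group[1], "subacute")
  # printed labels preserved verbatim: subject 25 is chronic at 25 weeks
  expect_equal(coh$group[coh$id == 25], "chronic")
  expect_equal(coh$lesion_age_weeks[coh$id == 25], 25)
})

test_that("bundled cohort reproduces the published group summaries", {
  coh <- load_reference_cohort()
  s <- coh$group == "subacute"
  expect_equal(mean(coh$age[s]), 63.08, tolerance = 1e-3)
  expect_equal(sd(coh$age[s]), 11.91, tolerance = 1e-3)
  expect_equal(mean(coh$age[!s]), 56.79, tolerance = 1e-3)
  expect_equal(mean(coh$lesion_age_weeks[s]), 13.38, tolerance = 1e-3)
  expect_equal(sd(coh$lesion_age_weeks[s]), 6.6, tolerance = 1e-2)
  expect_equal(mean(coh$lesion_age_weeks[!s]), 77.93, tolerance = 1e-3)
  expect_equal(sd(coh$lesion_age_weeks[!s]), 51.15, tolerance = 1e-3)
  expect_equal(mean(coh$lesion_volume_mm3[s], na.rm = TRUE), 50022.33,
               tolerance = 1e-6)
  expect_equal(mean(coh$lesion_volume_mm3[!s], na.rm = TRUE), 91862.69,
               tolerance = 1e-6)
})

test_that("generated cohorts derive the group label from lesion age", {
  spec <- cohort_spec(n_subacute = 5, n_chronic = 4,
                      lesion_age_subacute = c(2, 24))
  coh <- generate_cohort(spec, seed = 11)
  expect_equal(sum(coh$group == "subacute"), 5)
  expect_true(all(coh$lesion_age_weeks[coh$group == "subacute"] < 26))
  expect_true(all(coh$lesion_age_weeks[coh$group == "chronic"] >= 26))
})

test_that("cohort generation is deterministic and validates inputs", {
  expect_identical(generate_cohort(cohort_spec(), seed = 3),
                   generate_cohort(cohort_spec(), seed = 3))
  expect_error(cohort_spec(n_subacute = 0), "group sizes")
  expect_error(cohort_spec(lesion_age_subacute = c(2, 30)), "subacute")
  expect_error(cohort_spec(p_female = 1.4), "probabilities")
})

test_that("cohort CSV round-trips including missing volumes", {
  coh <- generate_cohort(cohort_spec(n_subacute = 3, n_chronic = 3), seed = 5)
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(coh, path)
  back <- read_cohort_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(coh))
})
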