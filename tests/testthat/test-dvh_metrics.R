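linear_dvh <- function(dmax = 60, total = 60) {
  # relative volume falls linearly from 1 at 0 Gy to 0 at dmax
  dvh(c(0, dmax), c(1, 0), structure = "rectum", total_volume = total)
}

test_that("dvh() validates its invariants", {
  expect_error(dvh(c(1, 2), c(1, 0), total_volume = 50), "start at 0")
  expect_error(dvh(c(0, 0), c(1, 0), total_volume = 50),
               "strictly increasing")
  expect_error(dvh(c(0, 10), c(0.9, 0), total_volume = 50),
               "start at relative volume 1")
  expect_error(dvh(c(0, 10, 20), c(1, 0.2, 0.5), total_volume = 50),
               "differential")
  expect_error(dvh(c(0, 10), c(1, 0), total_volume = -1), "positive volume")
})

test_that("dose_at_relative_volume() on hand-built shapes", {
  # step DVH: whole structure receives exactly D
  step <- dvh(c(0, 40, 40.001), c(1, 1, 0), total_volume = 50)
  for (v in c(0.9, 0.5, 0.1))
    expect_equal(dose_at_relative_volume(step, v), 40.001, tolerance = 1e-3)
  lin <- linear_dvh()
  expect_equal(dose_at_relative_volume(lin, 0.20), 48.0)  # line inversion
  expect_equal(dose_at_relative_volume(lin, 1), 0)
  expect_equal(dose_at_relative_volume(lin, 0), 60)       # max dose
  expect_error(dose_at_relative_volume(lin, 1.5), "\\[0, 1\\]")
  # non-increasing in v
  vs <- seq(0, 1, by = 0.05)
  expect_true(all(diff(dose_at_relative_volume(lin, vs)) <= 0))
})

test_that("flat segments resolve to the left-most crossing", {
  flat <- dvh(c(0, 10, 20, 30), c(1, 0.5, 0.5, 0), total_volume = 50)
  expect_equal(dose_at_relative_volume(flat, 0.5), 10)
})

test_that("absolute-volume metrics are the ratio identity", {
  lin <- linear_dvh(dmax = 60, total = 60)
  expect_equal(dose_at_absolute_volume(lin, 6), 54.0)     # v = 0.1
  lin50 <- linear_dvh(dmax = 60, total = 50)
  expect_equal(dose_at_absolute_volume(lin50, 10),
               dose_at_relative_volume(lin50, 0.2))
  expect_error(dose_at_absolute_volume(lin50, 75), "not evaluable")
  expect_error(dose_at_absolute_volume(lin50, 0), "positive")
})

test_that("metrics agree with the densified-grid brute-force oracle", {
  set.seed(101)
  for (k in 1:100) {
    d <- generate_dvh(d50 = runif(1, 25, 55), steepness = runif(1, 2, 8),
                      tail_dmax = runif(1, 60, 75),
                      noise_sd = runif(1, 0, 0.03), seed = k,
                      total_volume = runif(1, 34.59, 75.29))
    for (v in c(0.20, 0.10, 0.05, runif(1, 0.01, 0.9)))
      expect_equal(dose_at_relative_volume(d, v), ora_dvh_crossing(d, v),
                   tolerance = 1e-6)
    v_cc <- runif(1, 1, d$total_volume)
    expect_equal(dose_at_absolute_volume(d, v_cc),
                 dose_at_relative_volume(d, v_cc / d$total_volume))
  }
})

test_that("compliance evaluation flags margins and vacuous constraints", {
  cons <- cirt_fixture_constraints("nirs-16fx-lem")
  d <- generate_dvh_with_metrics(c("D20%" = 43.00, "D10%" = 53.0,
                                   "D5%" = 60.0, "D0%" = 64.0))
  rep <- evaluate_compliance(d, cons, patient_id = "X1")
  expect_s3_class(rep, "compliance_report")
  expect_equal(rep$margin[1], -0.14, tolerance = 1e-9)
  expect_true(all(rep$pass))
  expect_identical(attr(rep, "patient_id"), "X1")
  # empty set -> empty report
  empty <- constraint_set(cons[0, ])
  expect_identical(nrow(evaluate_compliance(d, empty)), 0L)
  # vacuous absolute constraint: not evaluable, not a silent pass
  vac <- dose_constraint("D60cc", "absolute-volume", 60, 54, "LEM", 16)
  rep2 <- evaluate_compliance(generate_dvh(38, 5, 60, total_volume = 40), vac)
  expect_false(rep2$evaluable)
  expect_true(is.na(rep2$pass))
})

test_that("cohort_summary() matches a direct sort oracle", {
  cons <- constraint_set(dose_constraint("D20%", "percent-volume", 0.2,
                                         43.14, "LEM", 16),
                         dose_constraint("D0%", "percent-volume", 0,
                                         68.33, "LEM", 16))
  vals <- list(c(40, 60), c(44, 62), c(38, 55))   # D20%, D0% per patient
  reps <- lapply(seq_along(vals), function(i)
    evaluate_compliance(generate_dvh_with_metrics(
      c("D20%" = vals[[i]][1], "D0%" = vals[[i]][2])), cons,
      patient_id = sprintf("P%d", i)))
  s <- cohort_summary(reps)
  expect_equal(s$median_measured, c(40, 60))
  expect_equal(s$max_measured, c(44, 62))
  expect_equal(s$n_exceed, c(1L, 0L))
  expect_true(all(s$median_measured <= s$max_measured))
  # single patient: median = max
  s1 <- cohort_summary(reps[1])
  expect_equal(s1$median_measured, s1$max_measured)
  # inconsistent labels are refused
  other <- evaluate_compliance(generate_dvh(38, 5, 60),
                               constraint_set(cons[1, ]))
  expect_error(cohort_summary(list(reps[[1]], other)), "inconsistent")
})
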