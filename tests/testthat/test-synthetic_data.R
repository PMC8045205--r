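test_that("generate_dvh() is deterministic and matches the logistic", {
  a <- generate_dvh(38, 5, 60, noise_sd = 0.02, seed = 11)
  b <- generate_dvh(38, 5, 60, noise_sd = 0.02, seed = 11)
  expect_identical(a, b)
  c2 <- generate_dvh(38, 5, 60, noise_sd = 0.02, seed = 12)
  expect_false(identical(a$rel_volume, c2$rel_volume))
  # clean curve: half the volume is covered at d50
  clean <- generate_dvh(38, 5, 60, noise_sd = 0)
  i50 <- which.min(abs(clean$dose - 38))
  expect_equal(clean$rel_volume[i50], 0.5, tolerance = 0.01)
  # analytic inversion oracle: D_x% of the logistic
  for (v in c(0.2, 0.1)) {
    analytic <- 38 + 5 * log((1 - v) / v)
    expect_equal(dose_at_relative_volume(clean, v), analytic,
                 tolerance = 0.1 / analytic)
  }
  expect_error(generate_dvh(-1, 5, 60), "invalid DVH shape")
  expect_error(generate_dvh(38, 5, 30), "invalid DVH shape")
})

test_that("metric-targeted generation round-trips", {
  tgt <- c("D20%" = 37.91, "D10%" = 53.53, "D0%" = 62.91)
  d <- generate_dvh_with_metrics(tgt, total_volume = 50.66)
  expect_equal(dose_at_relative_volume(d, 0.20), 37.91, tolerance = 0.05)
  expect_equal(dose_at_relative_volume(d, 0.10), 53.53, tolerance = 0.05)
  expect_equal(dose_at_relative_volume(d, 0), 62.91, tolerance = 0.05)
  # absolute-volume target uses the structure volume
  d2 <- generate_dvh_with_metrics(c("D10cc" = 37.58), total_volume = 50)
  expect_equal(dose_at_absolute_volume(d2, 10), 37.58, tolerance = 0.05)
  # single D0% target: max dose
  d3 <- generate_dvh_with_metrics(c("D0%" = 60))
  expect_equal(dose_at_relative_volume(d3, 0), 60, tolerance = 0.05)
  expect_error(generate_dvh_with_metrics(c("D20%" = 55, "D10%" = 50)),
               "inconsistent")
  expect_error(generate_dvh_with_metrics(c("Dfoo" = 50)), "cannot parse")
})

test_that("cohort generation hits exceedance counts exactly", {
  cons <- cirt_fixture_constraints("nirs-16fx-lem")
  co <- generate_cohort(38, cons, exceed_counts = c("D20%" = 8, "D10%" = 4),
                        seed = 20)
  expect_length(co$dvhs, 38)
  reports <- lapply(names(co$dvhs), function(id)
    evaluate_compliance(co$dvhs[[id]], cons, patient_id = id))
  s <- cohort_summary(reports)
  expect_equal(s$n_exceed[s$label == "D20%"], 8L)
  expect_equal(s$n_exceed[s$label == "D10%"], 4L)
  expect_equal(sum(s$n_exceed[s$label %in% c("D5%", "D0%")]), 0L)
  # nested head-sets: every D10% exceeder also exceeds D20%
  over20 <- vapply(reports, function(r) !r$pass[r$label == "D20%"],
                   logical(1L))
  over10 <- vapply(reports, function(r) !r$pass[r$label == "D10%"],
                   logical(1L))
  expect_true(all(which(over10) %in% which(over20)))
  # truth table agrees with the compliance pipeline
  for (i in seq_along(reports)) {
    tr <- co$truth[co$truth$patient_id == names(co$dvhs)[i], ]
    expect_equal(reports[[i]]$measured, tr$true_value, tolerance = 1e-9)
    expect_identical(!reports[[i]]$pass, tr$exceeds)
  }
  # volumes within the configured range
  vols <- vapply(co$dvhs, `[[`, numeric(1L), "total_volume")
  expect_true(all(vols >= 34.59 & vols <= 75.29))
})

test_that("cohort generation is reproducible and extendable", {
  cons <- cirt_fixture_constraints("nirs-16fx-lem")
  a <- generate_cohort(10, cons, c("D20%" = 2), seed = 5)
  b <- generate_cohort(10, cons, c("D20%" = 2), seed = 5)
  expect_identical(a, b)
  # growing the cohort does not reshuffle existing patients
  big <- generate_cohort(12, cons, c("D20%" = 2), seed = 5)
  expect_identical(big$dvhs[1:10], a$dvhs)
  # zero exceedances -> all pass
  z <- generate_cohort(5, cons, seed = 6)
  expect_false(any(z$truth$exceeds))
  expect_error(generate_cohort(5, cons, c("D20%" = 9), seed = 1),
               "cohort size")
  expect_error(generate_cohort(5, cons, c("nope" = 1), seed = 1),
               "labels")
})

test_that("synthetic conversion curves honour the ratio-decay model", {
  ident <- generate_conversion_curve(a = 0)
  grid <- seq(25, 65, by = 2.5)
  expect_equal(mkm_to_lem(ident, grid), grid, tolerance = 1e-9)
  # fit through the two extreme 16-fx anchors reproduces their ratios
  p <- fit_ratio_params(c(28.80, 60.80), c(43.14 / 28.80, 68.33 / 60.80))
  expect_equal(1 + p["a"] * exp(-28.80 / p["b"]), c(a = 43.14 / 28.80),
               tolerance = 1e-6)
  expect_equal(1 + p["a"] * exp(-60.80 / p["b"]), c(a = 68.33 / 60.80),
               tolerance = 1e-6)
  cv <- generate_conversion_curve(c(25, 65), a = p[["a"]], b = p[["b"]])
  expect_s3_class(cv, "conversion_curve")     # passed build validation
  ratios <- cv$lem / cv$mkm
  expect_true(all(diff(ratios) < 0))
  expect_true(all(diff(mkm_to_lem(cv, seq(25, 65, length.out = 500))) > 0))
  expect_error(generate_conversion_curve(a = -1), "a >= 0")
})
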