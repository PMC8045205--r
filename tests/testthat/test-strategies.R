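curves <- cirt_fixture_curves()
cv16 <- curves[["16"]]

test_that("constraint constructors validate", {
  expect_error(dose_constraint("D20%", "percent-volume", 1.2, 40, "MKM", 16),
               "fraction in")
  expect_error(dose_constraint("D10cc", "absolute-volume", -1, 40, "LEM", 16),
               "> 0 cc")
  expect_error(dose_constraint("D20%", "percent-volume", 0.2, 0, "MKM", 16),
               "positive dose")
  mixed <- rbind(as.data.frame(cirt_fixture_constraints("nirs-16fx")),
                 as.data.frame(cirt_fixture_constraints("cnao-16fx")))
  expect_error(constraint_set(mixed), "share one RBE model")
})

test_that("LEM LQ strategy reproduces published conversions", {
  nirs <- cirt_fixture_constraints("nirs-16fx")
  d20 <- constraint_set(nirs[1, ])
  r <- convert_lem_lq(d20, 12, cv16)
  expect_equal(round_half_up(r$target$limit), 39.55)
  expect_equal(unname(r$intermediates["LEM@16fx"]), 43.14, tolerance = 1e-9)
  expect_identical(r$target$model, "LEM")
  expect_identical(r$target$n_fractions, 12L)
  d10 <- constraint_set(nirs[2, ])
  expect_equal(round_half_up(convert_lem_lq(d10, 8, cv16)$target$limit), 45.86)
  # scheme_to = 16: the LQ step is the identity, result is the curve value
  expect_equal(convert_lem_lq(d20, 16, cv16)$target$limit, 43.14,
               tolerance = 1e-9)
})

test_that("MKM LQ strategy records the LQ intermediate then the curve step", {
  d20 <- constraint_set(cirt_fixture_constraints("nirs-16fx")[1, ])
  r <- convert_mkm_lq(d20, 12, curves[["12"]])
  expect_equal(round_half_up(r$target$limit), 37.60)  # anchor-exact fixture
  expect_equal(unname(r$intermediates["MKM@12fx"]),
               ora_iso_bisect(28.80, 16, 12), tolerance = 1e-9)
  expect_equal(round(unname(r$intermediates["MKM@12fx"]), 2), 26.77)
  # identity curve + same scheme returns the source limit unchanged
  ident <- conversion_curve(c(10, 70), c(10, 70), scheme = 16L)
  expect_equal(convert_mkm_lq(d20, 16, ident)$target$limit, 28.80)
  # curve/scheme mismatch is refused
  expect_error(convert_mkm_lq(d20, 8, curves[["12"]]), "labelled for 12")
  expect_error(convert_mkm_lq(constraint_set(cirt_fixture_constraints("cnao-16fx")[1, ]),
                              12, curves[["12"]]), "MKM-tagged")
})

test_that("LEM-native adaptation follows both orderings", {
  d10cc <- constraint_set(cirt_fixture_constraints("cnao-16fx")[1, ])
  r <- convert_lem_source(d10cc, "LEM_LQ", 12)
  expect_equal(round_half_up(r$target$limit), 49.14)
  expect_equal(convert_lem_source(d10cc, "LEM_LQ", 16)$target$limit, 54.00)
  r2 <- convert_lem_source(d10cc, "MKM_LQ", 12, curves)
  expect_equal(unname(r2$intermediates["MKM@16fx"]), 39.99,
               tolerance = 1e-9)                     # backward, anchor-exact
  expect_equal(round_half_up(r2$target$limit), 45.97)
  # backward-forward consistency at the source scheme with one curve
  r3 <- convert_lem_source(d10cc, "MKM_LQ", 16, list(`16` = cv16))
  expect_equal(r3$target$limit, 54.00, tolerance = 1e-6)
  expect_error(convert_lem_source(d10cc, "MKM_LQ", 12, list(`16` = cv16)),
               "needs curves")
})

test_that("relative_difference matches published cells and basics", {
  expect_equal(round_half_up(relative_difference(49.14, 45.97)), 6.90)
  expect_equal(relative_difference(5, 5), 0)
  # rounded-pair arithmetic may differ from unrounded chains by ~0.01
  expect_equal(relative_difference(42.59, 36.53), 16.58,
               tolerance = 0.02 / 16.58)
  expect_error(relative_difference(10, 0), "positive")
})

test_that("constraint table has the right shape and provenance", {
  nirs <- cirt_fixture_constraints("nirs-16fx")
  tab <- build_constraint_table(nirs, schemes = c(12, 8, 4),
                                curves = curves)
  vals <- unlist(tab[, grep("(mkm|lem)_lq_", names(tab))])
  expect_length(vals, 24)                      # 4 rows x 3 schemes x 2
  expect_length(unlist(tab[, grep("diff_", names(tab))]), 12)
  expect_false(anyNA(vals))
  # provenance completeness: last intermediate equals the target limit
  for (r in attr(tab, "results"))
    expect_equal(unname(r$intermediates[length(r$intermediates)]),
                 r$target$limit)
  # header-only table for an empty scheme list
  empty <- build_constraint_table(nirs, schemes = integer(), curves = curves)
  expect_identical(names(empty), c("label", "source_model", "source_limit"))
  expect_error(build_constraint_table(nirs, schemes = 6, curves = curves),
               "no conversion curve")
})

test_that("strategy ordering: LEM LQ >= MKM LQ, gap widens as fractions drop", {
  for (set in list(cirt_fixture_constraints("nirs-16fx"),
                   cirt_fixture_constraints("cnao-16fx"))) {
    tab <- build_constraint_table(set, schemes = c(12, 8, 4),
                                  curves = curves)
    for (n in c(12, 8, 4))
      expect_true(all(tab[[sprintf("lem_lq_%dfx", n)]] >=
                        tab[[sprintf("mkm_lq_%dfx", n)]]))
    expect_true(all(tab$diff_12fx_pct < tab$diff_8fx_pct))
    expect_true(all(tab$diff_8fx_pct < tab$diff_4fx_pct))
  }
})
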