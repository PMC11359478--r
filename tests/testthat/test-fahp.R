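test_that("the fuzzification scale widens judgments by one step with saturation", {
  expect_equal(unclass(tfn_scale(1))[c("l", "m", "u")],
               list(l = 1, m = 1, u = 1))
  expect_equal(unclass(tfn_scale(3))[c("l", "m", "u")],
               list(l = 2, m = 3, u = 4))
  expect_equal(unclass(tfn_scale(9))[c("l", "m", "u")],
               list(l = 8, m = 9, u = 9))
  expect_equal(unclass(tfn_scale(2))[c("l", "m", "u")],
               list(l = 1, m = 2, u = 3))
  expect_equal(unclass(tfn_scale(1 / 7))[c("l", "m", "u")],
               list(l = 1 / 8, m = 1 / 7, u = 1 / 6))
  expect_error(tfn_scale(2.5), "unsupported intensity")
  expect_error(tfn_scale(10), "unsupported intensity")
})

test_that("fuzzified reciprocals are fuzzy reciprocals of fuzzified values", {
  for (x in c(2:9, 1)) {
    direct <- tfn_scale(1 / x)
    via <- tfn_reciprocal(tfn_scale(x))
    expect_equal(direct$l, via$l)
    expect_equal(direct$m, via$m)
    expect_equal(direct$u, via$u)
  }
})

test_that("TFN arithmetic keeps l <= m <= u and is exact on degenerate numbers", {
  a <- tfn(2, 3, 4)
  b <- tfn(1 / 2, 1, 2)
  p <- a * b
  expect_equal(c(p$l, p$m, p$u), c(1, 3, 8))
  q <- a / a
  expect_true(q$l <= q$m && q$m <= q$u)
  expect_equal(q$m, 1)
  r <- a^0.5
  expect_equal(c(r$l, r$m, r$u), sqrt(c(2, 3, 4)))
  expect_error(tfn(3, 2, 4), "l <= m <= u")
  expect_error(tfn(0, 1, 2), "positive")
})

test_that("Buckley weights on the fixture reproduce the published triples at 2 dp", {
  fw <- buckley_fuzzy_weights(fixture_matrix())
  got <- round_half_up(rbind(fw$l, fw$m, fw$u), 2)
  expect_equal(unname(got[, "warming"]), c(0.07, 0.10, 0.15))
  expect_equal(unname(got[, "flooding"]), c(0.49, 0.65, 0.86))
  expect_equal(unname(got[, "drought"]), c(0.13, 0.19, 0.27))
  expect_equal(unname(got[, "sea_level_rise"]), c(0.04, 0.06, 0.09))
})

test_that("fuzzy-weight modes equal the crisp geometric-mean weights exactly", {
  m <- fixture_matrix()
  expect_equal(buckley_fuzzy_weights(m)$m, as.numeric(geometric_mean_weights(m)),
               ignore_attr = TRUE, tolerance = 1e-12)
  # and on simulator-drawn snapped matrices
  mats <- simulate_matrices(workshop_sim_config(seed = 5, n_participants = 2))
  for (pm in mats) {
    for (mm in pm) {
      fw <- buckley_fuzzy_weights(mm)
      expect_equal(fw$m, as.numeric(geometric_mean_weights(mm)),
                   ignore_attr = TRUE, tolerance = 1e-12)
      expect_true(all(fw$l <= fw$m + 1e-12) && all(fw$m <= fw$u + 1e-12))
      expect_equal(sum(fw$m), 1, tolerance = 1e-9)
    }
  }
})

test_that("the crisp embedding collapses fuzzy weights to crisp weights", {
  m <- fixture_matrix()
  fw <- buckley_fuzzy_weights(m, scale = function(x) tfn(x, x, x))
  w <- as.numeric(geometric_mean_weights(m))
  expect_equal(fw$l, w, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(fw$m, w, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(fw$u, w, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("a degenerate single-criterion set gets fuzzy weight (1, 1, 1)", {
  fw <- buckley_fuzzy_weights(pcmatrix(matrix(1, 1, 1), "only"))
  expect_equal(c(fw$l, fw$m, fw$u), c(1, 1, 1), ignore_attr = TRUE)
})

test_that("centroid defuzzification and normalization match the published columns", {
  expect_equal(defuzzify(tfn(0.49, 0.65, 0.86)), 2 / 3, tolerance = 1e-12)
  expect_equal(round_half_up(defuzzify(tfn(0.07, 0.10, 0.15)), 2), 0.11)
  expect_equal(defuzzify(tfn(0.3, 0.3, 0.3)), 0.3)

  dfz <- c(0.1067, 0.6667, 0.1967, 0.0633)
  expect_equal(round_half_up(normalize_defuzzified(dfz), 2),
               c(0.10, 0.65, 0.19, 0.06))
  expect_equal(normalize_defuzzified(c(0.25, 0.75)), c(0.25, 0.75))
  expect_equal(normalize_defuzzified(3), 1)
  expect_error(normalize_defuzzified(c(1, 0)), "positive")
})

test_that("display rounding is half away from zero", {
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(round_half_up(0.1049, 2), 0.10)
})

test_that("fuzzy group aggregation preserves the mode/crisp correspondence", {
  mats <- simulate_matrices(workshop_sim_config(seed = 9, n_participants = 3))
  hz <- lapply(mats, `[[`, "hazard")
  fg <- aggregate_group_fuzzy(hz)
  cg <- aggregate_group(hz)
  # the mode matrix of the fuzzy group equals the crisp group matrix
  expect_equal(fg$m, unclass(cg), tolerance = 1e-12, ignore_attr = TRUE)
  fw <- buckley_fuzzy_weights(fg)
  expect_equal(fw$m, as.numeric(geometric_mean_weights(cg)),
               ignore_attr = TRUE, tolerance = 1e-12)
})
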