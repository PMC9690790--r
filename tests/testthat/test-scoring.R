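test_that("S-type ramp reproduces the published fertility scores", {
  expect_equal(round_half_up(score_s_type(18.21, 6, 40), 2), 0.36)
  expect_equal(round_half_up(score_s_type(127.81, 30, 200), 2), 0.58)
  expect_equal(round_half_up(score_s_type(12.1, 10, 20), 2), 0.21)
  expect_equal(score_s_type(6, 6, 40), 0)
  expect_equal(score_s_type(40, 6, 40), 1)
  expect_error(score_s_type(1, 5, 5), "L < H")
})

test_that("inverse-S ramp reproduces the published bio-accumulation scores", {
  expect_equal(round_half_up(score_inverse_s(46, 10, 100), 2), 0.60)
  expect_equal(score_inverse_s(8, 10, 100), 1)
  expect_equal(score_inverse_s(100, 10, 100), 0)
  expect_error(score_inverse_s(1, 100, 10), "L < H")
})

test_that("parabolic (midpoint) curve reproduces the published pH scores", {
  expect_equal(round_half_up(score_parabolic(7.27, 3, 5, 7, 9), 2), 0.87)
  expect_equal(round_half_up(score_parabolic(7.11, 3, 5, 7, 9), 2), 0.95)
  expect_equal(score_parabolic(6, 3, 5, 7, 9), 1)
  expect_equal(score_parabolic(9, 3, 5, 7, 9), 0)
  expect_equal(score_parabolic(3, 3, 5, 7, 9), 0)
  expect_error(score_parabolic(6, 3, 5, 9, 7), "L1 < L < H < H1")
})

test_that("all curves are bounded, monotone/unimodal, complementary and continuous", {
  x <- c(stats::runif(500, -1e3, 1e3), -1e9, 1e9, 0, 6, 40)
  s <- score_s_type(x, 6, 40)
  inv <- score_inverse_s(x, 6, 40)
  p <- score_parabolic(x, 3, 5, 7, 9)
  expect_true(all(s >= 0 & s <= 1))
  expect_true(all(inv >= 0 & inv <= 1))
  expect_true(all(p >= 0 & p <= 1))

  # complementarity on shared thresholds
  expect_equal(s + inv, rep(1, length(x)), tolerance = 1e-12)

  # monotonicity / unimodality on a fine grid
  g <- seq(-5, 50, by = 0.01)
  expect_true(all(diff(score_s_type(g, 6, 40)) >= -1e-12))
  expect_true(all(diff(score_inverse_s(g, 6, 40)) <= 1e-12))
  dp <- diff(score_parabolic(seq(2, 10, by = 0.01), 3, 5, 7, 9))
  turn <- which(dp < -1e-12)
  expect_true(all(dp[seq_len(min(turn) - 1)] >= -1e-12))  # rises then falls

  # continuity at every breakpoint, including the corrected rising limb at L1
  eps <- 1e-9
  for (b in c(6, 40)) {
    expect_equal(score_s_type(b - eps, 6, 40), score_s_type(b + eps, 6, 40),
                 tolerance = 1e-6)
  }
  for (b in c(3, 5, 7, 9)) {
    expect_equal(score_parabolic(b - eps, 3, 5, 7, 9),
                 score_parabolic(b + eps, 3, 5, 7, 9), tolerance = 1e-6)
  }
})

test_that("display rounding is half away from zero", {
  expect_equal(round_half_up(0.945, 2), 0.95)
  expect_equal(round_half_up(0.865, 2), 0.87)
  expect_equal(round_half_up(24.9122807, 1), 24.9)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(round_half_up(2.5), 3)
})

test_that("score_indicator applies transform, curve and compliance per definition", {
  reg <- default_registry()

  ahm <- score_indicator(reg$AHM, list(treatment = "RBC", value = 2.14,
                                       value_before = 2.85))
  expect_equal(round_half_up(ahm$score, 2), 0.33)
  expect_equal(round_half_up(ahm$transformed, 1), 24.9)

  cec <- score_indicator(reg$CEC, list(treatment = "HAP", value = 12.1))
  expect_equal(round_half_up(cec$score, 2), 0.21)

  an <- score_indicator(reg$`A-N`, list(treatment = "HAP", value = 25.66))
  expect_equal(an$score, 0)

  # negative reduction rate warns and scores 0
  expect_warning(
    worse <- score_indicator(reg$AHM, list(treatment = "x", value = 3.2,
                                           value_before = 2.85)),
    "increased")
  expect_equal(worse$score, 0)
  expect_lt(worse$transformed, 0)

  # group-I compliance flag rides along without changing the score
  thm <- score_indicator(reg$THM, list(treatment = "x", value = 1.2))
  expect_false(thm$compliant)
  expect_equal(thm$score, score_inverse_s(1.2, 0.6, 3.0))
  ok <- score_indicator(reg$amendment_hm, list(treatment = "x", value = 0))
  expect_true(ok$compliant)
  expect_equal(ok$score, 1)

  # missing companion values are hard errors
  expect_error(score_indicator(reg$AHM, list(value = 2)), "value_before")
  expect_error(score_indicator(reg$root_hm, list(value = 2)), "soil_total_hm")
  expect_error(score_indicator(reg$production, list(value = 2)),
               "reference_value")
})

test_that("the full pot-experiment score table reproduces at 2 decimals", {
  scored <- score_measurements(pot_experiment())
  expected <- pot_experiment_expected()
  merged <- merge(scored, expected, by = c("indicator", "treatment"),
                  suffixes = c("", "_expected"))
  expect_equal(nrow(merged), 34L)
  expect_equal(round_half_up(merged$score, 2), merged$score_expected)
})

test_that("unknown indicators are rejected when scoring a table", {
  bad <- data.frame(indicator = "conductivity", treatment = "x", value = 1)
  expect_error(score_measurements(bad), "unknown indicator")
})
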