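test_that("grid peaks follow the calibrated breakpoint formulas", {
  g <- build_grid(calibration_constants(-1, 0, 1))
  expect_equal(unname(g$peaks), c(-1.5, -1, 0, 0.5, 1, 1.5))
  expect_equal(names(g$peaks), FUZZY_LABELS)

  g2 <- build_grid(calibration_constants(-2, 0, 2))
  expect_equal(unname(g2$peaks), c(-3, -2, 0, 1, 2, 3))

  # hand evaluation of (3 x_n - x_o)/2, (x_o + x_p)/2, (x_o + 3 x_p)/2
  g3 <- build_grid(calibration_constants(-0.4, 0.1, 0.9))
  expect_equal(unname(g3$peaks), c(-0.65, -0.4, 0.1, 0.5, 0.9, 1.4))
  expect_true(all(diff(g3$peaks) > 0))
  expect_identical(g3$b1, g3$peaks[["High_N"]])
  expect_identical(g3$b2, g3$peaks[["High"]])
})

test_that("degenerate calibration orderings are rejected with a diagnostic", {
  expect_error(calibration_constants(0, 0, 1), "x_n < x_o")
  expect_error(calibration_constants(-1, 1, 0.5), "x_o < x_p")
  expect_error(calibration_constants(1, 0, -1), "x_n < x_o")
  expect_error(calibration_constants(NA, 0, 1), "finite")
})

test_that("fuzzification is exact at peaks, saturated outside, linear between", {
  g <- demo_grid()
  for (lab in FUZZY_LABELS) {
    w <- fuzzify(g$peaks[[lab]], g)
    expect_equal(unname(w[lab]), 1)
    expect_equal(sum(w), 1)
  }
  # saturation branches
  expect_equal(unname(fuzzify(g$b2 + 0.1, g)),
               c(0, 0, 0, 0, 0, 1))
  expect_equal(unname(fuzzify(g$b1 - 0.1, g)),
               c(1, 0, 0, 0, 0, 0))
  expect_equal(unname(fuzzify(-100, g)), c(1, 0, 0, 0, 0, 0))
  # midpoint of Off and Low peaks splits 50/50
  w <- fuzzify(0.25, g)
  expect_equal(unname(w[c("Off", "Low")]), c(0.5, 0.5))
  expect_equal(sum(w != 0), 2)
  # linear interpolation between adjacent peaks
  w <- fuzzify(0.6, g)  # between Low (0.5) and Med (1)
  expect_equal(unname(w["Low"]), 0.8)
  expect_equal(unname(w["Med"]), 0.2)
  expect_error(fuzzify(NaN, g), "finite")
  expect_error(fuzzify(Inf, g), "finite")
})

test_that("weights form a partition of unity with at most two active labels", {
  set.seed(42)
  g <- demo_grid()
  v <- runif(1e4, g$b1, g$b2)
  W <- membership_weights(v, g)
  expect_true(all(abs(rowSums(W) - 1) < 1e-9))
  expect_true(all(rowSums(W > 0) <= 2))
  expect_true(all(W >= 0 & W <= 1))
  # outside the support exactly one weight equals 1
  vout <- c(runif(500, g$b1 - 2, g$b1 - 1e-12), runif(500, g$b2 + 1e-12, g$b2 + 2))
  Wout <- membership_weights(vout, g)
  expect_true(all(rowSums(Wout == 1) == 1))
  expect_true(all(rowSums(Wout) == 1))
})

test_that("weights are continuous across every breakpoint", {
  g <- demo_grid()
  eps <- 1e-9
  for (p in c(unname(g$peaks))) {
    lo <- fuzzify(p - eps, g)
    at <- fuzzify(p, g)
    hi <- fuzzify(p + eps, g)
    expect_true(max(abs(at - lo)) < 1e-6)
    expect_true(max(abs(hi - at)) < 1e-6)
  }
})

test_that("calibrate pools segment means with the published sign filters", {
  rec <- labeled_recording(
    channel_1 = c(-1, -3, 0, 0, 2, 2),
    channel_2 = c(-1, -3, 0, 0, 2, 2),
    labels = c("wrist_extension", "wrist_extension", "rest", "rest",
               "finger_flexion", "wrist_flexion"))
  calib <- calibrate(rec)
  expect_equal(calib$x_n, -2)
  expect_equal(calib$x_o, 0)
  expect_equal(calib$x_p, 2)

  no_rest <- labeled_recording(c(-1, 2), c(-1, 2),
                               c("wrist_extension", "finger_flexion"))
  expect_error(calibrate(no_rest), "rest")
  no_neg <- labeled_recording(c(1, 0, 2), c(1, 0, 2),
                              c("wrist_extension", "rest", "finger_flexion"))
  expect_error(calibrate(no_neg), "negative")
})

test_that("calibrate recovers known plateau means on synthetic data", {
  model <- signal_model(rbind(rest = c(0.05, -0.05),
                              wrist_extension = c(-1.2, -1.4),
                              ulnar_deviation = c(0.6, 0.4),
                              finger_flexion = c(0.9, 1.1),
                              wrist_flexion = c(1.5, 1.3)),
                        ramp_s = 0, noise_sd = 0.02)
  script <- motion_script(TRUTH_LABELS, rep(0.02, 5), sample_rate = 1000)
  rec <- simulate_recording(script, model, seed = 7)
  calib <- calibrate(rec)
  # independent one-pass tally over the samples
  x_n <- x_o <- x_p <- 0; n_n <- n_o <- n_p <- 0L
  for (i in seq_along(rec$labels)) {
    for (v in c(rec$channel_1[i], rec$channel_2[i])) {
      if (rec$labels[i] == "rest") { x_o <- x_o + v; n_o <- n_o + 1L }
      if (rec$labels[i] == "wrist_extension" && v < 0) {
        x_n <- x_n + v; n_n <- n_n + 1L
      }
      if (rec$labels[i] %in% c("ulnar_deviation", "finger_flexion",
                               "wrist_flexion") && v > 0) {
        x_p <- x_p + v; n_p <- n_p + 1L
      }
    }
  }
  expect_equal(calib$x_n, x_n / n_n)
  expect_equal(calib$x_o, x_o / n_o)
  expect_equal(calib$x_p, x_p / n_p)
})
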