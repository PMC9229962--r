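test_that("canonical levels sit on each motion's dominant rule pair", {
  calib <- demo_calib()
  m <- canonical_signal_model(calib, noise_sd = 0)
  expect_equal(unname(m$levels["rest", ]), c(0, 0))
  expect_equal(unname(m$levels["ulnar_deviation", ]), c(0.5, 0))
  expect_equal(unname(m$levels["finger_flexion", 1]), 1)
  # saturated plateaus sit 5% of (x_p - x_o) beyond the boundaries
  expect_equal(unname(m$levels["wrist_extension", ]), c(-1.55, -1.55))
  expect_equal(unname(m$levels["wrist_flexion", ]), c(1.55, 1.55))
  expect_equal(unname(m$levels["finger_flexion", 2]), 1.55)
})

test_that("simulation honours durations, plateaus, ramps and the seed", {
  calib <- demo_calib()
  model <- canonical_signal_model(calib, noise_sd = 0, ramp_s = 0)
  script <- all_motion_sequences()[[1]]
  rec <- simulate_recording(script, model)
  expect_equal(length(rec$channel_1), 30000L)
  expect_equal(length(rec$labels), 30000L)
  # degenerate generator: piecewise-constant exactly at plateau levels
  for (seg in split(seq_along(rec$labels), cumsum(c(TRUE, diff(match(rec$labels, TRUTH_LABELS)) != 0)))) {
    lab <- rec$labels[seg[1]]
    expect_true(all(rec$channel_1[seg] == model$levels[lab, 1]))
    expect_true(all(rec$channel_2[seg] == model$levels[lab, 2]))
  }
  # ramps interpolate linearly over the first ramp_s of the incoming segment
  model_r <- canonical_signal_model(calib, noise_sd = 0, ramp_s = 0.2)
  rec_r <- simulate_recording(script, model_r)
  ramp <- rec_r$channel_1[5001:5200]   # rest -> first motion
  expect_true(all(abs(diff(ramp) - diff(ramp)[1]) < 1e-12))
  expect_equal(rec_r$channel_1[5200],
               unname(model_r$levels[rec_r$labels[5200], 1]))

  # seeded determinism
  noisy <- canonical_signal_model(calib)
  r1 <- simulate_recording(script, noisy, seed = 123)
  r2 <- simulate_recording(script, noisy, seed = 123)
  expect_identical(r1$channel_1, r2$channel_1)
  expect_identical(r1$channel_2, r2$channel_2)
  r3 <- simulate_recording(script, noisy, seed = 124)
  expect_false(identical(r1$channel_1, r3$channel_1))
})

test_that("segment sample means recover plateau levels under noise", {
  calib <- demo_calib()
  sd <- 0.1 * (calib$x_p - calib$x_o)
  model <- canonical_signal_model(calib, noise_sd = sd, ramp_s = 0)
  script <- motion_script(c("rest", "ulnar_deviation", "wrist_flexion"),
                          rep(5, 3))
  rec <- simulate_recording(script, model, seed = 21)
  n_seg <- 5000
  tol <- 3 * sd / sqrt(n_seg)
  for (lab in unique(script$labels)) {
    sel <- rec$labels == lab
    expect_lt(abs(mean(rec$channel_1[sel]) - model$levels[lab, 1]), tol)
    expect_lt(abs(mean(rec$channel_2[sel]) - model$levels[lab, 2]), tol)
  }
})

test_that("the sequence generator enumerates all 24 four-motion orderings", {
  scripts <- all_motion_sequences()
  expect_length(scripts, 24L)
  orders <- vapply(scripts, function(s) paste(s$labels[2:5], collapse = ">"),
                   character(1))
  expect_equal(anyDuplicated(orders), 0L)
  # brute-force enumeration of 4! permutations
  motions <- MOTION_STATES[1:4]
  brute <- character()
  for (a in motions) for (b in setdiff(motions, a))
    for (c in setdiff(motions, c(a, b))) {
      d <- setdiff(motions, c(a, b, c))
      brute <- c(brute, paste(c(a, b, c, d), collapse = ">"))
    }
  expect_setequal(unname(orders), brute)
  for (s in scripts) {
    expect_length(s$labels, 6L)
    expect_equal(sum(s$durations_s), 30)
    expect_equal(s$labels[c(1, 6)], c("rest", "rest"))
  }
})

test_that("the stress knob lowers only ulnar deviation following wrist extension", {
  calib <- demo_calib()
  model <- canonical_signal_model(calib, noise_sd = 0, ramp_s = 0,
                                  we_ud_factor = 0.2)
  hit <- motion_script(c("wrist_extension", "ulnar_deviation"), c(1, 1))
  rec <- simulate_recording(hit, model)
  ud <- rec$labels == "ulnar_deviation"
  expect_equal(unique(rec$channel_1[ud]), 0.2 * 0.5)
  expect_equal(unique(rec$channel_2[ud]), 0)
  # an ulnar deviation not preceded by wrist extension is untouched
  miss <- motion_script(c("rest", "ulnar_deviation"), c(1, 1))
  rec2 <- simulate_recording(miss, model)
  expect_equal(unique(rec2$channel_1[rec2$labels == "ulnar_deviation"]), 0.5)
})
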