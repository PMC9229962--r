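# Independent oracles used across the suite.

demo_calib <- function() calibration_constants(-1, 0, 1)
demo_grid <- function() build_grid(demo_calib())

# Literal transcription of the rule-evaluation + defuzzification algorithm:
# all 36 MIN terms are formed explicitly; each state's numerator sums
# m_i * w_i and each state's denominator sums the same m_i. Returns the five
# scores plus the five per-state denominators (which must coincide).
oracle_defuzz <- function(w1, w2, table) {
  num <- stats::setNames(numeric(5), MOTION_STATES)
  den <- stats::setNames(numeric(5), MOTION_STATES)
  for (r in seq_len(nrow(table))) {
    m <- min(w1[[table$label_1[r]]], w2[[table$label_2[r]]])
    for (s in MOTION_STATES) {
      num[s] <- num[s] + m * STRENGTH_CENTERS[[table[[s]][r]]]
      den[s] <- den[s] + m
    }
  }
  list(scores = num / den, den = den)
}

# random valid label-weight vector: fuzzify a uniform draw over a range
# extending past both saturation boundaries
random_weights <- function(n, grid) {
  span <- grid$b2 - grid$b1
  v <- stats::runif(n, grid$b1 - 0.3 * span, grid$b2 + 0.3 * span)
  membership_weights(v, grid)
}

# brute-force argmax with the same tie rule as decide()
oracle_decide <- function(scores, previous = NULL) {
  best <- -Inf; tied <- character()
  for (s in MOTION_STATES) {
    if (scores[[s]] > best) { best <- scores[[s]]; tied <- s }
    else if (scores[[s]] == best) tied <- c(tied, s)
  }
  if (length(tied) > 1 && !is.null(previous) && previous %in% tied) previous
  else tied[1]
}

# sequences whose script has ulnar deviation directly after wrist extension
we_ud_adjacent <- function(scripts) {
  names(scripts)[vapply(scripts, function(s) {
    l <- s$labels
    any(l[-1] == "ulnar_deviation" & l[-length(l)] == "wrist_extension")
  }, logical(1))]
}
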