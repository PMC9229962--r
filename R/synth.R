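#' A timed motion script
#'
#' An ordered list of (motion label, duration) segments describing a
#' recording protocol, e.g. 5 s of rest followed by four 5-s motions and a
#' final rest.
#'
#' @param labels Character vector of segment labels from [TRUTH_LABELS].
#' @param durations_s Positive numeric vector of segment durations in
#'   seconds.
#' @param sample_rate Sampling rate in Hz (default 1000).
#' @return An object of class `motion_script`.
#' @export
motion_script <- function(labels, durations_s, sample_rate = 1000) {
  if (length(labels) != length(durations_s) || length(labels) == 0L) {
    stop("labels and durations_s must be non-empty and of equal length",
         call. = FALSE)
  }
  bad <- setdiff(unique(labels), TRUTH_LABELS)
  if (length(bad)) stop("unknown motion label(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (any(!is.finite(durations_s)) || any(durations_s <= 0)) {
    stop("segment durations must be positive", call. = FALSE)
  }
  structure(list(labels = as.character(labels),
                 durations_s = as.numeric(durations_s),
                 sample_rate = sample_rate),
            class = "motion_script")
}

#' @export
print.motion_script <- function(x, ...) {
  cat(sprintf("Motion script (%g Hz, %.1f s total):\n", x$sample_rate,
              sum(x$durations_s)))
  cat(paste(sprintf("  %s (%.1f s)", x$labels, x$durations_s), collapse = "\n"),
      "\n")
  invisible(x)
}

#' Signal model: per-motion plateau levels, ramps, noise and drift
#'
#' Describes the synthetic signal: one plateau level per (motion, channel);
#' linear ramps of `ramp_s` seconds at segment changes; i.i.d. Gaussian
#' noise of standard deviation `noise_sd`; optional linear drift. The
#' `we_ud_factor` knob reproduces the documented hard case of the bracelet:
#' when ulnar deviation immediately follows wrist extension the change in
#' sensor contact area is small, so the module-1 plateau is pulled toward
#' the rest level by that factor (1 = no stress, the default).
#'
#' @param levels 5 x 2 numeric matrix of plateau levels in volts; rows named
#'   by [TRUTH_LABELS], columns are channels 1 and 2.
#' @param ramp_s Transition ramp duration in seconds (>= 0).
#' @param noise_sd Noise standard deviation in volts (>= 0).
#' @param drift_per_s Linear drift in volts/second (default 0).
#' @param we_ud_factor Fraction of the ulnar-deviation module-1 excursion
#'   retained when it directly follows wrist extension, in `[0, 1]`.
#' @return An object of class `signal_model`.
#' @export
signal_model <- function(levels, ramp_s = 0.2, noise_sd = 0,
                         drift_per_s = 0, we_ud_factor = 1) {
  levels <- as.matrix(levels)
  if (!all(TRUTH_LABELS %in% rownames(levels)) || ncol(levels) != 2L) {
    stop("levels must be a 5 x 2 matrix with rows named by TRUTH_LABELS",
         call. = FALSE)
  }
  if (noise_sd < 0 || ramp_s < 0) {
    stop("noise_sd and ramp_s must be non-negative", call. = FALSE)
  }
  structure(list(levels = levels[TRUTH_LABELS, , drop = FALSE],
                 ramp_s = ramp_s, noise_sd = noise_sd,
                 drift_per_s = drift_per_s, we_ud_factor = we_ud_factor),
            class = "signal_model")
}

#' Canonical signal model for a given calibration
#'
#' Places each motion's plateau at the label pair of its dominant
#' (High_motion) rule, emulating the per-motion signatures of the real
#' bracelet signal: rest at (x_o, x_o) so both channels read Off; wrist
#' extension below the lower saturation boundary on both channels (High_N,
#' High_N); ulnar deviation at the Low peak on module 1 with module 2 at
#' rest (Low, Off); finger flexion at the Med peak on module 1 with module
#' 2 above the upper boundary (Med, High); wrist flexion above the upper
#' boundary on both (High, High). Saturated plateaus sit `delta` = 5% of
#' `x_p - x_o` beyond the boundary.
#'
#' @param calib A [calibration_constants()] object.
#' @param noise_sd Noise standard deviation; defaults to
#'   `0.1 * (x_p - x_o)`.
#' @param ramp_s Transition ramp duration in seconds (default 0.2).
#' @param we_ud_factor Stress factor for the wrist-extension to
#'   ulnar-deviation transition (default 1 = no stress).
#' @return A [signal_model()].
#' @examples
#' m <- canonical_signal_model(calibration_constants(-1, 0, 1), noise_sd = 0)
#' m$levels
#' @export
canonical_signal_model <- function(calib,
                                   noise_sd = 0.1 * (calib$x_p - calib$x_o),
                                   ramp_s = 0.2, we_ud_factor = 1) {
  stopifnot(inherits(calib, "calibration_constants"))
  g <- build_grid(calib)
  delta <- 0.05 * (calib$x_p - calib$x_o)
  levels <- rbind(
    rest            = c(calib$x_o, calib$x_o),
    wrist_extension = c(g$b1 - delta, g$b1 - delta),
    ulnar_deviation = c((calib$x_o + calib$x_p) / 2, calib$x_o),
    finger_flexion  = c(calib$x_p, g$b2 + delta),
    wrist_flexion   = c(g$b2 + delta, g$b2 + delta))
  signal_model(levels, ramp_s = ramp_s, noise_sd = noise_sd,
               we_ud_factor = we_ud_factor)
}

#' Simulate a labeled two-channel recording from a script and model
#'
#' Each segment holds its motion's plateau level on both channels; at a
#' segment change the signal ramps linearly over the first `ramp_s`
#' seconds of the incoming segment (ramp samples carry the incoming
#' segment's label); i.i.d. Gaussian noise and optional linear drift are
#' added per sample. With `we_ud_factor < 1`, an ulnar-deviation segment
#' directly preceded by wrist extension has its module-1 plateau pulled
#' toward the rest level by that factor. Fully reproducible given `seed`.
#'
#' @param script A [motion_script()].
#' @param model A [signal_model()].
#' @param seed Integer seed for the noise generator, or `NULL` to use the
#'   current RNG state.
#' @return A [labeled_recording()].
#' @export
simulate_recording <- function(script, model, seed = NULL) {
  stopifnot(inherits(script, "motion_script"), inherits(model, "signal_model"))
  rate <- script$sample_rate
  ns <- round(script$durations_s * rate)
  n <- sum(ns)
  x_o <- model$levels["rest", 1L]

  seg_levels <- model$levels[script$labels, , drop = FALSE]
  if (model$we_ud_factor < 1) {
    for (s in seq_along(script$labels)[-1L]) {
      if (script$labels[s] == "ulnar_deviation" &&
          script$labels[s - 1L] == "wrist_extension") {
        seg_levels[s, 1L] <- x_o + model$we_ud_factor * (seg_levels[s, 1L] - x_o)
      }
    }
  }

  make_channel <- function(ch) {
    out <- numeric(n)
    pos <- 0L
    prev_level <- seg_levels[1L, ch]
    for (s in seq_along(ns)) {
      lev <- seg_levels[s, ch]
      seg <- rep(lev, ns[s])
      nr <- min(round(model$ramp_s * rate), ns[s])
      if (s > 1L && nr > 0L) {
        seg[seq_len(nr)] <- prev_level + (lev - prev_level) * seq_len(nr) / nr
      }
      out[pos + seq_len(ns[s])] <- seg
      pos <- pos + ns[s]
      prev_level <- lev
    }
    out
  }

  ch1 <- make_channel(1L)
  ch2 <- make_channel(2L)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (model$noise_sd > 0) {
    ch1 <- ch1 + stats::rnorm(n, sd = model$noise_sd)
    ch2 <- ch2 + stats::rnorm(n, sd = model$noise_sd)
  }
  if (model$drift_per_s != 0) {
    drift <- model$drift_per_s * (seq_len(n) - 1) / rate
    ch1 <- ch1 + drift
    ch2 <- ch2 + drift
  }
  labels <- rep(script$labels, times = ns)
  labeled_recording(ch1, ch2, labels, rate)
}

#' All 24 four-motion sequence scripts
#'
#' Enumerates the 24 permutations of (wrist extension, ulnar deviation,
#' finger flexion, wrist flexion) in lexicographic order of that fixed
#' motion order, each wrapped as 5 s rest + four 5-s motion segments +
#' 5 s rest (30 s total at `sample_rate`).
#'
#' @param segment_s Duration of each segment in seconds (default 5).
#' @param sample_rate Sampling rate in Hz (default 1000).
#' @return Named list of 24 [motion_script()] objects (`seq_01` ...
#'   `seq_24`).
#' @export
all_motion_sequences <- function(segment_s = 5, sample_rate = 1000) {
  motions <- MOTION_STATES[1:4]
  perms <- permutations_lex(4L)
  scripts <- lapply(seq_len(nrow(perms)), function(i) {
    motion_script(c("rest", motions[perms[i, ]], "rest"),
                  rep(segment_s, 6L), sample_rate)
  })
  names(scripts) <- sprintf("seq_%02d", seq_along(scripts))
  scripts
}

# lexicographic permutations of 1..n (n! rows)
permutations_lex <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_lex(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(first) {
    rest <- setdiff(seq_len(n), first)
    cbind(first, matrix(rest[sub], nrow(sub), n - 1L), deparse.level = 0)
  }))
}
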