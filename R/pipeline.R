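#' A two-channel recording with per-sample ground-truth labels
#'
#' Container for the bracelet signal: two voltage channels sampled at
#' `sample_rate` (nominally 1 kHz) and a per-sample motion label from
#' [TRUTH_LABELS].
#'
#' @param channel_1,channel_2 Numeric vectors, volts.
#' @param labels Character vector of per-sample labels, same length.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @return An object of class `labeled_recording`.
#' @export
labeled_recording <- function(channel_1, channel_2, labels,
                              sample_rate = 1000) {
  n <- length(channel_1)
  if (length(channel_2) != n || length(labels) != n) {
    stop("channels and labels must have equal length", call. = FALSE)
  }
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    stop("sample_rate must be positive", call. = FALSE)
  }
  bad <- setdiff(unique(labels), TRUTH_LABELS)
  if (length(bad)) {
    stop("unknown motion label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(channel_1 = as.numeric(channel_1),
                 channel_2 = as.numeric(channel_2),
                 labels = as.character(labels),
                 sample_rate = sample_rate),
            class = "labeled_recording")
}

#' @export
print.labeled_recording <- function(x, ...) {
  cat(sprintf("Labeled recording: %d samples at %g Hz (%.2f s)\n",
              length(x$channel_1), x$sample_rate,
              length(x$channel_1) / x$sample_rate))
  print(table(x$labels))
  invisible(x)
}

#' Reduce a recording to non-overlapping window means
#'
#' Consecutive blocks of `k` samples (default 5, the unit the classifier
#' operates on) are reduced to their per-channel means. Each window takes
#' the majority ground-truth label of its samples, ties resolved to the
#' label occurring earliest in the window. A trailing partial block is
#' dropped.
#'
#' @param recording A [labeled_recording()].
#' @param k Window length in samples (>= 1).
#' @return Data frame with columns `window_index`, `time_s` (window
#'   center), `module_1`, `module_2`, `label`.
#' @export
window_means <- function(recording, k = 5L) {
  stopifnot(inherits(recording, "labeled_recording"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("window length k must be >= 1", call. = FALSE)
  n <- length(recording$channel_1)
  nw <- n %/% k
  if (nw == 0L) stop("recording shorter than one window", call. = FALSE)
  keep <- seq_len(nw * k)
  colmean <- function(ch) colMeans(matrix(ch[keep], nrow = k))
  lab_codes <- match(recording$labels[keep], TRUTH_LABELS)
  lab_mat <- matrix(lab_codes, nrow = k)
  maj <- apply(lab_mat, 2, function(col) {
    counts <- tabulate(col, nbins = length(TRUTH_LABELS))
    cand <- which(counts == max(counts))
    if (length(cand) > 1L) cand <- cand[which.min(match(cand, col))]
    cand
  })
  data.frame(window_index = seq_len(nw),
             time_s = ((seq_len(nw) - 0.5) * k) / recording$sample_rate,
             module_1 = colmean(recording$channel_1),
             module_2 = colmean(recording$channel_2),
             label = TRUTH_LABELS[maj],
             stringsAsFactors = FALSE)
}

#' Classify a recording into a per-window decision stream
#'
#' Runs the full three-step fuzzy pipeline on every `k`-sample window:
#' fuzzify both channel means, evaluate the rule base, defuzzify into five
#' scores, and decide by argmax. The previous decision threads through for
#' tie-breaking, initialized to the off state.
#'
#' @param recording A [labeled_recording()].
#' @param calib A [calibration_constants()] object.
#' @param table A `rule_table` (default: [default_rule_table()]).
#' @param k Window length in samples (default 5).
#' @return Data frame with columns `window_index`, `time_s`, the five
#'   scores (`score_wrist_extension`, ..., `score_off_state`), `decision`
#'   (state name), `code` (integer 1-5), and `truth` (window majority
#'   label).
#' @export
classify_stream <- function(recording, calib, table = default_rule_table(),
                            k = 5L) {
  grid <- build_grid(calib)
  wm <- window_means(recording, k)
  W1 <- membership_weights(wm$module_1, grid)
  W2 <- membership_weights(wm$module_2, grid)
  scores <- defuzz_scores_matrix(W1, W2, table)
  dec <- decide_stream(scores, previous = "off_state")
  out <- data.frame(window_index = wm$window_index, time_s = wm$time_s,
                    stringsAsFactors = FALSE)
  for (s in MOTION_STATES) out[[paste0("score_", s)]] <- scores[, s]
  out$decision <- dec
  out$code <- unname(MOTION_CODES[dec])
  out$truth <- wm$label
  out
}

# windows within `margin_s` of a ground-truth label change (the change time
# is the midpoint between the adjacent windows)
transition_mask <- function(time_s, truth, margin_s) {
  excl <- rep(FALSE, length(truth))
  if (margin_s <= 0 || length(truth) < 2L) return(excl)
  ch <- which(truth[-1L] != truth[-length(truth)])
  for (i in ch) {
    t_ch <- (time_s[i] + time_s[i + 1L]) / 2
    excl <- excl | abs(time_s - t_ch) <= margin_s
  }
  excl
}

# per-sequence failure scan: TRUE if any contiguous run of misclassified
# windows within a single ground-truth plateau lasts >= min_s seconds
has_detection_failure <- function(time_s, truth, decision, min_s = 1) {
  if (length(truth) < 2L) return(FALSE)
  dt <- stats::median(diff(time_s))
  plateau <- cumsum(c(TRUE, truth[-1L] != truth[-length(truth)]))
  wrong <- decision != truth_to_state(truth)
  for (p in split(seq_along(truth), plateau)) {
    r <- rle(wrong[p])
    if (any(r$values & r$lengths * dt >= min_s)) return(TRUE)
  }
  FALSE
}

#' Score a decision stream against ground truth
#'
#' Computes the per-motion detection accuracy two ways: `rate_1` pools all
#' sequences; `rate_2` pools only sequences that are neither manually
#' excluded nor flagged as containing a detection failure (>= `failure_min_s`
#' seconds of contiguous misclassification within one motion plateau).
#' Windows within `transition_margin_s` of a ground-truth label change are
#' omitted from both rates, since scoring during a movement ramp is
#' ill-posed.
#'
#' @param predictions A decision-stream data frame from [classify_stream()]
#'   (with columns `time_s`, `decision`, `truth`), or a named list of such
#'   data frames, one per sequence.
#' @param truth Optional character vector of window truth labels overriding
#'   the `truth` column (single-sequence input only); must align with
#'   `predictions`.
#' @param transition_margin_s Seconds excluded on each side of a truth
#'   label change (default 0.25; 0 disables).
#' @param excluded_sequences Sequence names excluded from `rate_2` in
#'   addition to the automatically flagged failures.
#' @param failure_min_s Minimum contiguous misclassification duration that
#'   flags a sequence (default 1 s).
#' @return An `eval_report`: list with `per_motion` (data frame of
#'   `motion`, `rate_1`, `rate_2`, `n_1`, `n_2`), `overall_accuracy`,
#'   `overall_accuracy_2`, `failure_sequences`, `excluded_sequences` (the
#'   final rate-2 exclusion set) and `config`.
#' @export
accuracy_rates <- function(predictions, truth = NULL,
                           transition_margin_s = 0.25,
                           excluded_sequences = NULL,
                           failure_min_s = 1) {
  if (is.data.frame(predictions)) predictions <- list(seq_1 = predictions)
  if (is.null(names(predictions)) || any(names(predictions) == "")) {
    names(predictions) <- paste0("seq_", seq_along(predictions))
  }
  if (!is.null(truth)) {
    if (length(predictions) != 1L) {
      stop("a separate truth vector is only supported for a single sequence",
           call. = FALSE)
    }
    if (length(truth) != nrow(predictions[[1L]])) {
      stop("misaligned streams: ", nrow(predictions[[1L]]),
           " predictions vs ", length(truth), " truth labels", call. = FALSE)
    }
    predictions[[1L]]$truth <- truth
  }
  for (nm in names(predictions)) {
    p <- predictions[[nm]]
    need <- c("time_s", "decision", "truth")
    if (!all(need %in% names(p))) {
      stop("sequence '", nm, "' lacks required columns: ",
           paste(setdiff(need, names(p)), collapse = ", "), call. = FALSE)
    }
  }
  failure_sequences <- names(predictions)[vapply(predictions, function(p) {
    has_detection_failure(p$time_s, p$truth, p$decision, failure_min_s)
  }, logical(1))]
  excluded <- union(as.character(excluded_sequences), failure_sequences)

  scored <- do.call(rbind, lapply(names(predictions), function(nm) {
    p <- predictions[[nm]]
    keep <- !transition_mask(p$time_s, p$truth, transition_margin_s)
    data.frame(sequence = nm,
               state = truth_to_state(p$truth[keep]),
               correct = p$decision[keep] == truth_to_state(p$truth[keep]),
               stringsAsFactors = FALSE)
  }))
  rate <- function(d, m) {
    sel <- d$state == m
    if (!any(sel)) return(c(NA_real_, 0))
    c(100 * mean(d$correct[sel]), sum(sel))
  }
  scored2 <- scored[!(scored$sequence %in% excluded), , drop = FALSE]
  per <- do.call(rbind, lapply(MOTION_STATES, function(m) {
    r1 <- rate(scored, m); r2 <- rate(scored2, m)
    data.frame(motion = m, rate_1 = r1[1], rate_2 = r2[1],
               n_1 = as.integer(r1[2]), n_2 = as.integer(r2[2]),
               stringsAsFactors = FALSE)
  }))
  structure(list(
    per_motion = per,
    overall_accuracy = 100 * mean(scored$correct),
    overall_accuracy_2 = if (nrow(scored2)) 100 * mean(scored2$correct) else NA_real_,
    failure_sequences = failure_sequences,
    excluded_sequences = excluded,
    config = list(transition_margin_s = transition_margin_s,
                  failure_min_s = failure_min_s,
                  n_sequences = length(predictions))),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Motion detection accuracy (rate_1: all sequences; rate_2: failures excluded)\n")
  print(x$per_motion, row.names = FALSE, digits = 4)
  cat(sprintf("Overall accuracy: %.2f%% (rate_2 basis: %.2f%%)\n",
              x$overall_accuracy, x$overall_accuracy_2))
  if (length(x$failure_sequences)) {
    cat("Flagged failure sequences:", paste(x$failure_sequences, collapse = ", "), "\n")
  } else {
    cat("No flagged failure sequences\n")
  }
  invisible(x)
}

#' Write an evaluation report to JSON
#'
#' Serializes an `eval_report` including the scoring configuration for
#' provenance.
#'
#' @param report An `eval_report` from [accuracy_rates()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
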