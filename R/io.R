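# File formats: signal CSV (time_s, module_1_v, module_2_v[, label]),
# decisions CSV (window_index, time_s, five scores, decision code), and the
# segment-annotation JSON used to label a calibration recording.

#' Read / write the two-channel signal CSV
#'
#' The signal format has a header row and columns `time_s`, `module_1_v`,
#' `module_2_v` and optionally `label`. The label column is required for
#' calibration and evaluation input; when absent, samples are labeled
#' `rest` (classification does not use labels).
#'
#' @param path File path.
#' @param sample_rate Sampling rate in Hz; if `NULL`, inferred from the
#'   median spacing of `time_s`.
#' @return `read_signal_csv()` returns a [labeled_recording()];
#'   `write_signal_csv()` returns `path` invisibly.
#' @export
read_signal_csv <- function(path, sample_rate = NULL) {
  if (!file.exists(path)) stop("signal file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "module_1_v", "module_2_v")
  if (!all(need %in% names(d))) {
    stop("malformed signal CSV: missing column(s) ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  }
  if (is.null(sample_rate)) {
    dt <- stats::median(diff(d$time_s))
    if (!is.finite(dt) || dt <= 0) {
      stop("cannot infer sample rate from time_s column", call. = FALSE)
    }
    sample_rate <- 1 / dt
  }
  labels <- if ("label" %in% names(d)) d$label else rep("rest", nrow(d))
  labeled_recording(d$module_1_v, d$module_2_v, labels, sample_rate)
}

#' @rdname read_signal_csv
#' @param recording A [labeled_recording()].
#' @param digits Number of significant digits written (default 6).
#' @export
write_signal_csv <- function(recording, path, digits = 6) {
  stopifnot(inherits(recording, "labeled_recording"))
  n <- length(recording$channel_1)
  d <- data.frame(time_s = signif((seq_len(n) - 1) / recording$sample_rate, digits),
                  module_1_v = signif(recording$channel_1, digits),
                  module_2_v = signif(recording$channel_2, digits),
                  label = recording$labels)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a decision-stream CSV
#'
#' Columns: `window_index`, `time_s`, the five defuzzification scores, and
#' `decision` as the integer code (1 = off state, 2 = wrist extension,
#' 3 = ulnar deviation, 4 = finger flexion, 5 = wrist flexion).
#'
#' @param stream A decision stream from [classify_stream()].
#' @param path File path.
#' @return `read_decisions_csv()` returns a decision-stream data frame with
#'   the state names restored; `write_decisions_csv()` returns `path`
#'   invisibly.
#' @export
write_decisions_csv <- function(stream, path) {
  d <- data.frame(window_index = stream$window_index, time_s = stream$time_s)
  for (s in MOTION_STATES) d[[paste0("score_", s)]] <- stream[[paste0("score_", s)]]
  d$decision <- stream$code
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_decisions_csv
#' @export
read_decisions_csv <- function(path) {
  if (!file.exists(path)) stop("decision file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("window_index", "time_s", paste0("score_", MOTION_STATES), "decision")
  if (!all(need %in% names(d))) {
    stop("malformed decision CSV: missing column(s) ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  }
  d$code <- as.integer(d$decision)
  bad <- setdiff(unique(d$code), unname(MOTION_CODES))
  if (length(bad)) stop("unknown decision code(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  d$decision <- names(MOTION_CODES)[match(d$code, MOTION_CODES)]
  d
}

#' Read segment annotations and apply them to a recording
#'
#' Annotations are a JSON list of `{"label", "start_s", "end_s"}` records
#' with half-open intervals `[start_s, end_s)` in seconds from recording
#' start. Samples outside every segment keep their existing labels.
#'
#' @param path Path to the segments JSON.
#' @return `read_segments()` returns a data frame `label`, `start_s`,
#'   `end_s`.
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop("segments file not found: ", path, call. = FALSE)
  seg <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE),
                       stringsAsFactors = FALSE)
  need <- c("label", "start_s", "end_s")
  if (!all(need %in% names(seg))) {
    stop("malformed segments JSON: need fields label, start_s, end_s",
         call. = FALSE)
  }
  bad <- setdiff(unique(seg$label), TRUTH_LABELS)
  if (length(bad)) stop("unknown segment label(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (any(seg$end_s <= seg$start_s)) {
    stop("segment intervals must have end_s > start_s", call. = FALSE)
  }
  seg
}

#' @rdname read_segments
#' @param recording A [labeled_recording()].
#' @param segments A segments data frame from `read_segments()`.
#' @return `apply_segments()` returns the recording with labels overwritten
#'   inside the annotated intervals.
#' @export
apply_segments <- function(recording, segments) {
  stopifnot(inherits(recording, "labeled_recording"))
  t <- (seq_along(recording$channel_1) - 1) / recording$sample_rate
  labels <- recording$labels
  for (r in seq_len(nrow(segments))) {
    sel <- t >= segments$start_s[r] & t < segments$end_s[r]
    labels[sel] <- segments$label[r]
  }
  labeled_recording(recording$channel_1, recording$channel_2, labels,
                    recording$sample_rate)
}
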