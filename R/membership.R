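#' Calibration constants for the input membership function
#'
#' The three voltage anchors that position every triangle of the input
#' membership function: `x_n`, the mean of the negative samples recorded
#' during wrist extension; `x_o`, the mean during rest; and `x_p`, the mean
#' of the positive samples recorded during the other three motions
#' (ulnar deviation, finger flexion, wrist flexion).
#'
#' Only the strict ordering `x_n < x_o < x_p` is enforced, not the signs:
#' the geometry of the membership grid needs nothing more.
#'
#' @param x_n Numeric scalar, volts. Anchor of the negative (wrist-extension)
#'   region.
#' @param x_o Numeric scalar, volts. Anchor of the resting region.
#' @param x_p Numeric scalar, volts. Anchor of the positive-motion region.
#' @return An object of class `calibration_constants`.
#' @examples
#' calibration_constants(-1, 0, 1)
#' @export
calibration_constants <- function(x_n, x_o, x_p) {
  vals <- c(x_n = x_n, x_o = x_o, x_p = x_p)
  if (!all(is.finite(vals))) {
    stop("calibration constants must be finite numbers", call. = FALSE)
  }
  if (!(x_n < x_o)) {
    stop("invalid calibration: ordering x_n < x_o violated (x_n = ",
         format(x_n), ", x_o = ", format(x_o), ")", call. = FALSE)
  }
  if (!(x_o < x_p)) {
    stop("invalid calibration: ordering x_o < x_p violated (x_o = ",
         format(x_o), ", x_p = ", format(x_p), ")", call. = FALSE)
  }
  structure(list(x_n = x_n, x_o = x_o, x_p = x_p),
            class = "calibration_constants")
}

#' @export
print.calibration_constants <- function(x, ...) {
  cat(sprintf("Calibration constants (V): x_n = %g, x_o = %g, x_p = %g\n",
              x$x_n, x$x_o, x$x_p))
  invisible(x)
}

#' Read / write calibration constants as JSON
#'
#' The on-disk form is a flat JSON object `{"x_n": ..., "x_o": ..., "x_p": ...}`
#' in volts.
#'
#' @param path File path.
#' @return `read_calibration()` returns a `calibration_constants` object;
#'   `write_calibration()` returns `path` invisibly.
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("x_n", "x_o", "x_p")) {
    if (is.null(obj[[f]])) stop("calibration file missing field '", f, "'",
                                call. = FALSE)
  }
  calibration_constants(obj$x_n, obj$x_o, obj$x_p)
}

#' @rdname read_calibration
#' @param calib A `calibration_constants` object.
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "calibration_constants"))
  jsonlite::write_json(list(x_n = calib$x_n, x_o = calib$x_o, x_p = calib$x_p),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Build the triangular membership grid from calibration constants
#'
#' Positions the six triangle peaks on the voltage axis:
#' `(3 x_n - x_o)/2`, `x_n`, `x_o`, `(x_o + x_p)/2`, `x_p`,
#' `(x_o + 3 x_p)/2`, associated in order with the labels High_N, Low_N,
#' Off, Low, Med and High. Adjacent triangles overlap by 50%, so interior
#' weights form a partition of unity. Beyond the outer peaks (`b1`, `b2`)
#' exactly one label saturates at weight 1.
#'
#' @param calib A [calibration_constants()] object.
#' @return An object of class `membership_grid` with fields `peaks` (named
#'   numeric, length 6), `b1` and `b2` (saturation boundaries).
#' @examples
#' build_grid(calibration_constants(-1, 0, 1))$peaks
#' @export
build_grid <- function(calib) {
  if (!inherits(calib, "calibration_constants")) {
    calib <- calibration_constants(calib$x_n, calib$x_o, calib$x_p)
  }
  peaks <- c((3 * calib$x_n - calib$x_o) / 2,
             calib$x_n,
             calib$x_o,
             (calib$x_o + calib$x_p) / 2,
             calib$x_p,
             (calib$x_o + 3 * calib$x_p) / 2)
  names(peaks) <- FUZZY_LABELS
  structure(list(peaks = peaks, b1 = peaks[[1]], b2 = peaks[[6]],
                 calib = calib),
            class = "membership_grid")
}

#' @export
print.membership_grid <- function(x, ...) {
  cat("Membership grid peaks (V):\n")
  print(x$peaks)
  invisible(x)
}

# Vectorized fuzzification: n values -> n x 6 weight matrix.
# Branch boundaries are upper-inclusive / lower-exclusive, matching the
# half-open branches of the fuzzification pseudocode; at interior boundaries
# the interpolated weights are continuous so inclusivity is only observable
# at the saturation edges.
membership_weights <- function(v, grid) {
  stopifnot(inherits(grid, "membership_grid"))
  if (!all(is.finite(v))) stop("input voltage must be finite", call. = FALSE)
  p <- unname(grid$peaks)
  n <- length(v)
  W <- matrix(0, nrow = n, ncol = 6, dimnames = list(NULL, FUZZY_LABELS))
  idx <- findInterval(v, p, left.open = TRUE)  # v in (p[i], p[i+1]] -> i
  W[idx == 0L, 1L] <- 1            # at or below the lower boundary: High_N
  W[idx == 6L, 6L] <- 1            # above the upper boundary: High
  interior <- which(idx >= 1L & idx <= 5L)
  if (length(interior)) {
    i <- idx[interior]
    lo <- p[i]; hi <- p[i + 1L]
    wlo <- (hi - v[interior]) / (hi - lo)
    W[cbind(interior, i)] <- wlo
    W[cbind(interior, i + 1L)] <- 1 - wlo
  }
  W
}

#' Fuzzify a voltage value into six weighted labels
#'
#' Converts one crisp voltage (typically a 5-sample window mean) into
#' weights on the six fuzzy labels. At most two adjacent labels receive
#' nonzero weight; inside the grid support the weights sum to 1; outside,
#' the outermost label saturates at 1.
#'
#' @param v Finite numeric scalar, volts.
#' @param grid A [build_grid()] membership grid.
#' @return Named numeric vector of six weights in `[0, 1]`, in
#'   [FUZZY_LABELS] order.
#' @examples
#' g <- build_grid(calibration_constants(-1, 0, 1))
#' fuzzify(0, g)      # at the Off peak
#' fuzzify(0.25, g)   # Off/Low split 50/50
#' @export
fuzzify <- function(v, grid) {
  if (length(v) != 1L) stop("fuzzify() takes a single value; see membership_weights()",
                            call. = FALSE)
  drop(membership_weights(v, grid))
}

#' Estimate calibration constants from a labeled recording
#'
#' Implements the calibration protocol: `x_n` is the mean of the
#' negative-valued samples within wrist-extension segments, `x_p` the mean
#' of the positive-valued samples within ulnar-deviation, finger-flexion and
#' wrist-flexion segments, and `x_o` the mean of all samples within rest
#' segments. Samples are pooled across both channels.
#'
#' @param recording A [labeled_recording()].
#' @return A [calibration_constants()] object.
#' @export
calibrate <- function(recording) {
  stopifnot(inherits(recording, "labeled_recording"))
  lab <- recording$labels
  pooled <- function(sel) c(recording$channel_1[sel], recording$channel_2[sel])
  rest_vals <- pooled(lab == "rest")
  if (!length(rest_vals)) {
    stop("calibration recording has no rest-labeled samples", call. = FALSE)
  }
  we_vals <- pooled(lab == "wrist_extension")
  we_neg <- we_vals[we_vals < 0]
  if (!length(we_neg)) {
    stop("calibration recording has no negative samples during wrist extension",
         call. = FALSE)
  }
  pos_lab <- c("ulnar_deviation", "finger_flexion", "wrist_flexion")
  pos_vals <- pooled(lab %in% pos_lab)
  pos_pos <- pos_vals[pos_vals > 0]
  if (!length(pos_pos)) {
    stop("calibration recording has no positive samples during ",
         "ulnar deviation / finger flexion / wrist flexion", call. = FALSE)
  }
  calibration_constants(mean(we_neg), mean(rest_vals), mean(pos_pos))
}
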