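#' Activate the rules matched by a pair of label-weight vectors
#'
#' A rule fires only when both of its antecedent labels carry nonzero
#' weight; its firing strength `m` is the minimum of the two weights.
#' Because fuzzification yields at most two nonzero labels per channel,
#' between 1 and 4 rules activate.
#'
#' @param w1,w2 Named numeric weight vectors of length 6 (module 1 and
#'   module 2), as returned by [fuzzify()].
#' @param table A `rule_table`.
#' @return A data frame with one row per activated rule: `label_1`,
#'   `label_2`, `m`, and the five center values of that rule's consequents
#'   (columns named as [MOTION_STATES]).
#' @export
activate <- function(w1, w2, table) {
  w1 <- check_weights(w1); w2 <- check_weights(w2)
  table <- validate_rule_table(table)
  i <- which(w1 > 0); j <- which(w2 > 0)
  pairs <- expand.grid(i = i, j = j, KEEP.OUT.ATTRS = FALSE)
  key <- paste(FUZZY_LABELS[pairs$i], FUZZY_LABELS[pairs$j])
  rows <- match(key, paste(table$label_1, table$label_2))
  out <- data.frame(label_1 = FUZZY_LABELS[pairs$i],
                    label_2 = FUZZY_LABELS[pairs$j],
                    m = pmin(w1[pairs$i], w2[pairs$j]),
                    stringsAsFactors = FALSE)
  for (s in MOTION_STATES) out[[s]] <- unname(STRENGTH_CENTERS[table[[s]][rows]])
  rownames(out) <- NULL
  out
}

check_weights <- function(w) {
  if (!is.numeric(w) || length(w) != 6L) {
    stop("label weights must be a numeric vector of length 6", call. = FALSE)
  }
  if (!is.null(names(w)) && !identical(names(w), FUZZY_LABELS)) {
    w <- w[FUZZY_LABELS]
  }
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("label weights must be finite and non-negative", call. = FALSE)
  }
  if (all(w == 0)) stop("all-zero label weights are invalid", call. = FALSE)
  unname(w)
}

#' Weighted-centroid defuzzification of activated rules
#'
#' For each output state, the score is the firing-strength-weighted average
#' of the activated rules' center values:
#' `score = sum(m_i * w_i) / sum(m_i)`. The denominator is the same for all
#' five states, so each score is a convex combination of center values and
#' lies in `[0.5, 2]`.
#'
#' @param activations Non-empty data frame from [activate()].
#' @return Named numeric vector of five scores in [MOTION_STATES] order.
#' @export
defuzzify <- function(activations) {
  if (is.null(activations) || nrow(activations) == 0L) {
    stop("empty activation set: upstream label weights were all zero",
         call. = FALSE)
  }
  den <- sum(activations$m)
  vapply(MOTION_STATES,
         function(s) sum(activations$m * activations[[s]]) / den,
         numeric(1))
}

#' Decide the motion from defuzzification scores
#'
#' Returns the state with the strictly largest score. On an exact tie the
#' previous decision wins if it is among the tied states (temporal
#' continuity); otherwise the tied state earliest in [MOTION_STATES] order.
#'
#' @param scores Named numeric vector of five scores.
#' @param previous Previous decision (a state name) or `NULL`.
#' @return One of [MOTION_STATES].
#' @export
decide <- function(scores, previous = NULL) {
  scores <- scores[MOTION_STATES]
  tied <- MOTION_STATES[scores == max(scores)]
  if (length(tied) > 1L && !is.null(previous) && previous %in% tied) {
    return(previous)
  }
  tied[1L]
}

# Vectorized rule evaluation + defuzzification over n window pairs.
# W1, W2: n x 6 weight matrices. Returns n x 5 score matrix.
defuzz_scores_matrix <- function(W1, W2, table) {
  arr <- rule_center_array(table)
  n <- nrow(W1)
  num <- matrix(0, n, 5, dimnames = list(NULL, MOTION_STATES))
  den <- numeric(n)
  for (i in 1:6) {
    w1i <- W1[, i]
    if (all(w1i == 0)) next
    for (j in 1:6) {
      m <- pmin(w1i, W2[, j])
      nz <- m > 0
      if (!any(nz)) next
      den <- den + m
      num <- num + m * rep(arr[i, j, ], each = n)
    }
  }
  num / den
}

# Sequential decisions over a score matrix, threading the previous decision
# through exact ties; `previous` initializes the chain.
decide_stream <- function(scores, previous = "off_state") {
  n <- nrow(scores)
  first <- max.col(scores, ties.method = "first")
  rowmax <- scores[cbind(seq_len(n), first)]
  ntied <- rowSums(scores == rowmax)
  dec <- MOTION_STATES[first]
  for (r in which(ntied > 1L)) {
    prev <- if (r == 1L) previous else dec[r - 1L]
    tied <- MOTION_STATES[scores[r, ] == rowmax[r]]
    dec[r] <- if (!is.null(prev) && prev %in% tied) prev else tied[1L]
  }
  dec
}
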