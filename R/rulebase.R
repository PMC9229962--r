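# The 18 published rule rows (rules 1-3, 7-9, 13-15, 21-23, 28-30, 34-36).
# Strength tokens are Low / Med / High with center values 0.5 / 1 / 2.
published_rules <- function() {
  tab <- c(
    # label_1, label_2, WE,   UD,   FF,   WF,   off
    "High_N", "High_N", "High", "Low", "Low", "Low", "Low",
    "High_N", "Low_N",  "Med",  "Low", "Low", "Low", "Low",
    "High_N", "Off",    "Low",  "Low", "Low", "Low", "Low",
    "Low_N",  "High_N", "Med",  "Low", "Low", "Low", "Low",
    "Low_N",  "Low_N",  "Med",  "Low", "Low", "Low", "Med",
    "Low_N",  "Off",    "Low",  "Low", "Low", "Low", "Med",
    "Off",    "High_N", "Low",  "Low", "Low", "Low", "Low",
    "Off",    "Low_N",  "Low",  "Low", "Low", "Low", "Med",
    "Off",    "Off",    "Low",  "Low", "Low", "Low", "High",
    "Low",    "Off",    "Low",  "High", "Low", "Low", "Med",
    "Low",    "Low",    "Low",  "Med",  "Low", "Low", "Med",
    "Low",    "Med",    "Low",  "Low",  "Low", "Low", "Low",
    "Med",    "Low",    "Low",  "Med",  "Low", "Low", "Low",
    "Med",    "Med",    "Low",  "Low",  "Med", "Low", "Low",
    "Med",    "High",   "Low",  "Low",  "High", "Low", "Low",
    "High",   "Low",    "Low",  "Low",  "Low", "Low", "Low",
    "High",   "Med",    "Low",  "Low",  "Med", "Med", "Low",
    "High",   "High",   "Low",  "Low",  "Low", "High", "Low")
  m <- matrix(tab, ncol = 7, byrow = TRUE)
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- c("label_1", "label_2", MOTION_STATES)
  df
}

#' The default 36-entry fuzzy rule table
#'
#' Returns the complete rule base mapping every ordered pair of fuzzy labels
#' (module 1, module 2) to the strength (`Low`, `Med`, `High`) of each of
#' the five output states. 18 of the 36 rows are published; the remaining 18
#' are a documented completion — `Low` for every output, except that the
#' unpublished (Off, Low) entry mirrors the published (Low, Off) rule.
#' Completed rows are flagged `inferred = TRUE` so they are never mistaken
#' for published rules; any completion can be replaced via
#' [load_rule_table()].
#'
#' @return A `rule_table` data frame with 36 rows and columns `label_1`,
#'   `label_2`, one strength column per state in [MOTION_STATES] order, and
#'   `inferred`.
#' @examples
#' tab <- default_rule_table()
#' subset(tab, label_1 == "Off" & label_2 == "Off")
#' @export
default_rule_table <- function() {
  grid <- expand.grid(label_2 = FUZZY_LABELS, label_1 = FUZZY_LABELS,
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)[, c("label_1", "label_2")]
  tab <- data.frame(grid, wrist_extension = "Low", ulnar_deviation = "Low",
                    finger_flexion = "Low", wrist_flexion = "Low",
                    off_state = "Low", inferred = TRUE,
                    stringsAsFactors = FALSE)
  pub <- published_rules()
  key <- function(d) paste(d$label_1, d$label_2)
  i <- match(key(pub), key(tab))
  tab[i, MOTION_STATES] <- pub[, MOTION_STATES]
  tab$inferred[i] <- FALSE
  # symmetry completion: (Off, Low) mirrors the published (Low, Off) rule
  mirror <- match("Off Low", key(tab))
  src <- match("Low Off", key(tab))
  tab[mirror, MOTION_STATES] <- tab[src, MOTION_STATES]
  validate_rule_table(tab)
}

#' Validate a fuzzy rule table
#'
#' Checks that a table holds exactly one rule for each of the 36 ordered
#' label pairs, with a legal strength token for all five output states.
#'
#' @param tab A data frame with columns `label_1`, `label_2`, the five state
#'   columns and optionally `inferred`.
#' @return The table, ordered module-1-major, with class `rule_table`.
#' @export
validate_rule_table <- function(tab) {
  need <- c("label_1", "label_2", MOTION_STATES)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("rule table is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad_lab <- setdiff(unique(c(tab$label_1, tab$label_2)), FUZZY_LABELS)
  if (length(bad_lab)) {
    stop("rule table contains unknown fuzzy labels: ",
         paste(bad_lab, collapse = ", "), call. = FALSE)
  }
  for (s in MOTION_STATES) {
    bad <- setdiff(unique(tab[[s]]), names(STRENGTH_CENTERS))
    if (length(bad)) {
      stop("illegal strength token(s) in column '", s, "': ",
           paste(bad, collapse = ", "), " (expected Low/Med/High)",
           call. = FALSE)
    }
  }
  key <- paste(tab$label_1, tab$label_2)
  dup <- unique(key[duplicated(key)])
  if (length(dup)) {
    stop("duplicate rule(s) for label pair(s): ", paste(dup, collapse = "; "),
         call. = FALSE)
  }
  all_pairs <- as.vector(outer(FUZZY_LABELS, FUZZY_LABELS, paste))
  absent <- setdiff(all_pairs, key)
  if (length(absent)) {
    stop("incomplete rule table; missing pair(s): ",
         paste(absent, collapse = "; "), call. = FALSE)
  }
  if (is.null(tab$inferred)) tab$inferred <- FALSE
  tab$inferred <- as.logical(tab$inferred)
  ord <- order(match(tab$label_1, FUZZY_LABELS), match(tab$label_2, FUZZY_LABELS))
  tab <- tab[ord, c("label_1", "label_2", MOTION_STATES, "inferred")]
  rownames(tab) <- NULL
  class(tab) <- c("rule_table", "data.frame")
  tab
}

#' Load a fuzzy rule table from JSON or CSV
#'
#' The file is a list (JSON) or table (CSV) of 36 records with fields
#' `label_1`, `label_2`, one strength token (`Low`/`Med`/`High`) per output
#' state, and an optional `inferred` flag. Tables with missing or duplicate
#' pairs, unknown labels or illegal strength tokens are rejected with a
#' diagnostic naming the offending entries.
#'
#' @param path Path to a `.json` or `.csv` file, or the string `"default"`
#'   for the shipped default table.
#' @return A validated `rule_table`.
#' @export
load_rule_table <- function(path) {
  if (identical(path, "default")) return(default_rule_table())
  if (!file.exists(path)) stop("rule-table file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  tab <- if (ext == "json") {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE),
                  stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  validate_rule_table(tab)
}

#' Write a fuzzy rule table to JSON or CSV
#'
#' @param tab A `rule_table`.
#' @param path Destination `.json` or `.csv` path.
#' @return `path`, invisibly.
#' @export
write_rule_table <- function(tab, path) {
  tab <- validate_rule_table(tab)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(tab, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @export
print.rule_table <- function(x, ...) {
  cat("Fuzzy rule table: 36 rules (", sum(!x$inferred), " published, ",
      sum(x$inferred), " inferred)\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}

# 6 x 6 x 5 array of center values, indexed [label_1, label_2, state]
rule_center_array <- function(tab) {
  tab <- validate_rule_table(tab)
  arr <- array(NA_real_, dim = c(6, 6, 5),
               dimnames = list(FUZZY_LABELS, FUZZY_LABELS, MOTION_STATES))
  i <- match(tab$label_1, FUZZY_LABELS)
  j <- match(tab$label_2, FUZZY_LABELS)
  for (s in seq_along(MOTION_STATES)) {
    arr[cbind(i, j, s)] <- STRENGTH_CENTERS[tab[[MOTION_STATES[s]]]]
  }
  arr
}
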