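#' Confidence-rating count table for a detection experiment
#'
#' Builds the 2 x 4 table of response counts used throughout the package:
#' one row per condition ("present", "absent") and category, with the four
#' ordered categories running 1 = definitely no (normal) to 4 = definitely
#' yes (abnormal). Conditions are always keyed by name, never by row order.
#'
#' @param present Integer vector of 4 counts for target-present trials,
#'   ordered definitely-no to definitely-yes.
#' @param absent Integer vector of 4 counts for target-absent trials, same
#'   ordering.
#' @param labels Optional character vector of 4 category names.
#' @return A tibble of class `pd_counts` with columns `condition`,
#'   `category`, `label`, `count` (8 rows).
#' @examples
#' detection_counts(present = c(3, 3, 12, 33), absent = c(33, 9, 14, 2))
#' @export
detection_counts <- function(present, absent,
                             labels = c(
                               "definitely no", "probably no",
                               "probably yes", "definitely yes"
                             )) {
  check_counts_vec <- function(x, what) {
    if (length(x) != 4L) stop(what, " must have 4 categories", call. = FALSE)
    if (any(!is.finite(x)) || any(x < 0) || any(x != round(x))) {
      stop(what, " counts must be non-negative integers", call. = FALSE)
    }
    as.integer(round(x))
  }
  present <- check_counts_vec(present, "present")
  absent <- check_counts_vec(absent, "absent")
  stopifnot(length(labels) == 4L)
  out <- tibble::tibble(
    condition = rep(c("present", "absent"), each = 4L),
    category = rep(1:4, 2L),
    label = rep(as.character(labels), 2L),
    count = c(present, absent)
  )
  class(out) <- c("pd_counts", class(out))
  out
}

# internal: keyed extraction to list(present=, absent=) of length-4 vectors
counts_vectors <- function(counts) {
  if (!is.data.frame(counts)) stop("counts must be a data frame", call. = FALSE)
  need <- c("condition", "category", "count")
  if (!all(need %in% names(counts))) {
    stop("counts needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  pull_cond <- function(cond) {
    rows <- counts[counts$condition == cond, ]
    if (nrow(rows) != 4L || !setequal(rows$category, 1:4)) {
      stop("condition '", cond, "' must have exactly one row per category 1..4",
        call. = FALSE
      )
    }
    as.numeric(rows$count[order(rows$category)])
  }
  list(present = pull_cond("present"), absent = pull_cond("absent"))
}

#' Read a detection count table from CSV
#'
#' The schema has columns `condition` (`present` or `absent`), `category`
#' (1 to 4) and `count`, with exactly 8 rows. Row order is irrelevant; rows
#' are keyed by condition and category.
#'
#' @param path Path to a CSV file.
#' @return A `pd_counts` tibble.
#' @examples
#' path <- system.file("extdata", "radiology_counts.csv", package = "pdetect")
#' read_counts(path)
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) {
    stop("counts file '", path, "' does not exist", call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "category", "count")
  if (!all(need %in% names(raw))) {
    stop("'", path, "': expected columns ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(raw) != 8L) {
    stop("'", path, "': expected 8 rows, found ", nrow(raw), call. = FALSE)
  }
  bad <- !raw$condition %in% c("present", "absent")
  if (any(bad)) {
    stop("'", path, "': unknown condition in row ", which(bad)[1], call. = FALSE)
  }
  if (any(raw$count < 0) || any(raw$count != round(raw$count))) {
    stop("'", path, "': counts must be non-negative integers (row ",
      which(raw$count < 0 | raw$count != round(raw$count))[1], ")",
      call. = FALSE
    )
  }
  key <- paste(raw$condition, raw$category)
  if (anyDuplicated(key)) {
    stop("'", path, "': duplicate condition/category row ",
      which(duplicated(key))[1], call. = FALSE
    )
  }
  v <- counts_vectors(raw)
  detection_counts(present = v$present, absent = v$absent)
}

#' Write a detection count table to CSV
#'
#' @param counts A `pd_counts` tibble (or compatible data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  v <- counts_vectors(counts)
  out <- detection_counts(v$present, v$absent)
  utils::write.csv(out[, c("condition", "category", "count")], path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Worked radiology example: one radiologist rating 109 CT scans
#'
#' The Hanley-McNeil frequencies for a single radiologist classifying CT
#' scans on a four-point scale from "definitely normal" to "definitely
#' abnormal". There were 51 truly abnormal scans (target-present) with
#' counts (3, 3, 12, 33) and 58 normal scans (target-absent) with counts
#' (33, 9, 14, 2).
#'
#' @return A `pd_counts` tibble.
#' @examples
#' fit_mle(radiology_scans())
#' @export
radiology_scans <- function() {
  detection_counts(
    present = c(3, 3, 12, 33),
    absent = c(33, 9, 14, 2),
    labels = c(
      "definitely normal", "probably normal",
      "probably abnormal", "definitely abnormal"
    )
  )
}
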