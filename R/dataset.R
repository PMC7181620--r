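# Trial-level behavioral datasets: container, validation, CSV round-trip.

.dataset_columns <- c(
  "subject", "experiment", "config", "target_x", "target_y",
  "true_category", "response_category", "confidence"
)

#' Construct a behavioral dataset for one subject
#'
#' A `conf_dataset` is a data frame of trials (one subject, one experiment)
#' with columns `config` (1--4), `target_x`, `target_y` (degrees),
#' `true_category` (1--3; required in experiment 3, `NA` otherwise),
#' `response_category` (1--3) and `confidence` (1--4), plus an optional
#' `block` index. Invariants are validated on construction.
#'
#' @param trials data frame of trials.
#' @param subject subject identifier.
#' @param experiment experiment id, 1, 2 or 3.
#'
#' @return An object of classes `conf_dataset` and `data.frame`.
#' @export
conf_dataset <- function(trials, subject, experiment) {
  experiment <- as.integer(experiment)
  trials <- as.data.frame(trials)
  need <- c("config", "target_x", "target_y", "response_category", "confidence")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols) > 0L) {
    stop_triconf("trials are missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"true_category" %in% names(trials)) trials$true_category <- NA_integer_
  trials$subject <- rep(as.character(subject), length.out = nrow(trials))
  trials$experiment <- rep(experiment, length.out = nrow(trials))
  errs <- validate_trials(trials, experiment)
  if (length(errs) > 0L) {
    stop_triconf("invalid trials:\n", paste0("  - ", errs, collapse = "\n"))
  }
  first <- intersect(.dataset_columns, names(trials))
  trials <- trials[, c(first, setdiff(names(trials), first))]
  class(trials) <- c("conf_dataset", "data.frame")
  trials
}

# Itemized validation; returns a character vector of problems (empty if ok).
validate_trials <- function(trials, experiment) {
  errs <- character()
  row_ids <- function(bad) paste(which(bad), collapse = ", ")
  if (nrow(trials) == 0L) {
    return("dataset contains no trials")
  }
  bad <- !trials$config %in% 1:4
  if (any(bad)) {
    errs <- c(errs, sprintf("unknown config id in rows %s", row_ids(bad)))
  }
  bad <- !is.finite(trials$target_x) | !is.finite(trials$target_y)
  if (any(bad)) {
    errs <- c(errs, sprintf("non-finite target position in rows %s", row_ids(bad)))
  }
  bad <- !trials$response_category %in% 1:3
  if (any(bad)) {
    errs <- c(errs, sprintf("response_category outside 1-3 in rows %s", row_ids(bad)))
  }
  bad <- !trials$confidence %in% 1:4
  if (any(bad)) {
    errs <- c(errs, sprintf("confidence rating outside 1-4 in rows %s", row_ids(bad)))
  }
  if (experiment == 3L) {
    bad <- !trials$true_category %in% 1:3
    if (any(bad)) {
      errs <- c(errs, sprintf(
        "experiment 3 requires true_category in 1-3; missing/invalid in rows %s",
        row_ids(bad)
      ))
    }
  } else {
    bad <- !is.na(trials$true_category)
    if (any(bad)) {
      errs <- c(errs, sprintf(
        "true_category must be absent outside experiment 3; present in rows %s",
        row_ids(bad)
      ))
    }
  }
  errs
}

#' @export
print.conf_dataset <- function(x, ...) {
  cat(sprintf(
    "<conf_dataset> subject %s, experiment %d: %d trials over configs {%s}\n",
    x$subject[1], x$experiment[1], nrow(x),
    paste(sort(unique(x$config)), collapse = ", ")
  ))
  NextMethod()
}

#' Write a dataset to CSV
#'
#' Writes the standard trial schema (`subject, experiment, config, target_x,
#' target_y, true_category, response_category, confidence`, plus `block` if
#' present). [read_dataset()] inverts it field-for-field.
#'
#' @param dataset a [conf_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "conf_dataset"))
  cols <- intersect(c(.dataset_columns, "block"), names(dataset))
  write.csv(as.data.frame(dataset)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset from CSV
#'
#' Reads a trial CSV written by [write_dataset()] (or prepared externally in
#' the same schema) and validates every invariant, reporting all offending
#' rows at once.
#'
#' @param path CSV path.
#' @return A [conf_dataset()].
#' @export
read_dataset <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(.dataset_columns, "true_category")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop_triconf("dataset file is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  subject <- unique(df$subject)
  experiment <- unique(df$experiment)
  if (length(subject) != 1L || length(experiment) != 1L) {
    stop_triconf("a dataset file must contain exactly one subject and one experiment")
  }
  conf_dataset(df[, setdiff(names(df), c("subject", "experiment"))],
    subject = subject, experiment = experiment
  )
}
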