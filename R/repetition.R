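EXERCISES <- c("DS", "HS", "IL", "TSP")
SIDES <- c("left", "right", "none")
SCORE_LEVELS <- 1:3

#' A single exercise repetition
#'
#' One complete execution of an exercise, recorded as a channels-by-time
#' matrix. Rows follow the [imu_layout()] ordering (accelerometer in g,
#' gyroscope in degrees/s, IMU by IMU); columns are time steps at
#' `sampling_rate` Hz. Raters score movement quality on the ordinal scale
#' 1 (incomplete execution) / 2 (complete with compensation movements) /
#' 3 (perfect execution); `resolved_label` holds the majority-vote label once
#' resolved (see [majority_vote()]).
#'
#' @param repetition_id unique identifier.
#' @param subject_id subject identifier.
#' @param exercise one of `"DS"`, `"HS"`, `"IL"`, `"TSP"`.
#' @param data numeric matrix, `n_channel_rows(layout)` rows by `T >= 1`
#'   columns.
#' @param layout the [imu_layout()] the data rows follow.
#' @param side `"left"`, `"right"` or `"none"` (default).
#' @param sampling_rate sampling rate in Hz (default 120).
#' @param rater_scores integer vector of 0 to 3 rater scores, values in 1..3.
#' @param resolved_label resolved quality label in 1..3, or `NA`.
#' @return an object of class `repetition`.
#' @export
repetition <- function(repetition_id, subject_id, exercise, data, layout,
                       side = "none", sampling_rate = 120,
                       rater_scores = integer(0), resolved_label = NA_integer_) {
  stopifnot(inherits(layout, "imu_layout"))
  exercise <- match.arg(exercise, EXERCISES)
  side <- match.arg(side, SIDES)
  if (!is.matrix(data) || !is.numeric(data)) stop("`data` must be a numeric matrix", call. = FALSE)
  if (nrow(data) != n_channel_rows(layout)) {
    stop(sprintf(
      "repetition '%s': data has %d rows but layout requires %d",
      repetition_id, nrow(data), n_channel_rows(layout)
    ), call. = FALSE)
  }
  if (ncol(data) < 1L) stop("repetition must contain at least one time step", call. = FALSE)
  rater_scores <- as.integer(rater_scores)
  if (length(rater_scores) && !all(rater_scores %in% SCORE_LEVELS)) {
    stop(sprintf("repetition '%s': rater scores must lie in {1,2,3}", repetition_id), call. = FALSE)
  }
  if (!is.na(resolved_label) && !(resolved_label %in% SCORE_LEVELS)) {
    stop("`resolved_label` must be in {1,2,3} or NA", call. = FALSE)
  }
  structure(
    list(
      repetition_id = as.character(repetition_id),
      subject_id = as.character(subject_id),
      exercise = exercise,
      side = side,
      sampling_rate = as.numeric(sampling_rate),
      data = unname(data),
      rater_scores = rater_scores,
      resolved_label = as.integer(resolved_label)
    ),
    class = "repetition"
  )
}

#' @export
print.repetition <- function(x, ...) {
  cat(sprintf(
    "<repetition> %s  subject=%s  %s/%s  %d x %d @ %g Hz  scores=[%s]  label=%s\n",
    x$repetition_id, x$subject_id, x$exercise, x$side,
    nrow(x$data), ncol(x$data), x$sampling_rate,
    paste(x$rater_scores, collapse = ","),
    ifelse(is.na(x$resolved_label), "NA", x$resolved_label)
  ))
  invisible(x)
}

#' A collection of repetitions sharing one channel layout
#'
#' @param repetitions list of [repetition()] objects with unique ids.
#' @param layout the shared [imu_layout()].
#' @param manifest named list of free-form metadata (e.g. generator settings
#'   and seed for synthetic datasets).
#' @return an object of class `imu_dataset`.
#' @export
imu_dataset <- function(repetitions, layout, manifest = list()) {
  stopifnot(inherits(layout, "imu_layout"))
  if (!is.list(repetitions)) stop("`repetitions` must be a list", call. = FALSE)
  ids <- vapply(repetitions, function(r) r$repetition_id, character(1))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate repetition_id: %s", ids[duplicated(ids)][1]), call. = FALSE)
  }
  names(repetitions) <- ids
  ds <- structure(
    list(repetitions = repetitions, layout = layout, manifest = manifest),
    class = "imu_dataset"
  )
  ds
}

#' @export
print.imu_dataset <- function(x, ...) {
  n <- length(x$repetitions)
  subj <- unique(vapply(x$repetitions, function(r) r$subject_id, character(1)))
  cat(sprintf(
    "<imu_dataset> %d repetitions, %d subjects, layout %s\n",
    n, length(subj), format(x$layout)
  ))
  invisible(x)
}

#' @export
length.imu_dataset <- function(x) length(x$repetitions)

#' @export
format.imu_dataset <- function(x, ...) sprintf("imu_dataset(%d)", length(x$repetitions))

#' Extract the resolved labels of a dataset
#'
#' @param dataset an [imu_dataset()].
#' @return named integer vector of resolved labels (`NA` where unresolved).
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset$repetitions, function(r) as.integer(r$resolved_label), integer(1))
}

#' Extract the subject id of every repetition
#'
#' @param dataset an [imu_dataset()].
#' @return named character vector of subject ids.
#' @export
dataset_subjects <- function(dataset) {
  vapply(dataset$repetitions, function(r) r$subject_id, character(1))
}

dataset_lengths <- function(dataset) {
  vapply(dataset$repetitions, function(r) ncol(r$data), integer(1))
}

#' Check all dataset invariants
#'
#' Reports (rather than throws) violations: duplicate repetition ids, row
#' counts inconsistent with the layout, empty time axes, rater scores or
#' resolved labels outside \{1, 2, 3\}.
#'
#' @param dataset an [imu_dataset()].
#' @return character vector of violation messages; empty if the dataset is
#'   valid. Each message names the offending repetition and the violated rule.
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "imu_dataset"))
  violations <- character(0)
  ids <- vapply(dataset$repetitions, function(r) r$repetition_id, character(1))
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) {
    violations <- c(violations, sprintf("repetition '%s': duplicate repetition_id", d))
  }
  rows_needed <- n_channel_rows(dataset$layout)
  for (r in dataset$repetitions) {
    if (!is.matrix(r$data) || nrow(r$data) != rows_needed) {
      violations <- c(violations, sprintf(
        "repetition '%s': %d data rows, layout requires %d",
        r$repetition_id, NROW(r$data), rows_needed
      ))
    }
    if (NCOL(r$data) < 1L) {
      violations <- c(violations, sprintf("repetition '%s': empty time axis", r$repetition_id))
    }
    if (length(r$rater_scores) && !all(r$rater_scores %in% SCORE_LEVELS)) {
      violations <- c(violations, sprintf(
        "repetition '%s': rater score outside {1,2,3}", r$repetition_id
      ))
    }
    if (!is.na(r$resolved_label) && !(r$resolved_label %in% SCORE_LEVELS)) {
      violations <- c(violations, sprintf(
        "repetition '%s': resolved label outside {1,2,3}", r$repetition_id
      ))
    }
  }
  violations
}
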