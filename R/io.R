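DATASET_FORMAT_VERSION <- 1L

# Label map shared by every artifact: ordinal scores {1,2,3} map to the class
# indices {0,1,2} used internally by the network (ascending score order).
label_map <- function() {
  list(scores = 1:3, class_index = 0:2)
}

#' Write a dataset to a directory
#'
#' The on-disk format is plain text: a `manifest.json` holding the layout,
#' the score-to-class-index label map, per-repetition metadata and the file
#' index, plus one tab-separated array file per repetition under `arrays/`
#' (rows = channels, columns = time steps, full double precision). A dataset
#' round-trips losslessly: `read_dataset(write_dataset(ds, p))` reproduces
#' every field and every array value exactly.
#'
#' @param dataset an [imu_dataset()].
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "imu_dataset"))
  ids <- names(dataset$repetitions)
  if (anyDuplicated(ids)) stop("duplicate repetition_id; refusing to write", call. = FALSE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop(sprintf("cannot create directory '%s'", path), call. = FALSE)
  arr_dir <- file.path(path, "arrays")
  dir.create(arr_dir, showWarnings = FALSE)

  index <- lapply(dataset$repetitions, function(r) {
    list(
      repetition_id = r$repetition_id,
      subject_id = r$subject_id,
      exercise = r$exercise,
      side = r$side,
      sampling_rate = r$sampling_rate,
      n_rows = nrow(r$data),
      n_timesteps = ncol(r$data),
      rater_scores = r$rater_scores,
      resolved_label = if (is.na(r$resolved_label)) NULL else r$resolved_label,
      file = file.path("arrays", paste0(r$repetition_id, ".tsv"))
    )
  })
  manifest <- list(
    format = "imuqc-dataset",
    format_version = DATASET_FORMAT_VERSION,
    layout = list(
      n_imus = dataset$layout$n_imus,
      channels_per_imu = dataset$layout$channels_per_imu,
      imu_order = dataset$layout$imu_order,
      channel_order = dataset$layout$channel_order
    ),
    label_map = label_map(),
    metadata = dataset$manifest,
    repetitions = unname(index)
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  for (r in dataset$repetitions) {
    # 17 significant digits guarantee a value-exact double round trip
    txt <- matrix(sprintf("%.17g", r$data), nrow(r$data))
    data.table::fwrite(data.table::as.data.table(txt),
      file.path(arr_dir, paste0(r$repetition_id, ".tsv")),
      sep = "\t", col.names = FALSE, quote = FALSE
    )
  }
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param path dataset directory containing a `manifest.json`.
#' @return an [imu_dataset()]; all invariants are re-validated on read.
#' @export
read_dataset <- function(path) {
  manifest_path <- file.path(path, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop(sprintf("no manifest.json in '%s'", path), call. = FALSE)
  }
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(m$format, "imuqc-dataset")) stop("not an imuqc dataset directory", call. = FALSE)
  layout <- imu_layout(m$layout$n_imus, m$layout$imu_order)
  reps <- lapply(m$repetitions, function(entry) {
    f <- file.path(path, entry$file)
    if (!file.exists(f)) {
      stop(sprintf(
        "manifest references missing array file '%s' (repetition '%s')",
        entry$file, entry$repetition_id
      ), call. = FALSE)
    }
    mat <- as.matrix(data.table::fread(f, sep = "\t", header = FALSE))
    dimnames(mat) <- NULL
    if (nrow(mat) != entry$n_rows || ncol(mat) != entry$n_timesteps) {
      stop(sprintf(
        "repetition '%s': array shape (%d,%d) does not match manifest (%d,%d)",
        entry$repetition_id, nrow(mat), ncol(mat), entry$n_rows, entry$n_timesteps
      ), call. = FALSE)
    }
    repetition(
      repetition_id = entry$repetition_id,
      subject_id = entry$subject_id,
      exercise = entry$exercise,
      side = entry$side,
      sampling_rate = entry$sampling_rate,
      data = mat,
      layout = layout,
      rater_scores = unlist(entry$rater_scores) %||% integer(0),
      resolved_label = entry$resolved_label %||% NA_integer_
    )
  })
  ds <- imu_dataset(reps, layout, manifest = m$metadata %||% list())
  viol <- validate_dataset(ds)
  if (length(viol)) {
    stop(paste(c("dataset invariants violated on read:", viol), collapse = "\n"), call. = FALSE)
  }
  ds
}

#' Export one repetition as a delimited-text table for inspection
#'
#' Writes a tab-separated file with one row per channel (named
#' `<segment>.<channel>`) and one column per time step.
#'
#' @param rep a [repetition()].
#' @param layout its [imu_layout()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
export_repetition_tsv <- function(rep, layout, file) {
  stopifnot(inherits(rep, "repetition"), inherits(layout, "imu_layout"))
  rn <- paste(rep(layout$imu_order, each = layout$channels_per_imu),
    rep(layout$channel_order, times = layout$n_imus),
    sep = "."
  )
  dt <- data.table::data.table(channel = rn)
  dt <- cbind(dt, data.table::as.data.table(rep$data))
  data.table::fwrite(dt, file, sep = "\t", col.names = FALSE)
  invisible(file)
}
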