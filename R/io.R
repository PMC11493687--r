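# Plain-text persistence: array payloads as CSV with a JSON sidecar carrying
# provenance (units, seeds, model names).

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

read_sidecar <- function(path) {
  jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
}

#' Write a leadfield to a portable text container
#'
#' The gain matrix goes to `<path>` as headerless CSV (one row per sensor) and
#' the provenance (reference, ids, dimensions, units) to `<path>.json`.
#'
#' @param leadfield a [leadfield][compute_leadfield].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_leadfield <- function(leadfield, path) {
  stopifnot(inherits(leadfield, "leadfield"))
  data.table::fwrite(data.table::as.data.table(leadfield$gain), path,
                     col.names = FALSE)
  write_sidecar(path, list(
    type = "leadfield", units = "V per A.m", reference = leadfield$reference,
    n_sensors = leadfield$n_sensors, n_sources = leadfield$n_sources,
    source_space_id = leadfield$source_space_id,
    montage_id = leadfield$montage_id,
    shell_model_id = leadfield$shell_model_id))
  invisible(path)
}

#' Read a leadfield written by [write_leadfield()]
#' @param path file path.
#' @return a [leadfield][compute_leadfield] object.
#' @export
read_leadfield <- function(path) {
  meta <- read_sidecar(path)
  if (!identical(meta$type, "leadfield")) stop_invalid("not a leadfield container")
  gain <- as.matrix(data.table::fread(path, header = FALSE))
  dimnames(gain) <- NULL
  structure(list(gain = gain, reference = meta$reference,
                 n_sensors = meta$n_sensors, n_sources = meta$n_sources,
                 source_space_id = meta$source_space_id,
                 montage_id = meta$montage_id,
                 shell_model_id = meta$shell_model_id),
            class = "leadfield")
}

#' Write an epoch set to a portable text container
#'
#' Epochs are flattened to a `(n_epochs * n_sensors) x n_samples` CSV (epoch
#' index varying slowest); condition labels, timing and simulation metadata go
#' to the JSON sidecar.
#'
#' @param epochs an [epoch_set].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(2, 1, 3)), d[1] * d[2], d[3])
  data.table::fwrite(data.table::as.data.table(flat), path, col.names = FALSE)
  meta <- list(type = "epoch_set", n_epochs = d[1], n_sensors = d[2],
               n_samples = d[3], condition = epochs$condition,
               fs = epochs$fs, t0 = epochs$t0, montage_id = epochs$montage_id)
  keep <- setdiff(names(epochs$meta), "clean_erp")
  meta$extra <- epochs$meta[keep]
  write_sidecar(path, meta)
  invisible(path)
}

#' Read an epoch set written by [write_epochs()]
#' @param path file path.
#' @return an [epoch_set].
#' @export
read_epochs <- function(path) {
  meta <- read_sidecar(path)
  if (!identical(meta$type, "epoch_set")) stop_invalid("not an epoch_set container")
  flat <- as.matrix(data.table::fread(path, header = FALSE))
  dimnames(flat) <- NULL
  data <- aperm(array(flat, dim = c(meta$n_sensors, meta$n_epochs,
                                    meta$n_samples)), c(2, 1, 3))
  do.call(epoch_set, c(list(data = data, condition = meta$condition,
                            fs = meta$fs, t0 = meta$t0,
                            montage_id = meta$montage_id),
                       as.list(meta$extra)))
}

#' Export a condition-averaged evoked response as CSV
#'
#' Writes a `time_ms` column followed by one column per sensor.
#'
#' @param epochs an [epoch_set].
#' @param path output file path.
#' @param condition condition to average (default `"erp"`).
#' @return `path`, invisibly.
#' @export
write_evoked_csv <- function(epochs, path, condition = "erp") {
  ev <- sensor_evoked(epochs, condition)
  df <- data.frame(time_ms = epoch_time(epochs), t(ev))
  names(df) <- c("time_ms", sprintf("E%03d", seq_len(nrow(ev))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an experiment results table as CSV
#' @param table a `results_table` from [run_experiment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read an experiment results table written by [write_results()]
#' @param path file path.
#' @return a `results_table`.
#' @export
read_results <- function(path) {
  out <- coerce_results_cols(utils::read.csv(path, stringsAsFactors = FALSE))
  class(out) <- c("results_table", "data.frame")
  out
}
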