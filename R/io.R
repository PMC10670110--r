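#' Write a recording as delimited text
#'
#' One row per sample, one column per channel, preceded by a comment
#' header carrying the sampling rate.
#'
#' @param recording a [hemo_recording()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_recording <- function(recording, path) {
  writeLines(sprintf("# sampling_rate_hz=%.6g", recording$sampling_rate), path)
  data.table::fwrite(data.table::as.data.table(recording$data), path,
                     sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path file path.
#' @return a [hemo_recording()].
#' @export
read_recording <- function(path) {
  header <- readLines(path, n = 1)
  fs <- as.numeric(sub("# sampling_rate_hz=", "", header, fixed = TRUE))
  if (is.na(fs)) stop("missing sampling-rate header")
  dt <- data.table::fread(path, skip = 1, sep = "\t")
  hemo_recording(as.matrix(dt), fs, channels = names(dt))
}

#' Write / read behavioral trial or summary tables
#'
#' Plain tab-separated text with a header row.
#'
#' @param table a data.frame (trial table or `stroop_summary`).
#' @param path file path.
#' @return `write_trials`: the path, invisibly; `read_trials`: the table.
#' @export
write_trials <- function(table, path) {
  data.table::fwrite(table, path, sep = "\t")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}
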