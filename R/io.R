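#' Read and write the two-column waveform text format
#'
#' Signals travel as plain text: a header line `# record_id=<id> fs=<Hz>`
#' followed by one `t<TAB>v` pair per line (seconds, millivolts), mirroring
#' the two-column time/voltage array representation of the source records.
#'
#' @param record A [waveform_record()].
#' @param path File path.
#' @return `write_waveform()` returns `path` invisibly; `read_waveform()`
#'   returns a [waveform_record()].
#' @export
write_waveform <- function(record, path) {
  stopifnot(is.data.frame(record), all(c("t", "v") %in% names(record)))
  fs <- attr(record, "fs")
  id <- attr(record, "record_id")
  header <- sprintf("# record_id=%s fs=%s",
                    if (is.null(id)) "unknown" else id,
                    format(if (is.null(fs)) NA else fs, digits = 12))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(record[, c("t", "v")], con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  header <- readLines(path, n = 1)
  id <- sub("^# record_id=(\\S+) fs=.*$", "\\1", header)
  fs <- as.numeric(sub("^.* fs=(\\S+)$", "\\1", header))
  dat <- utils::read.table(path, skip = 1, sep = "\t",
                           col.names = c("t", "v"))
  waveform_record(dat$t, dat$v, fs = fs, record_id = id)
}

#' Write a numerics record as CSV (one column per channel)
#'
#' @param record A [synthesize_numerics()] record.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_numerics_csv <- function(record, path) {
  stopifnot(is.data.frame(record))
  utils::write.csv(as.data.frame(record), path, row.names = FALSE)
  invisible(path)
}

#' Format ECG feature vectors with the printed triage-table column names
#'
#' Renders rows from [extract_features()] under the ECG feature headers of
#' the printed triage table: `Peaks`, `QRS width`, `Peak to Peak`, `ST El.`.
#'
#' @param features Tibble from [extract_features()].
#' @param path Optional CSV path; when `NULL` the formatted tibble is
#'   returned without writing.
#' @return The formatted tibble (invisibly when `path` is given).
#' @export
format_features_printed <- function(features, path = NULL) {
  out <- tibble::tibble(
    Peaks = features$peaks,
    `QRS width` = features$qrs_width,
    `Peak to Peak` = features$pp_label,
    `ST El.` = ifelse(is.na(features$st_elevated), "",
                      tolower(as.character(features$st_elevated)))
  )
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
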