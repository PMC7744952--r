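#' Summarise a numerics record into a vital-feature row
#'
#' Each monitor channel present in the record is reduced to the rounded
#' (half-up) arithmetic mean of its valid samples. Valid means finite and
#' non-negative, and for SpO2 additionally at most 100. A channel that is
#' absent from the record is coded `NA` (printed as `"x"`, "not addressed");
#' a channel that is present but has no valid sample is coded `0`.
#'
#' @param record A [synthesize_numerics()] record (data frame with `t` plus
#'   channel columns named as in [numerics_channels()]).
#' @return A one-row tibble: `record`, `spo2_level`, `hr`, `abp_sys`,
#'   `abp_dias`, `pap_sys`, `pap_dias`, `nbp_sys`, `nbp_dias` (integers,
#'   `NA` = channel absent).
#' @export
#' @examples
#' rec <- synthesize_numerics(list(SpO2 = 94, HR = 53,
#'                                 `ABP Sys` = 37, `ABP Dias` = 54))
#' summarize_numerics(rec)
summarize_numerics <- function(record) {
  if (!is.data.frame(record) || nrow(record) == 0) {
    stop("`record` must be a non-empty numerics record.")
  }
  chans <- numerics_channels()
  present <- intersect(chans, names(record))
  if (!length(present)) stop("`record` holds none of the known channels: ",
                             toString(chans))
  summarise_one <- function(ch) {
    if (!ch %in% names(record)) return(NA_integer_)
    x <- record[[ch]]
    ok <- is.finite(x) & x >= 0
    if (ch == "SpO2") ok <- ok & x <= 100
    x <- x[ok]
    if (!length(x)) return(0L)
    round_half_up(mean(x))
  }
  vals <- vapply(chans, summarise_one, integer(1))
  id <- attr(record, "record_id")
  tibble::tibble(
    record = if (is.null(id)) NA_character_ else id,
    spo2_level = vals[["SpO2"]], hr = vals[["HR"]],
    abp_sys = vals[["ABP Sys"]], abp_dias = vals[["ABP Dias"]],
    pap_sys = vals[["PAP Sys"]], pap_dias = vals[["PAP Dias"]],
    nbp_sys = vals[["NBP Sys"]], nbp_dias = vals[["NBP Dias"]]
  )
}

# round half away from zero to an integer (printed tables are all-integer)
round_half_up <- function(x) as.integer(floor(x + 0.5))

#' Write vital-feature rows as a CSV in the printed table layout
#'
#' Emits the exact header order of the printed vital-features table
#' (`Record`, `Spo2 level`, `Heart Rates (HR)`, `ABP Sys`, `ABP Dias`,
#' `PAP Sys`, `PAP Dias`, `NBP Sys`, `NBP Dias`), with absent channels
#' printed as `"x"`.
#'
#' @param rows Tibble from [summarize_numerics()] (one or more rows).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vitals_csv <- function(rows, path) {
  hdr <- c("Record", "Spo2 level", "Heart Rates (HR)", "ABP Sys", "ABP Dias",
           "PAP Sys", "PAP Dias", "NBP Sys", "NBP Dias")
  cols <- c("record", "spo2_level", "hr", "abp_sys", "abp_dias",
            "pap_sys", "pap_dias", "nbp_sys", "nbp_dias")
  miss <- setdiff(cols, names(rows))
  if (length(miss)) stop("`rows` is missing column(s): ", toString(miss))
  out <- rows[cols]
  for (cc in cols[-1]) out[[cc]] <- ifelse(is.na(out[[cc]]), "x",
                                           as.character(out[[cc]]))
  names(out) <- hdr
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
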