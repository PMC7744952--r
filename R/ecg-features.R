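#' Split an ECG record into cardiac cycles
#'
#' The signal is referenced to its zero line (the sample median, a robust
#' estimate of the isoelectric baseline) and each sample is assigned to the
#' "up" or "down" half according to its sign. Beats are located as clusters
#' of samples exceeding half the maximum baseline-subtracted voltage, and the
#' record is partitioned into one cycle per beat at the temporal midpoints
#' between consecutive beat apexes. A record with no activity (or shorter
#' than one beat) yields zero cycles.
#'
#' @param record A [waveform_record()] (data frame with `t` and `v`).
#' @param min_gap Clusters of supra-threshold samples closer than this many
#'   seconds are merged into a single beat; default 0.05 s.
#' @param threshold Fraction of the maximum baseline-subtracted voltage a
#'   sample must reach to count as beat activity; default 0.5.
#' @return A nested tibble with one row per cycle: `cycle` (index) and
#'   `data`, a tibble of `t`, `v`, `v0` (baseline-subtracted voltage) and
#'   `up` (logical, `v0 > 0`). The baseline is stored in the `baseline`
#'   attribute.
#' @export
split_cycles <- function(record, min_gap = 0.05, threshold = 0.5) {
  if (!is.data.frame(record) || !all(c("t", "v") %in% names(record))) {
    stop("`record` must be a data frame with columns `t` and `v`.")
  }
  if (nrow(record) == 0) stop("`record` is empty.")
  baseline <- stats::median(record$v)
  v0 <- record$v - baseline
  empty <- tibble::tibble(cycle = integer(), data = list())
  attr(empty, "baseline") <- baseline
  amax <- max(v0)
  if (!is.finite(amax) || amax <= 0) return(empty)

  hi <- which(v0 >= threshold * amax)
  if (!length(hi)) return(empty)
  fs <- attr(record, "fs")
  if (is.null(fs)) fs <- 1 / stats::median(diff(record$t))
  gap_samples <- max(1, round(min_gap * fs))
  # group supra-threshold samples into beats, merging gaps below min_gap
  brk <- which(diff(hi) > gap_samples)
  starts <- hi[c(1, brk + 1)]
  ends <- hi[c(brk, length(hi))]
  apex <- vapply(seq_along(starts), function(k) {
    seg <- starts[k]:ends[k]
    seg[which.max(v0[seg])]
  }, integer(1))

  n <- nrow(record)
  bounds <- if (length(apex) >= 2) {
    c(1, floor((apex[-length(apex)] + apex[-1]) / 2), n)
  } else {
    c(1, n)
  }
  cycles <- lapply(seq_along(apex), function(k) {
    idx <- bounds[k]:(if (k == length(apex)) bounds[k + 1] else bounds[k + 1] - 1)
    vv <- v0[idx]
    tibble::tibble(t = record$t[idx], v = record$v[idx], v0 = vv, up = vv > 0)
  })
  out <- tibble::tibble(cycle = seq_along(cycles), data = cycles)
  attr(out, "baseline") <- baseline
  out
}

#' Locate the R point of one cycle
#'
#' Follows the sort-based rule: the samples of the cycle's upper half are
#' ordered by decreasing voltage (ties broken by earliest time) and the top
#' sample is the R apex.
#'
#' @param cycle One cycle tibble as produced by [split_cycles()] (columns
#'   `t`, `v`, `v0`, `up`).
#' @return A one-row tibble with `t` and `v` of the R point.
#' @export
locate_r <- function(cycle) {
  stopifnot(is.data.frame(cycle), all(c("t", "v0", "up") %in% names(cycle)))
  upper <- cycle[cycle$up, , drop = FALSE]
  if (nrow(upper) == 0) stop("no R wave in cycle: empty upper half")
  ord <- order(-upper$v0, upper$t)
  r <- upper[ord[1], ]
  tibble::tibble(t = r$t, v = r$v)
}

#' Locate the Q and S points around a given R apex
#'
#' Q is the minimum-voltage sample in a window before R and S the minimum in
#' a window after R (earliest sample wins on ties). The window is
#' proportional to the cycle length (`window_frac` of it, floored at
#' `window_min` seconds) so that wide QRS complexes remain inside it.
#'
#' @param cycle One cycle tibble from [split_cycles()].
#' @param r One-row tibble from [locate_r()].
#' @param window_frac Fraction of the cycle duration searched on each side of
#'   R; default 0.35.
#' @param window_min Lower bound on the search window in seconds; default
#'   0.12 s.
#' @return A list with one-row tibbles `q` and `s` (`q$t < r$t < s$t`).
#' @export
locate_qs <- function(cycle, r, window_frac = 0.35, window_min = 0.12) {
  stopifnot(is.data.frame(cycle), all(c("t", "v0") %in% names(cycle)))
  cyc_dur <- max(cycle$t) - min(cycle$t)
  win <- max(window_min, window_frac * cyc_dur)
  before <- cycle[cycle$t < r$t & cycle$t >= r$t - win, , drop = FALSE]
  after <- cycle[cycle$t > r$t & cycle$t <= r$t + win, , drop = FALSE]
  if (nrow(before) == 0 || nrow(after) == 0) {
    stop("degenerate cycle: no samples in the Q/S search window")
  }
  qi <- order(before$v0, before$t)[1]
  si <- order(after$v0, after$t)[1]
  list(q = tibble::tibble(t = before$t[qi], v = before$v[qi]),
       s = tibble::tibble(t = after$t[si], v = after$v[si]))
}

#' QRS width from the Q and S points
#'
#' @param q,s One-row tibbles (or lists) with a `t` element; `q$t <= s$t`.
#' @return Width in seconds, `s$t - q$t`.
#' @export
qrs_width <- function(q, s) {
  if (q$t > s$t) stop("ordering violation: Q occurs after S (q$t > s$t)")
  s$t - q$t
}

#' ST-segment elevation of one cycle
#'
#' The elevation magnitude is the mean baseline-subtracted voltage over a
#' measurement window after the S point (40-80 ms by default, i.e. around the
#' J point + 60 ms convention); the cycle is flagged elevated when the
#' magnitude reaches `threshold` millivolts.
#'
#' @param cycle One cycle tibble from [split_cycles()].
#' @param s One-row tibble from [locate_qs()].
#' @param window Two numbers: start and end of the measurement window in
#'   seconds after S; default `c(0.04, 0.08)`.
#' @param threshold Elevation flag threshold in mV; default 0.1 (the usual
#'   clinical cut-off).
#' @return A one-row tibble with `magnitude` (mV) and `st_elevated`.
#' @export
st_elevation <- function(cycle, s, window = c(0.04, 0.08), threshold = 0.1) {
  post <- cycle[cycle$t > s$t, , drop = FALSE]
  if (nrow(post) == 0) stop("truncated cycle: no samples after the S point")
  win <- post[post$t >= s$t + window[1] & post$t <= s$t + window[2], , drop = FALSE]
  if (nrow(win) == 0) win <- post  # short cycle tail: measure what exists
  mag <- mean(win$v0)
  tibble::tibble(magnitude = mag, st_elevated = mag >= threshold)
}

#' Extract the ECG feature vector of a record
#'
#' Runs the full fiducial pipeline - cycle splitting, R/Q/S localisation,
#' QRS width, ST elevation - and summarises the record into one feature row:
#' the beat (peak) count, the median QRS width, the mean R-R interval and its
#' Regular/Irregular label (coefficient of variation below `regularity_cv`
#' means Regular), the median ST magnitude with its flag, and the heart rate
#' (beats scaled to one minute over the record duration).
#'
#' @param record A [waveform_record()].
#' @param regularity_cv Coefficient-of-variation cut-off on R-R intervals
#'   below which the rhythm is labelled Regular; default 0.10.
#' @param st_threshold Elevation flag threshold in mV; default 0.1.
#' @return A one-row tibble: `peaks`, `qrs_width`, `pp_interval`, `pp_cv`,
#'   `pp_label`, `st_magnitude`, `st_elevated`, `heart_rate`.
#' @export
#' @examples
#' rec <- synthesize_ecg(class_profile("sleep_apnea")$params)
#' extract_features(rec)
extract_features <- function(record, regularity_cv = 0.10, st_threshold = 0.1) {
  cycles <- split_cycles(record)
  duration <- attr(record, "duration")
  if (is.null(duration)) {
    step <- stats::median(diff(record$t))
    duration <- max(record$t) - min(record$t) + step
  }
  if (nrow(cycles) == 0) {
    return(tibble::tibble(
      peaks = 0L, qrs_width = NA_real_, pp_interval = NA_real_,
      pp_cv = NA_real_, pp_label = "Regular", st_magnitude = NA_real_,
      st_elevated = NA, heart_rate = 0
    ))
  }
  per_cycle <- purrr::map(cycles$data, function(cyc) {
    tryCatch({
      r <- locate_r(cyc)
      qs <- locate_qs(cyc, r)
      st <- st_elevation(cyc, qs$s, threshold = st_threshold)
      tibble::tibble(r_t = r$t, qrs = qrs_width(qs$q, qs$s),
                     st_mag = st$magnitude)
    }, error = function(e) NULL)
  })
  per_cycle <- dplyr::bind_rows(per_cycle)
  peaks <- nrow(per_cycle)
  if (peaks == 0) {
    return(tibble::tibble(
      peaks = 0L, qrs_width = NA_real_, pp_interval = NA_real_,
      pp_cv = NA_real_, pp_label = "Regular", st_magnitude = NA_real_,
      st_elevated = NA, heart_rate = 0
    ))
  }
  rr <- diff(per_cycle$r_t)
  pp_interval <- if (length(rr)) mean(rr) else NA_real_
  pp_cv <- if (length(rr) >= 2 && mean(rr) > 0) stats::sd(rr) / mean(rr) else 0
  st_mag <- stats::median(per_cycle$st_mag)
  tibble::tibble(
    peaks = as.integer(peaks),
    qrs_width = stats::median(per_cycle$qrs),
    pp_interval = pp_interval,
    pp_cv = pp_cv,
    pp_label = if (pp_cv < regularity_cv) "Regular" else "Irregular",
    st_magnitude = st_mag,
    st_elevated = st_mag >= st_threshold,
    heart_rate = peaks * 60 / duration
  )
}
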