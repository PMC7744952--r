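#' Electrocardiogram morphology parameters
#'
#' Bundle the per-wave morphology of one cardiac cycle for the Gaussian-wave
#' synthesizer. Each of the five canonical deflections (P, Q, R, S, T) is a
#' Gaussian bump with an amplitude in millivolts, a centre offset in seconds
#' relative to the R-wave apex, and a width (Gaussian standard deviation) in
#' seconds. An optional plateau of height `st_offset` raises the segment
#' between the S trough and the T wave, emulating ST elevation.
#'
#' @param heart_rate Beats per minute; one cycle lasts `60 / heart_rate` s.
#' @param waves Data frame with columns `wave` (`"P","Q","R","S","T"`),
#'   `amp` (mV), `center` (s, offset from the R apex) and `width` (s, > 0).
#' @param st_offset Height in mV of the ST plateau between S and T; 0 means
#'   an isoelectric ST segment.
#' @param noise_sd Standard deviation in mV of additive white Gaussian noise.
#' @param seed Integer seed making the noise reproducible; `NULL` leaves the
#'   random-number state alone.
#'
#' @return An object of class `ecg_params`.
#' @export
#' @examples
#' p <- ecg_params(heart_rate = 60)
#' rec <- synthesize_ecg(p, duration = 10, fs = 250)
ecg_params <- function(heart_rate = 75,
                       waves = default_waves(),
                       st_offset = 0,
                       noise_sd = 0,
                       seed = NULL) {
  if (!is.numeric(heart_rate) || length(heart_rate) != 1 || heart_rate <= 0) {
    stop("`heart_rate` must be a single positive number (beats/min).")
  }
  waves <- tibble::as_tibble(waves)
  need <- c("wave", "amp", "center", "width")
  miss <- setdiff(need, names(waves))
  if (length(miss)) stop("`waves` is missing column(s): ", toString(miss))
  if (any(waves$width <= 0)) stop("`waves$width` must be positive.")
  amp <- stats::setNames(waves$amp, waves$wave)
  if (all(c("R", "Q", "S") %in% waves$wave) &&
      !(amp[["R"]] > abs(amp[["Q"]]) && amp[["R"]] > abs(amp[["S"]]))) {
    stop("R amplitude must exceed |Q| and |S| so that R is the cycle maximum.")
  }
  if (noise_sd < 0) stop("`noise_sd` must be non-negative.")
  structure(
    list(heart_rate = heart_rate, waves = waves, st_offset = st_offset,
         noise_sd = noise_sd, seed = seed),
    class = "ecg_params"
  )
}

#' @rdname ecg_params
#' @export
default_waves <- function() {
  tibble::tibble(
    wave   = c("P", "Q", "R", "S", "T"),
    amp    = c(0.15, -0.25, 1.2, -0.25, 0.3),
    center = c(-0.2, -0.04, 0, 0.04, 0.24),
    width  = c(0.02, 0.008, 0.008, 0.008, 0.03)
  )
}

#' Construct a waveform record from time/voltage samples
#'
#' A waveform record is a tibble of uniformly sampled `(t, v)` pairs (seconds,
#' millivolts) carrying its sampling rate, identifier and duration as
#' attributes, mirroring the two-column array representation of monitor
#' exports: row 0 at `t = 0`, row n at `t = duration - 1/fs`.
#'
#' @param t Sample times in seconds (strictly increasing, constant step).
#' @param v Voltages in millivolts, same length as `t`.
#' @param fs Sampling rate in Hz.
#' @param record_id Text label for the record.
#' @param ground_truth Optional list of generator ground truth (R times,
#'   Q/S times, cycle boundaries, ST offset) used by oracle tests.
#' @return A tibble of class `waveform_record` with columns `t` and `v`.
#' @export
waveform_record <- function(t, v, fs, record_id = "synthetic",
                            ground_truth = NULL) {
  stopifnot(length(t) == length(v), fs > 0)
  out <- tibble::tibble(t = as.numeric(t), v = as.numeric(v))
  attr(out, "fs") <- fs
  attr(out, "record_id") <- record_id
  attr(out, "duration") <- length(t) / fs
  attr(out, "ground_truth") <- ground_truth
  class(out) <- c("waveform_record", class(out))
  out
}

#' Synthesize an ECG waveform
#'
#' Renders a train of Gaussian-wave cardiac cycles at a fixed heart rate.
#' The generator records its own ground truth (true R apex times, Q/S trough
#' times, cycle boundaries and the ST plateau height) in the
#' `ground_truth` attribute so that feature extractors can be tested against
#' it. With all amplitudes, `st_offset` and `noise_sd` equal to zero the
#' output is identically zero.
#'
#' @param params An [ecg_params()] object.
#' @param duration Record length in seconds (> 0); default 60 s.
#' @param fs Sampling rate in Hz (> 0); default 250 Hz.
#' @param record_id Text label.
#' @return A [waveform_record()] with `round(duration * fs)` samples.
#' @export
#' @examples
#' rec <- synthesize_ecg(ecg_params(heart_rate = 67), duration = 60, fs = 250)
#' nrow(rec)  # 15000
synthesize_ecg <- function(params, duration = 60, fs = 250,
                           record_id = "synthetic_ecg") {
  if (!inherits(params, "ecg_params")) stop("`params` must be an `ecg_params` object.")
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0) {
    stop("`duration` must be a single positive number of seconds.")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("`fs` must be a single positive sampling rate in Hz.")
  }
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  v <- numeric(n)

  period <- 60 / params$heart_rate
  n_beats <- floor(duration / period + 1e-9)
  r_times <- (seq_len(n_beats) - 0.5) * period

  waves <- params$waves
  amp <- stats::setNames(waves$amp, waves$wave)
  cen <- stats::setNames(waves$center, waves$wave)
  wid <- stats::setNames(waves$width, waves$wave)

  for (rk in r_times) {
    for (w in seq_len(nrow(waves))) {
      if (waves$amp[w] == 0) next
      c_w <- rk + waves$center[w]
      s_w <- waves$width[w]
      idx <- which(t >= c_w - 5 * s_w & t <= c_w + 5 * s_w)
      if (length(idx)) {
        v[idx] <- v[idx] + waves$amp[w] * exp(-((t[idx] - c_w)^2) / (2 * s_w^2))
      }
    }
    if (params$st_offset != 0 && all(c("S", "T") %in% waves$wave)) {
      # smooth plateau from just after the S trough up to the T-wave centre
      a <- rk + cen[["S"]] + 0.015
      b <- rk + cen[["T"]]
      if (b > a) {
        tau <- 0.005
        idx <- which(t >= a - 6 * tau & t <= b + 6 * tau)
        if (length(idx)) {
          ramp <- stats::plogis((t[idx] - a) / tau) * stats::plogis(-(t[idx] - b) / tau)
          v[idx] <- v[idx] + params$st_offset * ramp
        }
      }
    }
  }

  if (params$noise_sd > 0) {
    noise <- if (is.null(params$seed)) {
      stats::rnorm(n, 0, params$noise_sd)
    } else {
      withr::with_seed(params$seed, stats::rnorm(n, 0, params$noise_sd))
    }
    v <- v + noise
  }

  bounds <- if (n_beats >= 1) {
    c(0, if (n_beats >= 2) (r_times[-n_beats] + r_times[-1]) / 2, duration)
  } else {
    c(0, duration)
  }
  gt <- list(
    r_times = r_times,
    q_times = r_times + if ("Q" %in% names(cen)) cen[["Q"]] else NA_real_,
    s_times = r_times + if ("S" %in% names(cen)) cen[["S"]] else NA_real_,
    cycle_bounds = bounds,
    st_offset = params$st_offset,
    heart_rate = params$heart_rate,
    qrs_width = if (all(c("Q", "S") %in% names(cen))) cen[["S"]] - cen[["Q"]] else NA_real_
  )
  waveform_record(t, v, fs, record_id, ground_truth = gt)
}

#' Allowed numerics channel names
#'
#' The low-rate monitor channels recognised by the numerics synthesizer and
#' summariser: oxygen saturation, heart rate, and systolic/diastolic pairs of
#' ambulatory (ABP), pulmonary-artery (PAP) and non-invasive (NBP) pressures.
#' @return Character vector of channel names.
#' @export
numerics_channels <- function() {
  c("SpO2", "HR", "ABP Sys", "ABP Dias", "PAP Sys", "PAP Dias",
    "NBP Sys", "NBP Dias")
}

#' Synthesize a low-rate numerics record
#'
#' Generates monitor-style "numerics" channels sampled every `interval`
#' seconds at `t = 0, interval, 2 * interval, ...`, so a channel holds
#' `floor(duration / interval) + 1` samples. The default interval of 1.024 s
#' corresponds to an implied sampling frequency of 0.976563 Hz.
#'
#' @param channel_specs Named list mapping a channel name (see
#'   [numerics_channels()]) to either a single number (constant channel) or a
#'   list with elements `mean` and `sd` (independent Gaussian samples).
#' @param duration Record length in seconds; default 60 s.
#' @param interval Sampling interval in seconds (> 0); default 1.024 s.
#' @param record_id Text label.
#' @param seed Optional integer seed for the random channels.
#' @return A tibble of class `numerics_record` with a `t` column and one
#'   column per channel.
#' @export
#' @examples
#' rec <- synthesize_numerics(list(SpO2 = 97, HR = 72))
#' nrow(rec)  # 59
synthesize_numerics <- function(channel_specs, duration = 60, interval = 1.024,
                                record_id = "synthetic_numerics", seed = NULL) {
  if (!is.numeric(interval) || length(interval) != 1 || interval <= 0) {
    stop("`interval` must be a single positive number of seconds.")
  }
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0) {
    stop("`duration` must be a single positive number of seconds.")
  }
  bad <- setdiff(names(channel_specs), numerics_channels())
  if (length(bad)) {
    stop("Unknown channel name(s): ", toString(bad),
         ". Allowed channels: ", toString(numerics_channels()))
  }
  n <- floor(duration / interval) + 1
  t <- (seq_len(n) - 1) * interval
  gen_one <- function(spec) {
    if (is.numeric(spec) && length(spec) == 1) {
      rep(as.numeric(spec), n)
    } else if (is.list(spec) && all(c("mean", "sd") %in% names(spec))) {
      stats::rnorm(n, spec$mean, spec$sd)
    } else {
      stop("Each channel spec must be a single number or list(mean=, sd=).")
    }
  }
  cols <- if (is.null(seed)) {
    lapply(channel_specs, gen_one)
  } else {
    withr::with_seed(seed, lapply(channel_specs, gen_one))
  }
  out <- tibble::as_tibble(c(list(t = t), cols))
  attr(out, "interval") <- interval
  attr(out, "record_id") <- record_id
  attr(out, "duration") <- duration
  class(out) <- c("numerics_record", class(out))
  out
}

#' Implied sampling frequency of a numerics interval
#'
#' @param interval Sampling interval in seconds.
#' @param digits Decimal places used for the printed frequency; the default 6
#'   reproduces the conventional "0.976563 Hz" for a 1.024 s interval.
#' @return The implied frequency in Hz, rounded to `digits` places.
#' @export
implied_sampling_frequency <- function(interval = 1.024, digits = 6) {
  if (interval <= 0) stop("`interval` must be positive.")
  # round half away from zero at the requested digit, as the tables print
  floor(10^digits / interval + 0.5) / 10^digits
}

#' ECG class profiles
#'
#' Named morphology presets whose noise-free synthesis reproduces, through the
#' feature extractor, the feature block printed for each disease class of the
#' ground-truth triage table: the beat count over 60 s (equal to the heart
#' rate in beats/min), the QRS width, the peak-to-peak regularity label and
#' the ST-elevation flag.
#'
#' Profiles: `sleep_apnea` and `long_term_st` (67 beats, QRS 0.06 s, ST
#' elevated), `arrhythmia_wide` (54 beats, QRS 0.5 s), `arrhythmia_narrow`
#' (77 beats, QRS 0.047 s, ST elevated), `heart_failure` (64 beats, QRS
#' 0.169 s), `normal` (75 beats, QRS 0.08 s) and `normal_hr110` (110 beats,
#' QRS 0.08 s).
#'
#' @param name Profile name.
#' @return A list with elements `profile` (one-row tibble of target features)
#'   and `params` (the matching [ecg_params()]).
#' @export
#' @examples
#' class_profile("sleep_apnea")$profile
class_profile <- function(name) {
  profiles <- class_profile_table()
  if (!is.character(name) || length(name) != 1 || !name %in% profiles$name) {
    stop("Unknown profile `", paste(name, collapse = ","),
         "`. Valid profiles: ", toString(profiles$name))
  }
  p <- profiles[profiles$name == name, ]
  period <- 60 / p$heart_rate
  qrs <- p$qrs_width
  qrs_sd <- max(0.006, qrs / 12)
  t_off <- qrs / 2 + min(0.2, 0.28 * period)
  p_off <- -qrs / 2 - min(0.16, 0.22 * period)
  waves <- tibble::tibble(
    wave   = c("P", "Q", "R", "S", "T"),
    amp    = c(0.15, -0.25, 1.2, -0.25, 0.3),
    center = c(p_off, -qrs / 2, 0, qrs / 2, t_off),
    width  = c(0.02, qrs_sd, qrs_sd, qrs_sd, 0.03)
  )
  params <- ecg_params(
    heart_rate = p$heart_rate, waves = waves,
    st_offset = if (p$st_elevated) 0.2 else 0, noise_sd = 0
  )
  list(profile = tibble::as_tibble(p), params = params)
}

#' @rdname class_profile
#' @export
class_profile_table <- function() {
  tibble::tibble(
    name = c("sleep_apnea", "long_term_st", "arrhythmia_wide",
             "arrhythmia_narrow", "heart_failure", "normal", "normal_hr110"),
    peaks = c(67L, 67L, 54L, 77L, 64L, 75L, 110L),
    qrs_width = c(0.06, 0.06, 0.5, 0.047, 0.169, 0.08, 0.08),
    st_elevated = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
    pp_label = "Regular",
    heart_rate = c(67, 67, 54, 77, 64, 75, 110)
  )
}
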