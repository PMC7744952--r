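# shared fixtures built in code

# noise-free synthetic record for a named class profile (memoised per run:
# synthesis is deterministic, so one copy serves every test)
profile_record <- local({
  cache <- new.env(parent = emptyenv())
  function(name, duration = 60, fs = 250) {
    key <- paste(name, duration, fs)
    if (is.null(cache[[key]])) {
      cache[[key]] <- synthesize_ecg(class_profile(name)$params,
                                     duration = duration, fs = fs)
    }
    cache[[key]]
  }
})

# a waveform with R-like Gaussian peaks at arbitrary times (for rhythm tests)
pulse_train <- function(r_times, duration, fs = 250, amp = 1, width = 0.01) {
  t <- (seq_len(round(duration * fs)) - 1) / fs
  v <- numeric(length(t))
  for (rk in r_times) v <- v + amp * exp(-((t - rk)^2) / (2 * width^2))
  waveform_record(t, v, fs = fs, record_id = "pulse_train",
                  ground_truth = list(r_times = r_times))
}

# one feature-vector row in the printed string encoding used by the model
feature_row <- function(spo2, bp_high, bp_low, cp, sb, pa, ar,
                        peaks, qrs, pp = "Regular", st) {
  tibble::tibble(spo2 = spo2, bp_high = bp_high, bp_low = bp_low,
                 chest_pain = cp, short_breath = sb, palpitation = pa,
                 at_rest = ar, peaks = peaks, qrs_width = qrs, pp = pp,
                 st = st)
}
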