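test_that("a flat record yields zero cycles and an empty feature vector", {
  t <- (0:14999) / 250
  rec <- waveform_record(t, rep(0, 15000), fs = 250, record_id = "flat")
  expect_equal(nrow(split_cycles(rec)), 0)
  f <- extract_features(rec)
  expect_equal(f$peaks, 0L)
  expect_equal(f$pp_label, "Regular")
  expect_true(is.na(f$pp_interval))
})

test_that("cycle boundaries recover the generator ground truth", {
  for (spec in list(c(beats = 6, hr = 60, dur = 6), c(beats = 60, hr = 60, dur = 60))) {
    rec <- synthesize_ecg(ecg_params(heart_rate = spec[["hr"]]),
                          duration = spec[["dur"]], fs = 250)
    gt <- attr(rec, "ground_truth")
    cycles <- split_cycles(rec)
    expect_equal(nrow(cycles), spec[["beats"]])
    # interior boundaries sit at the midpoints between true R apexes
    got_starts <- vapply(cycles$data, function(d) d$t[1], numeric(1))
    true_starts <- gt$cycle_bounds[-length(gt$cycle_bounds)]
    expect_true(all(abs(got_starts - true_starts) <= 1 / 250 + 1e-9))
  }
})

test_that("locate_r finds the apex of a single triangular pulse", {
  t <- (0:999) / 250
  v <- pmax(0, 1 - abs(t - 2) / 0.05)  # triangle peaking at t = 2
  rec <- waveform_record(t, v, fs = 250)
  cyc <- split_cycles(rec)
  expect_equal(nrow(cyc), 1)
  r <- locate_r(cyc$data[[1]])
  expect_equal(r$t, 2)
})

test_that("locate_r matches brute-force argmax over the upper half", {
  rec <- profile_record("sleep_apnea")
  cycles <- split_cycles(rec)
  for (k in c(1, 10, 33, 67)) {
    cyc <- cycles$data[[k]]
    r <- locate_r(cyc)
    upper <- cyc[cyc$up, ]
    expect_equal(r$t, upper$t[which.max(upper$v0)])
  }
})

test_that("locate_r on the up half requires an upper half", {
  cyc <- tibble::tibble(t = 1:5 / 5, v = -1, v0 = -1, up = FALSE)
  expect_error(locate_r(cyc), "no R wave")
})

test_that("Q and S are the windowed minima on each side of R", {
  rec <- profile_record("heart_failure")
  cycles <- split_cycles(rec)
  gt <- attr(rec, "ground_truth")
  for (k in c(2, 30, 63)) {
    cyc <- cycles$data[[k]]
    r <- locate_r(cyc)
    qs <- locate_qs(cyc, r)
    expect_lt(qs$q$t, r$t)
    expect_gt(qs$s$t, r$t)
    # generator oracle: troughs at the true Q/S wave centres (+- 1 sample)
    expect_lt(abs(qs$q$t - gt$q_times[k]), 1 / 250 + 1e-9)
    expect_lt(abs(qs$s$t - gt$s_times[k]), 1 / 250 + 1e-9)
    # brute-force windowed argmin oracle
    win <- max(0.12, 0.35 * (max(cyc$t) - min(cyc$t)))
    before <- cyc[cyc$t < r$t & cyc$t >= r$t - win, ]
    after <- cyc[cyc$t > r$t & cyc$t <= r$t + win, ]
    expect_equal(qs$q$t, before$t[which.min(before$v0)])
    expect_equal(qs$s$t, after$t[which.min(after$v0)])
  }
})

test_that("a symmetric QRS yields Q and S equidistant from R", {
  rec <- profile_record("sleep_apnea")
  cyc <- split_cycles(rec)$data[[5]]
  r <- locate_r(cyc)
  qs <- locate_qs(cyc, r)
  expect_lt(abs((r$t - qs$q$t) - (qs$s$t - r$t)), 1 / 250 + 1e-9)
})

test_that("qrs_width is the Q-to-S time difference with ordering enforced", {
  expect_equal(qrs_width(list(t = 1), list(t = 1)), 0)
  expect_equal(qrs_width(list(t = 1.0), list(t = 1.08)), 0.08)
  expect_error(qrs_width(list(t = 2), list(t = 1)), "ordering")
})

test_that("ST elevation measures the post-S offset against baseline", {
  # flat baseline after S -> zero magnitude, not elevated
  cyc <- tibble::tibble(t = (0:250) / 250, v = 0, v0 = 0, up = FALSE)
  cyc$v0[50] <- 1; cyc$up[50] <- TRUE  # a lone spike as R
  st <- st_elevation(cyc, s = list(t = cyc$t[60]))
  expect_equal(st$magnitude, 0)
  expect_false(st$st_elevated)
  expect_error(st_elevation(cyc, s = list(t = 2)), "truncated")
})

test_that("the generator's ST offset is recovered from elevated profiles", {
  rec <- profile_record("sleep_apnea")  # st_offset 0.2 mV
  f <- extract_features(rec)
  expect_equal(f$st_magnitude, 0.2, tolerance = 0.075) # baseline-bias bound
  expect_true(f$st_elevated)
  f2 <- extract_features(profile_record("arrhythmia_wide"))  # no offset
  expect_false(f2$st_elevated)
})

test_that("constant R-R intervals are Regular, alternating ones Irregular", {
  reg <- pulse_train(seq(0.5, 19.5, by = 1), duration = 20)
  f <- extract_features(reg)
  expect_equal(f$pp_label, "Regular")
  expect_equal(f$pp_interval, 1, tolerance = 1e-6)
  gaps <- rep(c(0.5, 1.0), 13)
  irr <- pulse_train(cumsum(c(0.5, gaps)), duration = 21)
  f2 <- extract_features(irr)  # CV of R-R about 0.33
  expect_equal(f2$pp_label, "Irregular")
  expect_gt(f2$pp_cv, 0.10)
})

test_that("feature extraction is deterministic", {
  rec <- profile_record("arrhythmia_narrow")
  expect_identical(extract_features(rec), extract_features(rec))
})

test_that("scaling the voltage leaves counts, times and labels unchanged", {
  rec <- profile_record("heart_failure", duration = 20)
  for (c_scale in c(0.5, 3)) {
    scaled <- waveform_record(rec$t, rec$v * c_scale, fs = attr(rec, "fs"))
    a <- split_cycles(rec)
    b <- split_cycles(scaled)
    expect_equal(nrow(a), nrow(b))
    expect_equal(vapply(a$data, function(d) locate_r(d)$t, numeric(1)),
                 vapply(b$data, function(d) locate_r(d)$t, numeric(1)))
    fa <- extract_features(rec); fb <- extract_features(scaled)
    expect_equal(fa$peaks, fb$peaks)
    expect_equal(fa$pp_label, fb$pp_label)
  }
})

test_that("doubling the sampling rate does not change the peak count", {
  for (nm in c("sleep_apnea", "arrhythmia_wide", "normal_hr110")) {
    f1 <- extract_features(profile_record(nm, duration = 30, fs = 250))
    f2 <- extract_features(profile_record(nm, duration = 30, fs = 500))
    expect_equal(f1$peaks, f2$peaks)
  }
})

test_that("extraction survives moderate additive noise", {
  p <- class_profile("normal")$params
  p$noise_sd <- 0.05
  p$seed <- 11
  rec <- synthesize_ecg(p, duration = 60, fs = 250)
  f <- extract_features(rec)
  expect_equal(f$peaks, 75L)
  expect_equal(f$pp_label, "Regular")
})
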