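tone_recording <- function(freqs, amps, fs = 125, dur = 20) {
  t <- (seq_len(dur * fs) - 1) / fs
  x <- Reduce(`+`, Map(function(f, a) a * sin(2 * pi * f * t), freqs, amps))
  eeg_recording(matrix(rep(x, 16), nrow = 16, byrow = TRUE), fs,
                default_montage())
}

mid_power <- function(rec, f) {
  # power at frequency f over the central 10 s (away from edge effects)
  x <- rec$samples[1, (5 * rec$fs + 1):(15 * rec$fs)]
  n <- length(x)
  bin <- round(f * n / rec$fs) + 1
  (2 * Mod(stats::fft(x))[bin] / n)^2
}

test_that("the filter chain notches 60 Hz, passes 10 Hz, and kills DC", {
  rec <- tone_recording(c(10, 60), c(1, 1))
  out <- apply_filters(rec)
  expect_lt(mid_power(out, 60) / mid_power(rec, 60), 0.01)
  expect_equal(mid_power(out, 10) / mid_power(rec, 10), 1, tolerance = 0.05)
  dc <- eeg_recording(matrix(7, 16, 125 * 10), 125, default_montage())
  out_dc <- apply_filters(dc)
  expect_lt(max(abs(out_dc$samples)), 1e-6)
  expect_identical(out$annotations, rec$annotations)
  expect_error(apply_filters(rec, filter_spec(band_high = 70)), "Nyquist")
})

test_that("filtering is idempotent in the stopbands", {
  rec <- tone_recording(c(10, 60), c(1, 1))
  once <- apply_filters(rec)
  twice <- apply_filters(once)
  # the second pass changes the passband by < 1% and cannot revive 60 Hz
  expect_equal(mid_power(twice, 10) / mid_power(once, 10), 1,
               tolerance = 0.01)
  expect_lt(mid_power(twice, 60), 0.01 * mid_power(rec, 60))
})

test_that("phase cropping trims annotations symmetrically and validates durations", {
  rec <- generate_recording(subject_profile(seed = 3),
                            protocol_spec(n_trials_per_session = 1,
                                          n_sessions = 1))
  cropped <- crop_phases(rec, 3)
  expect_equal(cropped$annotations$duration_s, rep(10, 3))
  expect_equal(cropped$annotations$onset_s, rec$annotations$onset_s + 3)
  expect_identical(crop_phases(rec, 0), rec)
  short <- generate_recording(subject_profile(seed = 3),
                              protocol_spec(phase_duration_s = 5,
                                            n_trials_per_session = 1,
                                            n_sessions = 1))
  expect_error(crop_phases(short, 3), "trial 1")
})

test_that("sliding-window epoch counts match the closed form and brute force", {
  fs <- 100
  mk <- function(T) eeg_recording(
    matrix(stats::rnorm(16 * round((T + 2) * fs)), nrow = 16), fs,
    default_montage(),
    data.frame(onset_s = 1, duration_s = T, phase = "motor_imagery",
               trial = 1L, session = 1L))
  count <- function(T, len, ov)
    length(make_epochs(mk(T), len, ov,
                       label_map = c(motor_imagery = "fist")))
  expect_equal(count(1, 1, 0.75), 1)        # boundary: exactly one window
  expect_equal(count(10, 1, 0.75), 37)      # 10 s eligible at 0.25 s hop
  expect_equal(count(0.8, 1, 0.75), 0)      # interval shorter than window
  set.seed(17)
  for (i in 1:200) {
    T <- round(stats::runif(1, 0.3, 8), 2)
    len <- round(stats::runif(1, 0.2, min(2, T + 0.5)), 2)
    ov <- round(stats::runif(1, 0, len - 0.05), 2)
    expect_equal(count(T, len, ov), brute_epoch_count(T, len, ov),
                 info = sprintf("T=%g len=%g ov=%g", T, len, ov))
  }
  expect_error(make_epochs(mk(5), 1, 1), "overlap")
})

test_that("the default protocol yields 666 epochs per class and clean provenance", {
  rec <- crop_phases(generate_recording(subject_profile(seed = 6),
                                        protocol_spec()))
  ep <- make_epochs(rec)
  expect_equal(unname(table(ep$labels)), c(666, 666), ignore_attr = TRUE)
  # no epoch extends beyond its (cropped) phase interval
  ann <- rec$annotations
  key <- paste(ann$session, ann$trial, ann$phase)
  ends <- stats::setNames(ann$onset_s + ann$duration_s, key)
  starts <- stats::setNames(ann$onset_s, key)
  k <- paste(ep$provenance$session, ep$provenance$trial, ep$provenance$phase)
  expect_true(all(ep$provenance$onset_s >= starts[k] - 1e-9))
  expect_true(all(ep$provenance$onset_s + 1 <= ends[k] + 1e-9))
  # motor execution is excluded by default
  expect_false("motor_execution" %in% ep$provenance$phase)
})

test_that("grouped splitting is leakage-free, stratified, and deterministic", {
  rec <- crop_phases(generate_recording(subject_profile(seed = 8),
                                        protocol_spec()))
  ep <- make_epochs(rec)
  parts <- split_by_group(ep, "trial", 0.22, seed = 5)
  trial_of <- function(e) unique(paste(e$provenance$session,
                                       e$provenance$trial))
  expect_length(trial_of(parts$test), 4)    # round(0.22 * 18)
  expect_length(trial_of(parts$train), 14)
  expect_length(intersect(trial_of(parts$train), trial_of(parts$test)), 0)
  expect_setequal(unique(parts$test$labels), c("fist", "rest"))
  again <- split_by_group(ep, "trial", 0.22, seed = 5)
  expect_identical(again$test$provenance, parts$test$provenance)
  other <- split_by_group(ep, "trial", 0.22, seed = 6)
  expect_false(identical(other$test$provenance, parts$test$provenance))
  # a single group cannot be split
  one <- ep[paste(ep$provenance$session, ep$provenance$trial) == "1 1"]
  expect_error(split_by_group(one, "trial", 0.5, seed = 1), "at least 2")
})
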