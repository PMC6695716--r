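test_that("ECG conditioning removes DC and mains while passing the QRS band", {
  fs <- 200
  t <- (0:5999) / fs
  # constant input decays to zero after the high-pass transient
  y <- condition_ecg(as_signal(rep(1, 6000), fs, unit = "millivolt"))$value
  expect_lt(max(abs(tail(y, 1000))), 1e-3)
  steady <- 2001:6000
  amp <- function(f) {
    x <- as_signal(sin(2 * pi * f * t), fs, unit = "millivolt")
    diff(range(condition_ecg(x)$value[steady])) / 2
  }
  expect_gt(amp(10), 10^(-1 / 20))      # within 1 dB at 10 Hz
  expect_lt(amp(10), 10^(1 / 20))
  expect_lt(amp(50), 10^(-20 / 20))     # >= 20 dB down at mains frequency
  expect_error(condition_ecg(as_signal(rnorm(100), 100, unit = "millivolt")),
               "sampling rate")
})

test_that("baseline estimation tracks wander and nothing else", {
  clean <- gen_ecg(hr_bpm = 60, noise_amp = 0, wander_amp = 0, seed = 3)
  b0 <- estimate_baseline(clean$signal)$value
  expect_lt(max(abs(b0)), 0.05)  # < 5% of the 1 mV R amplitude
  w <- gen_ecg(hr_bpm = 60, noise_amp = 0, wander_amp = 0.5,
               wander_freq_hz = 0.3, seed = 3)
  wander <- 0.5 * sin(2 * pi * 0.3 * w$signal$time_s)
  expect_gt(cor(estimate_baseline(w$signal)$value, wander), 0.95)
  const <- as_signal(rep(2.5, 2000), 200, unit = "millivolt")
  expect_equal(estimate_baseline(const)$value, rep(2.5, 2000))
})

test_that("QRS detection finds every clean beat and nothing else", {
  tol <- round(0.04 * 200)  # 40 ms
  for (hr in c(45, 60, 100, 150)) {
    e <- gen_ecg(hr_bpm = hr, seed = 2)
    q <- ecg_heart_rate(e$signal)
    m <- match_peaks(e$r_peaks, q$r_peaks, tol)
    expect_equal(m$miss, 0, info = sprintf("hr %d", hr))
    expect_equal(m$fp, 0, info = sprintf("hr %d", hr))
    expect_true(all(diff(q$r_peaks) >= 0.2 * 200))
    expect_equal(60 * q$fs / median(q$rr_intervals), hr, tolerance = 0.05)
  }
  # tall T waves must not double-fire the detector
  et <- gen_ecg(hr_bpm = 60, t_amp = 0.6, seed = 5)
  qt <- ecg_heart_rate(et$signal)
  expect_length(qt$r_peaks, length(et$r_peaks))
  # flat input: no beats, no error
  flat <- as_signal(rep(0, 2000), 200, unit = "millivolt")
  expect_length(detect_qrs(flat)$r_peaks, 0)
  expect_error(detect_qrs(as_signal(rnorm(100), 200, unit = "millivolt")),
               class = "coilrate_range")
})

test_that("QRS durations are physiological on synthetic beats", {
  e <- gen_ecg(hr_bpm = 60, seed = 2)
  q <- ecg_heart_rate(e$signal)
  expect_true(all(q$qrs_durations_ms > 20))
  expect_true(all(q$qrs_durations_ms < 160))
  expect_false(check_qrs_duration(q$qrs_durations_ms))
})

test_that("RR intervals convert to a bpm series", {
  q <- structure(list(r_peaks = seq(1L, 2001L, by = 200L),
                      rr_intervals = rep(200, 10),
                      qrs_durations_ms = rep(80, 11), fs = 200, n = 2200),
                 class = "qrs_result")
  bp <- rr_to_bpm(q)
  expect_equal(bp$bpm, rep(60, 10))
  q2 <- structure(list(r_peaks = c(1L, 101L, 201L), rr_intervals = c(100, 100),
                       qrs_durations_ms = rep(80, 3), fs = 200, n = 300),
                  class = "qrs_result")
  expect_equal(rr_to_bpm(q2)$bpm, c(120, 120))
  e <- gen_ecg(hr_bpm = 80, rr_jitter_ms = 15, seed = 6)
  q3 <- ecg_heart_rate(e$signal)
  expect_equal(mean(rr_to_bpm(q3)$bpm), 80, tolerance = 2)
  q4 <- q2; q4$r_peaks <- 1L
  expect_error(rr_to_bpm(q4), class = "coilrate_range")
})

test_that("windowed ECG rate pairs with the inductive window grid", {
  e <- gen_ecg(hr_bpm = 72, seed = 2)
  q <- ecg_heart_rate(e$signal)
  wb <- window_bpm(q, window_s = 15, hop_s = 5, duration_s = 30)
  expect_equal(wb$window_start_s, c(0, 5, 10, 15))
  expect_true(all(abs(wb$bpm - 72) < 2))
})
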