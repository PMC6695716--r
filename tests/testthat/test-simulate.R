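test_that("respiration generator is a seeded quasi-sinusoid at the set period", {
  # 32 s so that 0.25 Hz falls exactly on an FFT bin
  sc <- inductive_scenario(duration_s = 32, resp_period_s = 4, jitter = 0,
                           seed = 1)
  r <- gen_respiration(sc)
  expect_equal(dominant_freq(r$value, sc$fs), 0.25)
  expect_identical(gen_respiration(sc)$value, r$value)
  # a hold covering the whole recording silences the channel
  sch <- inductive_scenario(breath_hold = c(0, 30), seed = 1)
  expect_lt(max(abs(gen_respiration(sch)$value)), 1e-12)
  expect_error(inductive_scenario(breath_hold = c(10, 40)),
               class = "coilrate_range")
  expect_error(inductive_scenario(resp_amp = 1e-4, cardiac_amp = 2e-4),
               "resp_amp")
})

test_that("cardiac pulse train beats at the requested rate", {
  sc <- inductive_scenario(duration_s = 10, hr_bpm = 60, seed = 2)
  h <- gen_cardiac(sc)$value
  # count pulse maxima above half amplitude
  above <- h > sc$cardiac_amp / 2
  n_pulses <- sum(diff(c(FALSE, above)) == 1)
  expect_equal(n_pulses, 10)
  # autocorrelation peaks at one beat period
  cxx <- brute_cxx(h - mean(h), 30)
  k <- 2:30
  peaks <- k[cxx[k + 1] > cxx[k] & cxx[k + 1] >= cxx[k + 2]]
  expect_equal(peaks[which.max(cxx[peaks + 1])], 20)  # fs * 60 / hr
  # amplitude scales linearly
  sc2 <- inductive_scenario(duration_s = 10, hr_bpm = 60, seed = 2,
                            cardiac_amp = 4e-4, resp_amp = 5e-3)
  expect_equal(gen_cardiac(sc2)$value, 2 * h, tolerance = 1e-12)
  expect_error(gen_cardiac(inductive_scenario(hr_bpm = 200, pulse_sigma_s = 0.06)),
               class = "coilrate_range")
})

test_that("composite stream stays within noise + quantization of its parts", {
  for (pressed in c(TRUE, FALSE)) {
    sc <- inductive_scenario(pressed = pressed, seed = 6)
    s <- gen_inductive(sc)
    expect_identical(gen_inductive(sc)$value, s$value)  # deterministic
    truth <- gen_respiration(sc)$value + gen_cardiac(sc)$value
    l <- dequantize_counts(s, sc$full_scale)$value
    disp <- (sc$baseline_h - l) / sc$sensitivity_h_per_m
    lsb_m <- diff(sc$full_scale) / 65535 / sc$sensitivity_h_per_m
    expect_true(all(abs(disp - truth) <= sc$noise_amp + lsb_m))
  }
  pressed <- gen_inductive(inductive_scenario(pressed = TRUE, seed = 6))
  unpressed <- gen_inductive(inductive_scenario(pressed = FALSE, seed = 6))
  expect_gt(var(unpressed$value), var(pressed$value))
})

test_that("noise-free scenario reduces to the quantized cardiac train", {
  sc <- inductive_scenario(noise_amp = 0, resp_amp = 1e-6, cardiac_amp = 5e-7,
                           seed = 3)
  # respiration forced (near) zero via breath hold over the whole recording
  sc$breath_hold <- c(0, sc$duration_s)
  s <- gen_inductive(sc)
  l <- dequantize_counts(s, sc$full_scale)$value
  disp <- (sc$baseline_h - l) / sc$sensitivity_h_per_m
  lsb_m <- diff(sc$full_scale) / 65535 / sc$sensitivity_h_per_m
  expect_true(all(abs(disp - gen_cardiac(sc)$value) <= lsb_m))
})

test_that("synthetic ECG has the promised beat grid and amplitudes", {
  e <- gen_ecg(duration_s = 30, fs = 200, hr_bpm = 60, seed = 1)
  expect_length(e$r_peaks, 30)
  expect_true(all(diff(e$r_peaks) == 200))  # fs * 60 / hr samples
  clean <- gen_ecg(hr_bpm = 60, noise_amp = 0, wander_amp = 0, seed = 1)
  # R samples carry the template maximum (1 mV)
  expect_equal(unname(clean$signal$value[clean$r_peaks]),
               rep(1, length(clean$r_peaks)), tolerance = 0.02)
  expect_equal(max(clean$signal$value),
               max(clean$signal$value[clean$r_peaks]), tolerance = 0.02)
  jit <- gen_ecg(hr_bpm = 75, rr_jitter_ms = 20, seed = 4)
  expect_equal(mean(60 * 200 / diff(jit$r_peaks)), 75, tolerance = 2)
  expect_error(gen_ecg(qrs_width_ms = 250), "qrs_width_ms")
  expect_error(gen_ecg(hr_bpm = 30), "hr_bpm")
})
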