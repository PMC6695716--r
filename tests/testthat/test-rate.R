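test_that("autocorrelation follows the printed definition", {
  imp <- c(1, rep(0, 9))
  expect_equal(autocorrelation(imp, 5), c(1, rep(0, 5)))
  set.seed(2)
  d <- rnorm(50)
  expect_equal(autocorrelation(d, 10)[1], sum(d^2))
  # sinusoid of period 20 samples: maxima at multiples of 20
  x <- sin(2 * pi * (0:199) / 20)
  cxx <- autocorrelation(x, 45)
  k <- 2:44
  peaks <- k[cxx[k + 1] > cxx[k] & cxx[k + 1] >= cxx[k + 2]]
  expect_equal(peaks, c(20, 40))
  expect_error(autocorrelation(numeric(0), 5), class = "coilrate_empty")
})

test_that("lag bounds encode the 40-200 bpm range", {
  expect_equal(unname(lag_bounds(20)), c(6, 30))
  expect_equal(unname(lag_bounds(200)), c(60, 300))
  expect_error(lag_bounds(20, 100, 100), class = "coilrate_range")
  expect_error(lag_bounds(20, 200, 40), class = "coilrate_range")
  # bounds collapse at a very low sampling rate
  expect_error(lag_bounds(1.5), class = "coilrate_range")
})

test_that("period picking takes the highest in-band local maximum", {
  x <- sin(2 * pi * (0:299) / 20)
  cxx <- autocorrelation(x, 31)
  expect_equal(estimate_period(cxx, 6, 30), 20L)
  # monotone decay: no local maximum in range
  expect_true(is.na(estimate_period(exp(-(0:32) / 5), 6, 30)))
  # equal peaks: smaller lag wins
  c2 <- rep(0, 33)
  c2[c(11, 21)] <- 5  # lags 10 and 20
  expect_equal(estimate_period(c2, 6, 30), 10L)
  expect_error(estimate_period(cxx[1:20], 6, 30), class = "coilrate_range")
})

test_that("period converts to bpm by 60 f_s / T", {
  expect_equal(bpm_from_period(20, 20), 60)
  expect_equal(bpm_from_period(30, 20), 40)   # slowest admissible rate
  expect_equal(bpm_from_period(6, 20), 200)   # fastest admissible rate
  expect_error(bpm_from_period(0, 20))
})

test_that("windowed estimation recovers the rate and flags what it cannot", {
  sc <- inductive_scenario(hr_bpm = 72, seed = 3)
  s <- gen_inductive(sc)
  r <- estimate_heart_rate(s, window_s = 15, hop_s = 5)
  expect_s3_class(r, "hr_report")
  expect_true(all(r$valid))
  expect_true(all(abs(r$bpm - 72) <= 10))
  expect_true(all(r$window_end_s - r$window_start_s == 15))
  # estimates are invariant to amplitude scaling and constant offsets
  scaled <- as_signal(3 * s$value + 1000, fs = 20, unit = "counts")
  r2 <- estimate_heart_rate(scaled, window_s = 15, hop_s = 5)
  expect_equal(r2$bpm, r$bpm)
  expect_equal(r2$period_samples, r$period_samples)
  expect_error(estimate_heart_rate(s, window_s = 2), class = "coilrate_range")
  expect_error(estimate_heart_rate(s, window_s = 60), class = "coilrate_range")
})

test_that("parameter recovery holds across the heart-rate / breathing grid", {
  for (hr in c(48, 120)) {
    for (rp in c(3, 5)) {
      sc <- inductive_scenario(hr_bpm = hr, resp_period_s = rp, seed = 17)
      r <- estimate_heart_rate(gen_inductive(sc))
      expect_true(all(r$valid), info = sprintf("hr %g rp %g", hr, rp))
      expect_true(all(abs(r$bpm - hr) <= 10), info = sprintf("hr %g rp %g", hr, rp))
    }
  }
})

test_that("respiration rate comes from the low-pass component with guards", {
  lp <- design_lowpass(7, 1, 20)
  sc <- inductive_scenario(resp_period_s = 4, seed = 5)
  xs <- apply_filter(remove_offset(gen_inductive(sc)), lp, init = "steady")
  rr <- estimate_respiration_rate(xs)
  expect_true(rr$valid)
  expect_equal(rr$resp_bpm, 15, tolerance = 0.06)  # one lag quantum at T = 80
  # breath-hold-only: no respiratory periodicity to report
  sch <- inductive_scenario(breath_hold = c(0, 30), seed = 6)
  xh <- apply_filter(remove_offset(gen_inductive(sch)), lp, init = "steady")
  expect_false(estimate_respiration_rate(xh)$valid)
  # pure cardiac input: dominant component is out of the respiration band
  scc <- inductive_scenario(hr_bpm = 60, seed = 7)
  cardio <- as_signal(gen_cardiac(scc)$value, fs = 20, unit = "meter")
  xc <- apply_filter(remove_offset(cardio), lp, init = "steady")
  expect_false(estimate_respiration_rate(xc)$valid)
})

test_that("breathing and breath-hold halves give consistent heart rate", {
  sc <- inductive_scenario(hr_bpm = 72, breath_hold = c(15, 30), seed = 4)
  r <- estimate_heart_rate(gen_inductive(sc), window_s = 15, hop_s = 15)
  expect_true(all(r$valid))
  expect_lte(abs(r$bpm[1] - r$bpm[2]), 10)
  # respiration is reported while breathing, flagged during the hold
  expect_true(r$resp_valid[1])
  expect_false(r$resp_valid[2])
})

test_that("report export writes the windowed CSV", {
  sc <- inductive_scenario(seed = 2)
  r <- estimate_heart_rate(gen_inductive(sc))
  path <- withr::local_tempfile(fileext = ".csv")
  write_hr_report(r, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(r))
  expect_equal(back$bpm, r$bpm)
})
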