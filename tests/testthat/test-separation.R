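test_that("cross-correlation and AMDF match their definitions", {
  fs <- 20
  imp0 <- c(1, rep(0, 9))
  expect_equal(cross_correlation(imp0, imp0, 5), c(1, rep(0, 5)))
  # impulses at indices 3 and 4 (0-based 2 and 3): best lag is 1
  s <- rep(0, 10); s[3] <- 1
  st <- rep(0, 10); st[4] <- 1
  cxy <- cross_correlation(s, st, 6)
  expect_equal(which.max(cxy) - 1L, 1L)
  expect_equal(cxy[1], sum(s * st))
  expect_equal(amdf(s, s, 5)[1], 0)
  expect_true(all(amdf(s, st, 6) >= 0))
  # shifted copy: AMDF minimum at the shift (lag-4 overlap is exact)
  set.seed(8)
  x <- rnorm(60)
  y <- c(rep(x[1], 4), x[1:56])
  expect_equal(which.min(amdf(x, y, 10)) - 1L, 4L)
  expect_error(cross_correlation(1:5, 1:6, 2), class = "coilrate_length")
  expect_error(amdf(1:5, 1:5, 5), class = "coilrate_range")
})

test_that("vectorized lag functions equal brute-force double loops", {
  set.seed(13)
  for (i in 1:5) {
    x <- rnorm(200); y <- rnorm(200)
    expect_equal(cross_correlation(x, y, 40), brute_cxy(x, y, 40),
                 tolerance = 1e-12)
    expect_equal(amdf(x, y, 40), brute_dxy(x, y, 40), tolerance = 1e-12)
    expect_equal(autocorrelation(x, 40), brute_cxx(x, 40), tolerance = 1e-12)
  }
})

test_that("delay estimation recovers known shifts and reports residuals", {
  fs <- 20
  set.seed(21)
  x <- sin(2 * pi * 0.25 * (0:199) / fs) + 0.1 * rnorm(200)
  sx <- as_signal(x, fs)
  # no delay: offset 0, difference identically zero
  al0 <- estimate_delay(sx, sx, 40)
  expect_equal(al0$chosen_offset, 0L)
  expect_equal(max(abs(al0$d$value)), 0)
  # known integer delay, noiseless overlap
  k0 <- 7L
  y <- c(rep(x[1], k0), x[1:(200 - k0)])
  al <- estimate_delay(sx, as_signal(y, fs), 40)
  expect_equal(al$offset_amdf, k0)
  expect_equal(al$offset_corr, k0)
  expect_equal(al$chosen_offset, k0)
  expect_lt(mean(abs(al$d$value)), 0.05)
  expect_equal(nrow(al$d), 200 - k0)
  expect_error(estimate_delay(sx, sx, 250), class = "coilrate_range")
})

test_that("estimated delay matches the filter group delay on synthetic data", {
  lp <- design_lowpass(7, 1, 20)
  sc <- inductive_scenario(hr_bpm = 72, resp_period_s = 4, seed = 9)
  x0 <- remove_offset(gen_inductive(sc))
  xs <- apply_filter(x0, lp, init = "steady")
  al <- estimate_delay(x0, xs, 40)
  gd <- filter_group_delay(lp, 1 / sc$resp_period_s)
  expect_lte(abs(al$chosen_offset - gd), 2)
})

test_that("subtracting the aligned respiration leaves a rate-readable cardiac signal", {
  # noiseless composites across the physiologic range: recovered rate is
  # limited only by lag quantization
  lp <- design_lowpass(7, 1, 20)
  bounds <- lag_bounds(20)
  for (hr in c(45, 60, 90, 120, 180)) {
    sc <- inductive_scenario(hr_bpm = hr, noise_amp = 0, seed = 2)
    x0 <- remove_offset(gen_inductive(sc))
    xs <- apply_filter(x0, lp, init = "steady")
    al <- estimate_delay(x0, xs, 40)
    cxx <- autocorrelation(al$d, bounds[["t_max"]] + 1L)
    per <- estimate_period(cxx, bounds[["t_min"]], bounds[["t_max"]])
    expect_false(is.na(per))
    t_true <- 60 * 20 / hr
    quantum <- abs(bpm_from_period(floor(t_true), 20) -
                     bpm_from_period(floor(t_true) + 1, 20))
    expect_lte(abs(bpm_from_period(per, 20) - hr), quantum + 1e-9)
  }
  # the respiration fundamental is strongly attenuated in d
  sc <- inductive_scenario(hr_bpm = 72, seed = 9)
  x0 <- remove_offset(gen_inductive(sc))
  xs <- apply_filter(x0, lp, init = "steady")
  al <- estimate_delay(x0, xs, 40)
  n <- nrow(al$d)
  spec_of <- function(v) Mod(stats::fft(v - mean(v)))[seq_len(floor(n / 2)) + 1]
  f <- seq_len(floor(n / 2)) / n * 20
  resp_band <- f > 0.15 & f < 0.35
  raw_peak <- max(spec_of(x0$value[seq_len(n)])[resp_band])
  d_peak <- max(spec_of(al$d$value)[resp_band])
  expect_lt(d_peak, raw_peak / 10)
})
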