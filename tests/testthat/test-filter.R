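test_that("low-pass design has unit DC gain and half-power at the cutoff", {
  lp <- design_lowpass(7, 1, 20)
  expect_equal(length(lp$b), 8L)
  expect_equal(lp$a[1], 1)
  expect_lt(abs(sum(lp$b) / sum(lp$a) - 1), 1e-6)
  expect_equal(filter_magnitude(lp, 0), 1, tolerance = 1e-9)
  expect_equal(filter_magnitude(lp, 1), 1 / sqrt(2), tolerance = 1e-3)
  # stop-band: an octave above cutoff the analog prototype predicts
  # 1/sqrt(1 + 2^14) ~ 7.8e-3; the digital design must be at least that sharp
  expect_lt(filter_magnitude(lp, 2), 0.01)
  expect_error(design_lowpass(7, 10, 20), class = "coilrate_nyquist")
  expect_error(design_lowpass(7, 12, 20), class = "coilrate_nyquist")
})

test_that("magnitude response is monotonically non-increasing (maximal flatness)", {
  for (ord in c(2L, 4L, 7L)) {
    lp <- design_lowpass(ord, 1, 20)
    f <- seq(0, 10, length.out = 2000)
    mag <- filter_magnitude(lp, f)
    expect_true(all(diff(mag) <= 1e-9))
    # strictly decreasing beyond the cutoff
    beyond <- mag[f > 1 & f < 9.9]
    expect_true(all(diff(beyond) < 0))
  }
})

test_that("filtering matches the brute-force difference equation exactly", {
  lp <- design_lowpass(7, 1, 20)
  set.seed(7)
  for (i in 1:5) {
    x <- rnorm(100)
    got <- apply_filter(as_signal(x, 20), lp)$value
    expect_equal(got, brute_arma(lp$b, lp$a, x), tolerance = 1e-12)
  }
})

test_that("filter preserves DC and nullifies the zero signal", {
  lp <- design_lowpass(7, 1, 20)
  expect_equal(apply_filter(as_signal(rep(0, 50), 20), lp)$value, rep(0, 50))
  # constant input converges to the same constant (unity DC gain)
  y <- apply_filter(as_signal(rep(3.5, 400), 20), lp)$value
  expect_equal(tail(y, 50), rep(3.5, 50), tolerance = 1e-6)
  # impulse response accumulates to the DC gain
  imp <- c(1, rep(0, 399))  # 20 s at 20 Hz
  expect_equal(sum(apply_filter(as_signal(imp, 20), lp)$value), 1,
               tolerance = 1e-3)
})

test_that("steady-state initialization removes the start-up step swing", {
  lp <- design_lowpass(7, 1, 20)
  # constant input passes through untouched from the first sample
  y <- apply_filter(as_signal(rep(2.5, 60), 20), lp, init = "steady")$value
  expect_equal(y, rep(2.5, 60), tolerance = 1e-9)
  # equivalent to zero-state filtering of the deviation from the first sample
  set.seed(11)
  x <- cumsum(rnorm(80)) + 10
  ys <- apply_filter(as_signal(x, 20), lp, init = "steady")$value
  yz <- apply_filter(as_signal(x - x[1], 20), lp)$value + x[1]
  expect_equal(ys, yz, tolerance = 1e-12)
})

test_that("half-power search and group delay agree with the design", {
  lp <- design_lowpass(7, 1, 20)
  hp <- half_power_frequency(lp)
  expect_equal(hp$f_hz, 1, tolerance = 1e-6)
  gd <- filter_group_delay(lp, 0.25)
  expect_gt(gd, 0)
  # recursive part induces a delay of several samples at the respiration
  # frequency
  expect_gt(gd, 5)
  expect_lt(gd, 40)
})
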