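#' Design the respiration-extraction low-pass filter
#'
#' Digital Butterworth low-pass used to pull the respiration component out of
#' the raw inductive stream. The defaults are the chain's standard settings:
#' order 7, 1 Hz cut-off at a 20 Hz sampling rate. The feed-forward
#' coefficients are rescaled so the DC gain is exactly 1.
#'
#' @param order Filter order M (>= 1).
#' @param cutoff_hz Half-power (-3 dB) frequency in Hz; must lie strictly
#'   below the Nyquist frequency `fs_hz / 2`.
#' @param fs_hz Sampling rate in Hz.
#' @return An object of class `lowpass_filter`: list with feed-forward `b`
#'   and recursive `a` coefficient vectors (length `order + 1`, `a[1] == 1`),
#'   plus `order`, `cutoff_hz`, `fs_hz`.
#' @examples
#' lp <- design_lowpass(7, 1, 20)
#' filter_magnitude(lp, c(0, 1, 2))
#' @export
design_lowpass <- function(order = 7L, cutoff_hz = 1, fs_hz = 20) {
  if (order < 1L) abort("`order` must be >= 1")
  if (!(cutoff_hz > 0 && cutoff_hz < fs_hz / 2)) {
    abort("`cutoff_hz` must lie in (0, fs/2): cutoff at or above Nyquist",
          class = "coilrate_nyquist")
  }
  bt <- signal::butter(order, cutoff_hz / (fs_hz / 2), type = "low")
  b <- as.numeric(bt$b)
  a <- as.numeric(bt$a)
  b <- b / (sum(b) / sum(a))  # pin DC gain to exactly 1
  structure(
    list(b = b, a = a, order = as.integer(order),
         cutoff_hz = cutoff_hz, fs_hz = fs_hz),
    class = "lowpass_filter"
  )
}

#' @export
print.lowpass_filter <- function(x, ...) {
  cat(sprintf("<lowpass_filter> Butterworth order %d, cutoff %g Hz @ fs %g Hz\n",
              x$order, x$cutoff_hz, x$fs_hz))
  invisible(x)
}

#' Apply an ARMA (IIR) filter to a signal
#'
#' Runs the direct-form difference equation causally (direct-form II
#' transposed realization). The recursive part introduces a group delay that
#' the separation step compensates downstream. With `init = "zero"` the
#' filter starts from zero initial conditions; `init = "steady"` starts it
#' from the steady state for the first sample's level, which suppresses the
#' start-up swing when filtering short analysis windows of a signal with a
#' large slow component.
#'
#' @param s A `coil_signal` tibble.
#' @param coefs A `lowpass_filter` (or any list with `b` and `a`).
#' @param init `"zero"` or `"steady"` initial conditions.
#' @return Filtered signal, same length and sampling rate.
#' @export
apply_filter <- function(s, coefs, init = c("zero", "steady")) {
  init <- match.arg(init)
  v <- sig_values(s)
  if (init == "steady") {
    # response with steady-state ICs for level v[1]: by linearity the
    # constant part passes unchanged (unity DC gain) and only the deviation
    # from it is filtered from rest
    y <- v[1] + as.numeric(signal::filter(coefs$b, coefs$a, v - v[1]))
  } else {
    y <- as.numeric(signal::filter(coefs$b, coefs$a, v))
  }
  sig_rewrap(s, y)
}

#' Frequency response helpers
#'
#' `filter_magnitude()` evaluates the magnitude response |H(f)| of the
#' designed filter at arbitrary frequencies; `half_power_frequency()` locates
#' the frequency where the response crosses 1/sqrt(2) of the DC gain, by a
#' fine grid scan refined with root bisection.
#'
#' @param coefs A `lowpass_filter`.
#' @param f_hz Numeric vector of frequencies (Hz).
#' @return `filter_magnitude()`: numeric vector of gains.
#' @export
filter_magnitude <- function(coefs, f_hz) {
  k <- 0:(length(coefs$b) - 1)
  j <- 0:(length(coefs$a) - 1)
  vapply(f_hz, function(f) {
    w <- 2 * pi * f / coefs$fs_hz
    num <- sum(coefs$b * exp(-1i * w * k))
    den <- sum(coefs$a * exp(-1i * w * j))
    Mod(num / den)
  }, numeric(1))
}

#' @rdname filter_magnitude
#' @param n_grid Number of grid points over (0, fs/2) for the initial scan.
#' @return `half_power_frequency()`: list with `f_hz` (the -3 dB frequency)
#'   and `n_grid`.
#' @export
half_power_frequency <- function(coefs, n_grid = 20000L) {
  target <- filter_magnitude(coefs, 0) / sqrt(2)
  f <- seq(0, coefs$fs_hz / 2, length.out = n_grid + 1L)[-1L]
  g <- filter_magnitude(coefs, f) - target
  i <- which(g <= 0)[1L]
  if (is.na(i) || i == 1L) abort("no half-power crossing found on the grid")
  root <- uniroot(function(x) filter_magnitude(coefs, x) - target,
                  lower = f[i - 1L], upper = f[i], tol = 1e-10)
  list(f_hz = root$root, n_grid = n_grid)
}

#' Group delay of a filter at a given frequency
#'
#' Numerical derivative of the phase response; used to sanity-check the lag
#' found by the correlation/AMDF alignment step.
#'
#' @param coefs A `lowpass_filter`.
#' @param f_hz Frequency in Hz.
#' @return Group delay in samples.
#' @export
filter_group_delay <- function(coefs, f_hz) {
  df <- coefs$fs_hz * 1e-7
  h <- function(f) {
    k <- 0:(length(coefs$b) - 1)
    j <- 0:(length(coefs$a) - 1)
    w <- 2 * pi * f / coefs$fs_hz
    sum(coefs$b * exp(-1i * w * k)) / sum(coefs$a * exp(-1i * w * j))
  }
  # phase increment over 2*df, wrap-free because the step is tiny
  dphi <- Arg(h(f_hz + df) * Conj(h(f_hz - df)))
  -dphi / (2 * pi * 2 * df) * coefs$fs_hz
}
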