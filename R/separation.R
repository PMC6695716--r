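#' Cross-correlation and AMDF between a signal and its filtered version
#'
#' Raw (unnormalized) one-sided cross-correlation
#' `CXY[k] = sum_n s[n] * sstar[n + k]` and average magnitude difference
#' function `DXY[k] = sum_n |s[n] - sstar[n + k]|`, for lags `k = 0..max_lag`.
#' The causal low-pass delays its output, so the lag at which `CXY` peaks
#' (equivalently `DXY` dips) estimates the filtering delay.
#'
#' @param s,sstar Signals (tibbles or numeric vectors) of equal length.
#' @param max_lag Largest lag to evaluate, `0 < max_lag < N`.
#' @return Numeric vector of length `max_lag + 1` (element 1 is lag 0).
#' @export
cross_correlation <- function(s, sstar, max_lag) {
  xy <- align_args(s, sstar, max_lag)
  with(xy, vapply(0:max_lag, function(k) {
    sum(x[seq_len(n - k)] * y[seq_len(n - k) + k])
  }, numeric(1)))
}

#' @rdname cross_correlation
#' @export
amdf <- function(s, sstar, max_lag) {
  xy <- align_args(s, sstar, max_lag)
  with(xy, vapply(0:max_lag, function(k) {
    sum(abs(x[seq_len(n - k)] - y[seq_len(n - k) + k]))
  }, numeric(1)))
}

align_args <- function(s, sstar, max_lag) {
  x <- sig_values(s)
  y <- sig_values(sstar)
  if (length(x) != length(y)) {
    abort("signals must have equal length", class = "coilrate_length")
  }
  n <- length(x)
  if (!(max_lag > 0 && max_lag < n)) {
    abort("`max_lag` must satisfy 0 < max_lag < N", class = "coilrate_range")
  }
  list(x = x, y = y, n = n, max_lag = as.integer(max_lag))
}

#' Estimate the filtering delay and form the cardiac difference signal
#'
#' Runs both lag estimators — the AMDF global minimum and the correlation
#' global maximum — then keeps whichever candidate leaves the smaller mean
#' absolute residual between the raw signal and the shift-compensated
#' filtered signal. The aligned difference
#' `d[n] = s[n] - sstar[n + offset]` removes the respiration component and
#' keeps the cardiac one.
#'
#' @inheritParams cross_correlation
#' @return Object of class `delay_alignment`: `offset_amdf`, `offset_corr`,
#'   residuals `d1` (AMDF candidate) and `d2` (correlation candidate),
#'   `chosen_offset`, `method`, and the difference signal `d` (length
#'   `N - chosen_offset`).
#' @export
estimate_delay <- function(s, sstar, max_lag) {
  xy <- align_args(s, sstar, max_lag)
  cxy <- cross_correlation(s, sstar, max_lag)
  dxy <- amdf(s, sstar, max_lag)
  off_amdf <- which.min(dxy) - 1L
  off_corr <- which.max(cxy) - 1L
  resid_at <- function(off) {
    i <- seq_len(xy$n - off)
    mean(abs(xy$x[i] - xy$y[i + off]))
  }
  d1 <- resid_at(off_amdf)
  d2 <- resid_at(off_corr)
  if (d1 < d2) {
    chosen <- off_amdf; method <- "amdf"
  } else {
    chosen <- off_corr; method <- "correlation"
  }
  i <- seq_len(xy$n - chosen)
  fs <- if (is.data.frame(s)) signal_fs(s) else 1
  d <- as_signal(xy$x[i] - xy$y[i + chosen], fs = fs, unit = "adimensional")
  structure(
    list(offset_amdf = off_amdf, offset_corr = off_corr,
         d1 = d1, d2 = d2, chosen_offset = chosen, method = method,
         d = d, cxy = cxy, dxy = dxy),
    class = "delay_alignment"
  )
}

#' @export
print.delay_alignment <- function(x, ...) {
  cat(sprintf(
    "<delay_alignment> offset %d samples (%s; amdf %d / corr %d, residuals %.4g / %.4g)\n",
    x$chosen_offset, x$method, x$offset_amdf, x$offset_corr, x$d1, x$d2))
  invisible(x)
}

#' @export
tidy.delay_alignment <- function(x, ...) {
  tibble(offset_amdf = x$offset_amdf, offset_corr = x$offset_corr,
         resid_amdf = x$d1, resid_corr = x$d2,
         chosen_offset = x$chosen_offset, method = x$method)
}
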