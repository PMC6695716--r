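#' Raw autocorrelation of the cardiac difference signal
#'
#' `CXX[k] = sum_n d[n] * d[n + k]` for `k = 0..max_lag`; `CXX[1]` (lag 0)
#' is the signal energy.
#'
#' @param d Signal (tibble or numeric vector).
#' @param max_lag Largest lag, `0 < max_lag < length(d)`.
#' @return Numeric vector of length `max_lag + 1`.
#' @export
autocorrelation <- function(d, max_lag) {
  x <- sig_values(d)
  if (length(x) < 1L) abort("empty signal", class = "coilrate_empty")
  n <- length(x)
  if (!(max_lag > 0 && max_lag < n)) {
    abort("`max_lag` must satisfy 0 < max_lag < N", class = "coilrate_range")
  }
  vapply(0:max_lag, function(k) {
    sum(x[seq_len(n - k)] * x[seq_len(n - k) + k])
  }, numeric(1))
}

#' Physiologic lag bounds for the period search
#'
#' Converts the admissible heart-rate range into autocorrelation lag bounds:
#' `Tmin = round(60 / bpm_max * fs)`, `Tmax = round(60 / bpm_min * fs)`.
#' At 20 Hz with the default 40-200 bpm range this is (6, 30) samples.
#'
#' @param fs Sampling rate (Hz).
#' @param bpm_min,bpm_max Heart-rate search range in beats per minute.
#' @return Named numeric vector `c(t_min = ..., t_max = ...)` (samples).
#' @export
lag_bounds <- function(fs, bpm_min = 40, bpm_max = 200) {
  if (!(fs > 0)) abort("`fs` must be positive")
  if (!(bpm_min > 0 && bpm_min < bpm_max)) {
    abort("need 0 < bpm_min < bpm_max", class = "coilrate_range")
  }
  t_min <- round(60 / bpm_max * fs)
  t_max <- round(60 / bpm_min * fs)
  if (t_min < 1 || t_min >= t_max) {
    abort("lag bounds collapse at this sampling rate", class = "coilrate_range")
  }
  c(t_min = t_min, t_max = t_max)
}

#' Period of the strongest in-band autocorrelation peak
#'
#' Scans `CXX` for local maxima (`CXX[k] > CXX[k-1]` and `CXX[k] >= CXX[k+1]`)
#' with `t_min <= k <= t_max` and returns the lag of the highest one; ties go
#' to the smaller lag. `NA` when no local maximum lies in range (the caller
#' flags the window invalid rather than failing).
#'
#' @param cxx Autocorrelation vector from [autocorrelation()] (lag 0 first);
#'   must extend to at least `t_max + 1`.
#' @param t_min,t_max Lag bounds in samples (see [lag_bounds()]).
#' @return Integer period in samples, or `NA_integer_`.
#' @export
estimate_period <- function(cxx, t_min, t_max) {
  if (t_max + 2L > length(cxx)) {
    abort("`cxx` must extend to lag t_max + 1", class = "coilrate_range")
  }
  k <- seq.int(t_min, t_max)
  i <- k + 1L  # vector index of lag k
  is_peak <- cxx[i] > cxx[i - 1L] & cxx[i] >= cxx[i + 1L]
  if (!any(is_peak)) return(NA_integer_)
  cand <- k[is_peak]
  as.integer(cand[which.max(cxx[cand + 1L])])
}

#' Subharmonic-aware period selection
#'
#' The admissible 40-200 bpm lag range spans a fivefold ratio, so for fast
#' rates it necessarily contains the doubled and tripled beat period, whose
#' autocorrelation peaks can rival the true one (an integer multiple of a
#' fractional period is sampled more coherently than the rounded period
#' itself). `estimate_period_robust()` therefore (a) removes the slow
#' envelope of `CXX` with a running-median baseline, so that residual
#' low-frequency leakage cannot bias the comparison, and (b) among the
#' in-band local maxima takes the *earliest* lag whose detrended height
#' reaches `alpha` of the best one — the standard pitch-halving correction.
#' Candidate peaks are the same local maxima [estimate_period()] uses.
#'
#' @inheritParams estimate_period
#' @param alpha Fraction of the strongest detrended peak a smaller lag must
#'   reach to be preferred.
#' @param baseline_half Half-width (lags) of the running-median baseline.
#' @return Integer period in samples, or `NA_integer_`.
#' @export
estimate_period_robust <- function(cxx, t_min, t_max, alpha = 0.8,
                                   baseline_half = 5L) {
  if (t_max + baseline_half + 2L > length(cxx)) {
    abort("`cxx` must extend to lag t_max + baseline_half + 1",
          class = "coilrate_range")
  }
  base <- stats::runmed(cxx, 2L * baseline_half + 1L, endrule = "median")
  det <- cxx - base
  k <- seq.int(t_min, t_max)
  i <- k + 1L
  is_peak <- cxx[i] > cxx[i - 1L] & cxx[i] >= cxx[i + 1L]
  if (!any(is_peak)) return(NA_integer_)
  cand <- k[is_peak]
  best <- max(det[cand + 1L])
  if (best <= 0) return(as.integer(cand[which.max(det[cand + 1L])]))
  as.integer(cand[det[cand + 1L] >= alpha * best][1L])
}

#' Convert a period in samples to beats per minute
#'
#' `bpm = 60 / T * fs`.
#'
#' @param period_samples Period T in samples (>= 1).
#' @param fs Sampling rate (Hz).
#' @return Rate in beats (or breaths) per minute.
#' @export
bpm_from_period <- function(period_samples, fs) {
  if (any(period_samples < 1)) abort("period must be >= 1 sample")
  60 / period_samples * fs
}

#' Sliding-window heart-rate estimation from a raw inductive stream
#'
#' Runs the full chain on each analysis window: offset removal, 1 Hz
#' Butterworth low-pass (respiration component), correlation/AMDF delay
#' alignment, aligned difference (cardiac component), autocorrelation, and
#' period-to-bpm conversion within the physiologic lag bounds. Windows where
#' no in-band autocorrelation peak exists are flagged invalid, not dropped.
#' Respiration rate is also estimated per window from the low-pass output
#' when the window is long enough for the 6-30 breaths/min lag range.
#'
#' @param s Raw `coil_signal` (counts).
#' @param window_s,hop_s Analysis window length and hop in seconds. The
#'   window must hold at least `2 * t_max` samples.
#' @param order,cutoff_hz Low-pass design (defaults: order 7, 1 Hz).
#' @param bpm_min,bpm_max Heart-rate search range.
#' @param max_lag_s Delay-search bound in seconds (capped at a third of the
#'   window).
#' @param resp Also estimate respiration rate per window?
#' @return A tibble of class `hr_report`: one row per window with
#'   `window_start_s`, `window_end_s`, `offset`, `period_samples`, `bpm`,
#'   `valid`, `resp_bpm`, `resp_valid`, `method_note`.
#' @examples
#' sc <- inductive_scenario(hr_bpm = 72, seed = 7)
#' estimate_heart_rate(gen_inductive(sc))
#' @export
estimate_heart_rate <- function(s, window_s = 15, hop_s = 5,
                                order = 7L, cutoff_hz = 1,
                                bpm_min = 40, bpm_max = 200,
                                max_lag_s = 2, resp = TRUE) {
  fs <- signal_fs(s)
  v <- sig_values(s)
  bounds <- lag_bounds(fs, bpm_min, bpm_max)
  nw <- round(window_s * fs)
  if (nw < 2 * bounds[["t_max"]]) {
    abort("analysis window shorter than 2 * t_max samples",
          class = "coilrate_range")
  }
  if (nw > length(v)) {
    abort("analysis window longer than the recording", class = "coilrate_range")
  }
  lp <- design_lowpass(order, cutoff_hz, fs)
  # Steps 1-2 once over the whole stream: the filter is time-invariant, so
  # windowed slices of the full-output equal per-window filtering minus the
  # artificial start-up transient each window restart would add
  full0 <- remove_offset(s)
  fullstar <- apply_filter(full0, lp, init = "steady")
  starts <- seq(0L, length(v) - nw, by = max(1L, round(hop_s * fs)))
  rows <- map_dfr(starts, function(i0) {
    idx <- (i0 + 1):(i0 + nw)
    x0 <- as_signal(full0$value[idx], fs = fs, unit = signal_unit(s))
    xstar <- as_signal(fullstar$value[idx], fs = fs, unit = signal_unit(s))
    max_lag <- min(round(max_lag_s * fs), floor(nw / 3))
    al <- estimate_delay(x0, xstar, max_lag)
    res <- window_rate(al$d, bounds)
    rr <- if (resp) estimate_respiration_rate(xstar) else
      tibble(resp_bpm = NA_real_, period_samples = NA_integer_,
             valid = FALSE, note = "disabled")
    tibble(window_start_s = i0 / fs,
           window_end_s = (i0 + nw) / fs,
           offset = al$chosen_offset,
           period_samples = res$period,
           bpm = res$bpm,
           valid = res$valid,
           resp_bpm = rr$resp_bpm,
           resp_valid = rr$valid,
           method_note = paste0("align=", al$method, "; ", res$note))
  })
  attr(rows, "fs") <- fs
  attr(rows, "params") <- list(window_s = window_s, hop_s = hop_s,
                               order = order, cutoff_hz = cutoff_hz,
                               bpm_min = bpm_min, bpm_max = bpm_max)
  class(rows) <- c("hr_report", class(rows))
  rows
}

window_rate <- function(d, bounds) {
  t_max <- bounds[["t_max"]]
  nd <- nrow(d)
  max_lag <- t_max + 6L  # room for the median baseline of the robust picker
  if (nd < max_lag + 2L) {
    return(list(period = NA_integer_, bpm = NA_real_, valid = FALSE,
                note = "window too short after alignment"))
  }
  cxx <- autocorrelation(d, max_lag)
  per <- estimate_period_robust(cxx, bounds[["t_min"]], t_max)
  if (is.na(per)) {
    list(period = NA_integer_, bpm = NA_real_, valid = FALSE,
         note = "no in-band autocorrelation peak")
  } else {
    list(period = per, bpm = bpm_from_period(per, attr(d, "fs")),
         valid = TRUE, note = "ok")
  }
}

#' Respiration rate from the low-pass (respiration) component
#'
#' Applies the same autocorrelation period search to the filtered signal
#' with lag bounds from 6-30 breaths/min. A window is reported valid only if
#' the normalized autocorrelation peak is at least 0.25 and the dominant
#' spectral component of the input lies inside the respiration band — this
#' flags breath-hold windows (no periodicity) and cardiac leakage (dominant
#' component too fast) instead of reporting a spurious rate.
#'
#' @param sstar Low-pass output signal for one analysis window.
#' @param bpm_min,bpm_max Respiration-rate search range (breaths/min).
#' @param min_peak Minimum normalized autocorrelation peak height.
#' @return One-row tibble: `resp_bpm`, `period_samples`, `valid`, `note`.
#' @export
estimate_respiration_rate <- function(sstar, bpm_min = 6, bpm_max = 30,
                                      min_peak = 0.25) {
  fs <- signal_fs(sstar)
  bounds <- lag_bounds(fs, bpm_min, bpm_max)
  t_max <- bounds[["t_max"]]
  x <- sig_values(sstar) - mean(sig_values(sstar))
  invalid <- function(note) tibble(resp_bpm = NA_real_,
                                   period_samples = NA_integer_,
                                   valid = FALSE, note = note)
  if (length(x) < t_max + 2L) return(invalid("window too short"))
  if (all(x == 0)) return(invalid("flat input"))
  cxx <- autocorrelation(x, t_max + 1L)
  per <- estimate_period(cxx, bounds[["t_min"]], t_max)
  if (is.na(per)) return(invalid("no in-band peak"))
  if (cxx[per + 1L] / cxx[1L] < min_peak) return(invalid("weak periodicity"))
  spec <- Mod(fft(x))[seq_len(floor(length(x) / 2)) + 1L]
  f_dom <- which.max(spec) / length(x) * fs
  band <- c(bpm_min, bpm_max) / 60
  if (f_dom < band[1] * 0.8 || f_dom > band[2] * 1.2) {
    return(invalid("dominant component out of respiration band"))
  }
  tibble(resp_bpm = bpm_from_period(per, fs), period_samples = per,
         valid = TRUE, note = "ok")
}

#' @export
glance.hr_report <- function(x, ...) {
  ok <- x$valid
  tibble(n_windows = nrow(x), n_valid = sum(ok),
         median_bpm = median(x$bpm[ok]),
         median_resp_bpm = median(x$resp_bpm[x$resp_valid]))
}

#' @export
autoplot.hr_report <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes((.data$window_start_s + .data$window_end_s) / 2,
                               .data$bpm, shape = .data$valid)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(linetype = 3) +
    ggplot2::labs(x = "window centre (s)", y = "heart rate (bpm)")
}

#' Export a windowed rate report as CSV
#'
#' @param report An `hr_report` tibble.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_hr_report <- function(report, path) {
  readr::write_csv(
    dplyr::select(as_tibble(report), "window_start_s", "window_end_s",
                  "bpm", "valid", "resp_bpm", "resp_valid"),
    path)
  invisible(path)
}
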