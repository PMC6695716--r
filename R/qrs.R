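#' Condition a raw ECG for QRS detection
#'
#' Software analogue of the amplifier settings used for the reference
#' acquisition: 1 Hz high-pass (baseline stabilisation), 35 Hz low-pass
#' (noise), and a 50 Hz mains notch, all run causally.
#'
#' @param ecg `coil_signal` in millivolts, fs >= 200 Hz.
#' @return Conditioned signal.
#' @export
condition_ecg <- function(ecg) {
  fs <- signal_fs(ecg)
  if (fs < 200) abort("ECG sampling rate must be >= 200 Hz for the 35 Hz LPF")
  v <- sig_values(ecg)
  hp <- signal::butter(2, 1 / (fs / 2), type = "high")
  lp <- signal::butter(4, 35 / (fs / 2), type = "low")
  nt <- signal::butter(2, c(48, 52) / (fs / 2), type = "stop")
  y <- as.numeric(signal::filter(hp$b, hp$a, v))
  y <- as.numeric(signal::filter(lp$b, lp$a, y))
  y <- as.numeric(signal::filter(nt$b, nt$a, y))
  sig_rewrap(ecg, y)
}

#' Estimate the slow baseline of an ECG
#'
#' Two-scale median filtering (200 ms then 600 ms): the first pass flattens
#' QRS complexes, the second P/T waves, leaving the sub-0.5 Hz baseline
#' wander. Subtracting the result straightens the trace.
#'
#' @param ecg `coil_signal` in millivolts.
#' @return Baseline signal, same length.
#' @export
estimate_baseline <- function(ecg) {
  fs <- signal_fs(ecg)
  v <- sig_values(ecg)
  odd <- function(k) {
    k <- max(1L, as.integer(k))
    if (k %% 2L == 0L) k + 1L else k
  }
  m1 <- stats::runmed(v, odd(0.2 * fs), endrule = "constant")
  m2 <- stats::runmed(m1, odd(0.6 * fs), endrule = "constant")
  sig_rewrap(ecg, as.numeric(m2))
}

#' Detect QRS complexes (Pan-Tompkins-style)
#'
#' Derivative-energy detector on a conditioned, baseline-removed ECG:
#' 5-15 Hz band-pass, five-point derivative, squaring, 150 ms moving-window
#' integration, then adaptive signal/noise thresholds with a 200 ms
#' refractory period (rejects tall T waves) and a search-back pass that
#' revisits RR gaps longer than 1.66 times the running median RR with a
#' lowered threshold. Each accepted detection is localized to the largest
#' absolute input deflection in the preceding 250 ms; QRS duration is the
#' width of the band-passed envelope above 15% of its local peak.
#'
#' @param ecg Conditioned, baseline-removed `coil_signal` (>= 2 s long).
#' @param refractory_s Minimum beat separation in seconds.
#' @param searchback_factor RR-gap multiple that triggers search-back.
#' @return Object of class `qrs_result`: `r_peaks` (1-based indices),
#'   `rr_intervals` (samples), `qrs_durations_ms`, `fs`, `n`.
#' @export
detect_qrs <- function(ecg, refractory_s = 0.2, searchback_factor = 1.66) {
  fs <- signal_fs(ecg)
  v <- sig_values(ecg)
  n <- length(v)
  if (n < 2 * fs) abort("ECG shorter than 2 s", class = "coilrate_range")

  # zero-pad so the moving-window integration of a beat near the end still
  # completes its peak inside the analysed range
  npad <- as.integer(round(0.2 * fs))
  vp <- c(v, numeric(npad))
  bp <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  xf <- as.numeric(signal::filter(bp$b, bp$a, vp))
  dv <- as.numeric(stats::filter(xf, c(1, 2, 0, -2, -1) / 8, sides = 1))
  dv[is.na(dv)] <- 0
  sq <- dv^2
  wmwi <- max(3L, round(0.15 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / wmwi, wmwi), sides = 1))
  mwi[is.na(mwi)] <- 0

  # candidate peaks of the integrated energy
  pk <- which(diff(sign(diff(mwi))) < 0) + 1L
  pk <- pk[mwi[pk] > 0]
  if (length(pk) == 0) {
    return(qrs_result(integer(0), numeric(0), fs, n))
  }
  refr <- round(refractory_s * fs)

  init <- seq_len(min(n, 2L * round(fs)))
  spki <- 0.5 * max(mwi[init])
  npki <- 0.5 * mean(mwi[init])
  thr1 <- npki + 0.25 * (spki - npki)
  beats <- integer(0)
  rejected <- integer(0)
  for (i in pk) {
    if (length(beats) > 0 && i - beats[length(beats)] < refr) next
    if (mwi[i] >= thr1) {
      beats <- c(beats, i)
      spki <- 0.125 * mwi[i] + 0.875 * spki
    } else {
      rejected <- c(rejected, i)
      npki <- 0.125 * mwi[i] + 0.875 * npki
    }
    thr1 <- npki + 0.25 * (spki - npki)
  }
  # search-back over long RR gaps with half threshold
  if (length(beats) >= 3) {
    repeat {
      rr <- diff(beats)
      med_rr <- median(rr)
      gap <- which(rr > searchback_factor * med_rr)
      added <- FALSE
      for (g in gap) {
        cand <- rejected[rejected > beats[g] + refr &
                           rejected < beats[g + 1] - refr]
        cand <- cand[mwi[cand] >= 0.5 * thr1]
        if (length(cand) > 0) {
          beats <- sort(c(beats, cand[which.max(mwi[cand])]))
          added <- TRUE
          break
        }
      }
      if (!added) break
    }
  }

  # localize R as the largest absolute deflection shortly before the
  # integration peak (the MWI lags the R wave)
  back <- as.integer(round(0.25 * fs))
  r <- vapply(beats, function(i) {
    i1 <- min(as.integer(i), n)
    i0 <- max(1L, i1 - back)
    i0 - 1L + as.integer(which.max(abs(v[i0:i1])))
  }, integer(1))
  r <- sort(unique(r))
  if (length(r) > 1) {
    keep <- c(TRUE, diff(r) >= refr)
    r <- r[keep]
  }

  durations <- qrs_durations(v, r, fs)
  qrs_result(r, durations, fs, n)
}

qrs_durations <- function(xf, r, fs) {
  half <- round(0.1 * fs)
  vapply(r, function(i) {
    i0 <- max(1L, i - half); i1 <- min(length(xf), i + half)
    e <- abs(xf[i0:i1])
    thr <- 0.15 * max(e)
    above <- which(e >= thr)
    (max(above) - min(above)) / fs * 1000
  }, numeric(1))
}

qrs_result <- function(r, durations, fs, n) {
  structure(list(r_peaks = as.integer(r),
                 rr_intervals = if (length(r) > 1) diff(r) else numeric(0),
                 qrs_durations_ms = durations, fs = fs, n = n),
            class = "qrs_result")
}

#' @export
print.qrs_result <- function(x, ...) {
  cat(sprintf("<qrs_result> %d beats in %.1f s", length(x$r_peaks), x$n / x$fs))
  if (length(x$rr_intervals) > 0) {
    cat(sprintf(" (median %.1f bpm)", 60 * x$fs / median(x$rr_intervals)))
  }
  cat("\n")
  invisible(x)
}

#' @export
tidy.qrs_result <- function(x, ...) {
  tibble(beat = seq_along(x$r_peaks),
         r_index = x$r_peaks,
         time_s = (x$r_peaks - 1) / x$fs,
         rr_samples = c(NA_real_, x$rr_intervals),
         bpm = c(NA_real_, 60 * x$fs / x$rr_intervals),
         qrs_duration_ms = x$qrs_durations_ms)
}

#' @export
glance.qrs_result <- function(x, ...) {
  tibble(n_beats = length(x$r_peaks),
         median_bpm = if (length(x$rr_intervals) > 0)
           60 * x$fs / median(x$rr_intervals) else NA_real_,
         median_qrs_ms = if (length(x$qrs_durations_ms) > 0)
           median(x$qrs_durations_ms) else NA_real_)
}

#' Beat-to-beat heart rate from RR intervals
#'
#' @param qrs A `qrs_result` with at least 2 peaks.
#' @param fs Sampling rate (Hz); defaults to the one stored in `qrs`.
#' @return Tibble with `beat`, `time_s` (interval midpoint), `rr_samples`,
#'   `bpm`.
#' @export
rr_to_bpm <- function(qrs, fs = qrs$fs) {
  if (length(qrs$r_peaks) < 2) {
    abort("need at least two R peaks for RR intervals", class = "coilrate_range")
  }
  rr <- diff(qrs$r_peaks)
  tibble(beat = seq_along(rr) + 1L,
         time_s = (qrs$r_peaks[-length(qrs$r_peaks)] + rr / 2 - 1) / fs,
         rr_samples = rr,
         bpm = 60 * fs / rr)
}

#' Full reference-ECG chain: condition, de-baseline, detect
#'
#' @param ecg Raw ECG `coil_signal` (millivolts).
#' @return A `qrs_result` (with the estimated baseline attached as
#'   `$baseline`).
#' @export
ecg_heart_rate <- function(ecg) {
  cond <- condition_ecg(ecg)
  base <- estimate_baseline(cond)
  flat <- sig_rewrap(cond, sig_values(cond) - sig_values(base))
  q <- detect_qrs(flat)
  q$baseline <- base
  q
}

#' Median heart rate per analysis window from a QRS result
#'
#' Pairs the ECG chain with the inductive chain on a common window grid: for
#' each window, the median of per-interval bpm for RR intervals whose
#' midpoint falls inside the window.
#'
#' @param qrs A `qrs_result`.
#' @param window_s,hop_s Window grid (seconds), matching the inductive report.
#' @param duration_s Total duration (defaults to the signal length).
#' @return Tibble with `window_start_s`, `window_end_s`, `bpm`, `n_beats`.
#' @export
window_bpm <- function(qrs, window_s = 15, hop_s = 5,
                       duration_s = qrs$n / qrs$fs) {
  per <- rr_to_bpm(qrs)
  starts <- seq(0, duration_s - window_s, by = hop_s)
  map_dfr(starts, function(t0) {
    inwin <- per$time_s >= t0 & per$time_s < t0 + window_s
    tibble(window_start_s = t0, window_end_s = t0 + window_s,
           bpm = if (any(inwin)) median(per$bpm[inwin]) else NA_real_,
           n_beats = sum(inwin))
  })
}
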