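#' Scenario description for a synthetic inductive recording
#'
#' Encodes the acquisition conditions the generator emulates: an
#' approximately 30 s recording at 20 Hz in which respiration (3-5 s
#' exhalation period) dominates a smaller apex heartbeat pulse, with
#' uniform-like converter noise whose level depends on whether the coil is
#' pressed against the chest, and an optional breath-hold interval.
#' Amplitudes are chest-wall displacements in meters.
#'
#' @param duration_s Recording length in seconds.
#' @param fs Sampling rate in Hz.
#' @param hr_bpm Heart rate, 40-200 bpm.
#' @param resp_period_s Exhalation period in seconds (typically 3-5).
#' @param resp_amp Respiration displacement amplitude (m); must exceed
#'   `cardiac_amp`.
#' @param cardiac_amp Apex pulse displacement amplitude (m).
#' @param noise_amp Half-width of the uniform noise (m); defaults to
#'   `cardiac_amp / 5` when pressed and `cardiac_amp / 1.2` when not (the
#'   unpressed level is calibrated so that heart rate stays recoverable
#'   with analysis windows longer than 10 s but not with short ones).
#' @param pressed Is the coil pressed against the chest?
#' @param breath_hold Optional `c(t_start, t_end)` seconds of suspended
#'   respiration.
#' @param seed Integer seed; all generators are deterministic given it.
#' @param jitter Relative SD of the per-cycle respiration period.
#' @param pulse_sigma_s Gaussian width (SD, s) of the cardiac pulse.
#' @param baseline_h Resting coil inductance (H).
#' @param sensitivity_h_per_m Inductance change per meter of approach (H/m).
#' @param full_scale Converter full-scale inductance range `c(Lmin, Lmax)`.
#' @return A list of class `inductive_scenario`.
#' @export
inductive_scenario <- function(duration_s = 30, fs = 20, hr_bpm = 72,
                               resp_period_s = 4,
                               resp_amp = 4e-3, cardiac_amp = 2e-4,
                               noise_amp = NULL, pressed = TRUE,
                               breath_hold = NULL, seed = 1L,
                               jitter = 0.02, pulse_sigma_s = 0.05,
                               baseline_h = 3.5e-6,
                               sensitivity_h_per_m = 1e-5,
                               full_scale = c(3.3e-6, 3.7e-6)) {
  if (!(hr_bpm >= 40 && hr_bpm <= 200)) abort("`hr_bpm` must be in [40, 200]")
  if (resp_period_s <= 0) abort("`resp_period_s` must be positive")
  if (!(resp_amp > cardiac_amp && cardiac_amp > 0)) {
    abort("need resp_amp > cardiac_amp > 0: respiration dominates the raw stream")
  }
  noise_amp <- noise_amp %||% if (pressed) cardiac_amp / 5 else cardiac_amp / 1.2
  if (noise_amp < 0) abort("`noise_amp` must be non-negative")
  if (!is.null(breath_hold)) {
    if (length(breath_hold) != 2L || breath_hold[1] >= breath_hold[2] ||
        breath_hold[1] < 0 || breath_hold[2] > duration_s) {
      abort("`breath_hold` must be c(t0, t1) inside [0, duration_s]",
            class = "coilrate_range")
    }
  }
  structure(
    list(duration_s = duration_s, fs = fs, hr_bpm = hr_bpm,
         resp_period_s = resp_period_s, resp_amp = resp_amp,
         cardiac_amp = cardiac_amp, noise_amp = noise_amp, pressed = pressed,
         breath_hold = breath_hold, seed = as.integer(seed), jitter = jitter,
         pulse_sigma_s = pulse_sigma_s, baseline_h = baseline_h,
         sensitivity_h_per_m = sensitivity_h_per_m, full_scale = full_scale),
    class = "inductive_scenario"
  )
}

sc_times <- function(sc) {
  n <- round(sc$duration_s * sc$fs)
  (seq_len(n) - 1) / sc$fs
}

#' Synthetic respiration displacement
#'
#' Raised-cosine cycles (`0.5 - 0.5 cos(2 pi phi)`) with small per-cycle
#' period jitter — a smooth quasi-sinusoid whose instantaneous period varies
#' breath to breath; identically zero inside a breath-hold interval, with
#' 1 s cosine on/off ramps.
#'
#' @param sc An [inductive_scenario()].
#' @return Signal in meters.
#' @export
gen_respiration <- function(sc) {
  t <- sc_times(sc)
  ncyc <- ceiling(sc$duration_s / (sc$resp_period_s * 0.8)) + 2L
  periods <- withr::with_seed(sc$seed, {
    j <- rnorm(ncyc, 0, sc$jitter)
    j <- pmin(pmax(j, -3 * sc$jitter), 3 * sc$jitter)
    sc$resp_period_s * (1 + j)
  })
  starts <- cumsum(c(0, periods))
  ci <- findInterval(t, starts)
  phase <- (t - starts[ci]) / periods[ci]
  v <- sc$resp_amp * (0.5 - 0.5 * cos(2 * pi * phase))
  if (!is.null(sc$breath_hold)) {
    env <- rep(1, length(t))
    ramp <- 1
    t0 <- sc$breath_hold[1]; t1 <- sc$breath_hold[2]
    env[t >= t0 & t <= t1] <- 0
    pre <- t > t0 - ramp & t < t0
    env[pre] <- 0.5 + 0.5 * cos(pi * (t[pre] - (t0 - ramp)) / ramp)
    post <- t > t1 & t < t1 + ramp
    env[post] <- 0.5 - 0.5 * cos(pi * (t[post] - t1) / ramp)
    v <- v * env
  }
  as_signal(v, fs = sc$fs, unit = "meter")
}

#' Synthetic cardiac (apex pulse) displacement
#'
#' A Gaussian mechanical pulse per beat on a regular beat grid at `hr_bpm`.
#'
#' @param sc An [inductive_scenario()].
#' @return Signal in meters.
#' @export
gen_cardiac <- function(sc) {
  beat_period <- 60 / sc$hr_bpm
  if (6 * sc$pulse_sigma_s >= beat_period) {
    abort("cardiac pulse width >= beat period", class = "coilrate_range")
  }
  t <- sc_times(sc)
  beats <- seq(0, sc$duration_s - 1e-9, by = beat_period)
  v <- numeric(length(t))
  half <- 5 * sc$pulse_sigma_s
  for (tb in beats) {
    i <- which(t >= tb - half & t <= tb + half)
    v[i] <- v[i] + exp(-((t[i] - tb)^2) / (2 * sc$pulse_sigma_s^2))
  }
  as_signal(sc$cardiac_amp * v, fs = sc$fs, unit = "meter")
}

#' Synthetic inductive count stream
#'
#' Composes respiration + cardiac displacement + uniform noise, maps the sum
#' through the coil proximity model and 16-bit quantization, and returns the
#' count stream a converter would deliver. Under the default pressed scenario
#' the cardiac-to-noise amplitude ratio is 5 (beat periodicity plainly
#' visible); when not pressed it is 1.2 (beat buried in noise, recoverable
#' only with long analysis windows).
#'
#' @param sc An [inductive_scenario()].
#' @return Signal of 16-bit counts.
#' @export
gen_inductive <- function(sc) {
  sB <- sig_values(gen_respiration(sc))
  sH <- sig_values(gen_cardiac(sc))
  u <- withr::with_seed(sc$seed + 2L,
                        runif(length(sB), -sc$noise_amp, sc$noise_amp))
  disp <- as_signal(sB + sH + u, fs = sc$fs, unit = "meter")
  l <- modulate_inductance(disp, sc$baseline_h, sc$sensitivity_h_per_m)
  quantize_counts(l, sc$full_scale)
}

#' Synthetic single-lead ECG with known R-peak positions
#'
#' Gaussian P-QRS-T template repeated on a (optionally jittered) beat grid,
#' with optional sinusoidal baseline wander and white noise. P and T offsets
#' scale with sqrt(RR) so templates do not collide at high rates. The first R
#' peak sits at 0.5 s.
#'
#' @param duration_s Length in seconds.
#' @param fs Sampling rate (Hz), 200 by default.
#' @param hr_bpm Heart rate, 40-200.
#' @param qrs_width_ms Approximate QRS width (< 200 ms).
#' @param p_amp,t_amp P and T wave amplitudes (mV); R is 1 mV.
#' @param noise_amp SD of additive Gaussian noise (mV).
#' @param wander_amp,wander_freq_hz Baseline wander amplitude (mV) and
#'   frequency (< 0.5 Hz).
#' @param rr_jitter_ms SD of beat-to-beat RR jitter (ms).
#' @param seed Integer seed.
#' @return List of class `ecg_sim`: `signal` (millivolt `coil_signal`),
#'   `r_peaks` (ground-truth sample indices, 1-based), `fs`, `hr_bpm`.
#' @export
gen_ecg <- function(duration_s = 30, fs = 200, hr_bpm = 60,
                    qrs_width_ms = 80, p_amp = 0.15, t_amp = 0.3,
                    noise_amp = 0.02, wander_amp = 0, wander_freq_hz = 0.3,
                    rr_jitter_ms = 0, seed = 1L) {
  if (!(qrs_width_ms > 0 && qrs_width_ms < 200)) {
    abort("`qrs_width_ms` must be in (0, 200)")
  }
  if (!(hr_bpm >= 40 && hr_bpm <= 200)) abort("`hr_bpm` must be in [40, 200]")
  if (wander_freq_hz >= 0.5) abort("baseline wander must stay below 0.5 Hz")
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  rr <- 60 / hr_bpm
  n_beats <- floor((duration_s - 0.5) / rr) + 1L
  r_times <- withr::with_seed(seed, {
    jit <- if (rr_jitter_ms > 0) rnorm(n_beats, 0, rr_jitter_ms / 1000) else 0
    0.5 + (seq_len(n_beats) - 1) * rr + jit
  })
  r_times <- r_times[r_times >= 0.1 & r_times <= duration_s - 0.05]
  qt_scale <- sqrt(min(rr, 1))
  w <- qrs_width_ms / 1000
  # component waves: centre offset (s), width sigma (s), amplitude (mV)
  waves <- list(
    p = c(-0.16 * qt_scale, 0.020, p_amp),
    q = c(-0.30 * w,        w / 10, -0.15),
    r = c(0,                w / 8,   1.00),
    s = c(0.30 * w,         w / 10, -0.25),
    t = c(0.30 * qt_scale,  0.050 * qt_scale, t_amp)
  )
  v <- numeric(n)
  for (tb in r_times) {
    for (wv in waves) {
      half <- 4 * wv[2]
      i <- which(t >= tb + wv[1] - half & t <= tb + wv[1] + half)
      v[i] <- v[i] + wv[3] * exp(-((t[i] - tb - wv[1])^2) / (2 * wv[2]^2))
    }
  }
  if (wander_amp > 0) v <- v + wander_amp * sin(2 * pi * wander_freq_hz * t)
  if (noise_amp > 0) {
    v <- v + withr::with_seed(seed + 1L, rnorm(n, 0, noise_amp))
  }
  r_peaks <- pmin(pmax(round(r_times * fs) + 1L, 1L), n)
  structure(list(signal = as_signal(v, fs = fs, unit = "millivolt"),
                 r_peaks = as.integer(r_peaks), fs = fs, hr_bpm = hr_bpm),
            class = "ecg_sim")
}

#' @export
print.ecg_sim <- function(x, ...) {
  cat(sprintf("<ecg_sim> %d beats @ %g bpm, fs %g Hz, %.1f s\n",
              length(x$r_peaks), x$hr_bpm, x$fs,
              nrow(x$signal) / x$fs))
  invisible(x)
}
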