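---
title: "Extracting heart and respiration rate from a single inductive sensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting heart and respiration rate from a single inductive sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

A planar spiral coil woven into a garment in front of the cardiac apex,
read by an inductance-to-digital converter (LDC), sees the chest wall as a
diamagnetic body: as the tissue approaches the coil, the inductance drops.
The digitized count stream at `fs = 20` Hz therefore superposes two
mechanical signals — the large, slow chest excursion of breathing (period
3–5 s, millimetres) and the much smaller, faster apex impulse of each
heartbeat (tenths of a millimetre) — plus converter noise whose level
depends on how firmly the coil is pressed against the chest:

$$ s = s_B + s_H + u. $$

`coilrate` implements the full chain that turns such a stream into
per-window heart-rate and respiration-rate estimates, a reference ECG (QRS)
chain to validate against, rule-based pre-diagnosis alerts, Bland–Altman
agreement statistics, and a synthetic generator standing in for the
hardware.

## The processing chain

Per recording, with per-window reporting:

1. **Offset removal** — subtract the mean: `s_n ← s_n − mean(s)`.
2. **Respiration extraction** — a 7th-order digital Butterworth low-pass
   with a 1 Hz cutoff (`design_lowpass(7, 1, 20)`); its causal output
   `s* ≈ s_B` is the respiration component.
3. **Delay compensation** — the recursive (AR) part of the filter delays
   `s*`. The lag is estimated twice, by the raw cross-correlation
   `CXY[k] = Σ s[n] s*[n+k]` (global maximum) and the average magnitude
   difference function `DXY[k] = Σ |s[n] − s*[n+k]|` (global minimum); the
   candidate whose aligned overlap leaves the smaller mean absolute
   residual wins. The aligned difference `d[n] = s[n] − s*[n+offset]`
   keeps the cardiac component.
4. **Period detection** — raw autocorrelation `CXX[k] = Σ d[n] d[n+k]`,
   searched for local maxima between the physiologic lag bounds
   `Tmin = round(60/200·fs)` and `Tmax = round(60/40·fs)`
   (6 and 30 samples at 20 Hz).
5. **Rate** — `bpm = 60/T · fs`.

Respiration rate reuses the same machinery on `s*` with 6–30 breaths/min
bounds.

```{r}
library(coilrate)
sc <- inductive_scenario(hr_bpm = 72, pressed = TRUE, seed = 1)
stream <- gen_inductive(sc)
estimate_heart_rate(stream, window_s = 15, hop_s = 5)
```

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `fs` | 20 | Hz | inductive sampling rate of the acquisition chain |
| filter order / cutoff | 7 / 1 | – / Hz | respiration lives below ~0.5 Hz; heart rates start at 0.67 Hz |
| `window_s` / `hop_s` | 15 / 5 | s | windows must hold ≥ 2·Tmax samples; noisy (unpressed) recordings need windows above 10 s |
| bpm bounds | 40–200 | bpm | admissible heart-rate range; defines the lag search band |
| delay search bound | 2 | s | the filter's group delay at respiration frequencies is ≈ 0.7 s, far inside |
| respiration bounds | 6–30 | breaths/min | adult resting range |

## Numerical choices

* **Filter initialisation.** `apply_filter()` defaults to zero initial
  conditions (the plain difference equation). The windowed pipeline instead
  filters the *whole recording once* with steady-state initial conditions
  for the first sample's level, then slices windows from the raw and
  filtered streams. The filter is time-invariant, so windowed slices of the
  full output equal per-window filtering minus the start-up swing a
  restarted filter adds; that swing (the input effectively steps from zero
  to the respiration level, and the order-7 filter rings near its 1 Hz
  edge) is comparable to the whole respiration amplitude and would dominate
  the small cardiac difference signal.
* **Alignment is integer-lag.** Fractional-sample delay estimation is out
  of scope. Quantizing the ≈14.5-sample group delay to an integer leaves a
  few percent of the respiration amplitude in `d`; since respiration is
  ~20× the cardiac amplitude, `d` retains a visible slow residual. The
  suite asserts what the subtraction does guarantee: the respiration
  fundamental is attenuated more than tenfold relative to the raw signal.
* **Period selection.** `estimate_period()` implements the literal rule —
  the highest in-band local maximum of `CXX`, ties to the smaller lag. The
  pipeline uses `estimate_period_robust()`: the same candidate peaks, but
  compared after subtracting an 11-lag running-median baseline (so the slow
  residual above cannot bias the choice), taking the earliest candidate
  within 0.8 of the best detrended peak. The second part is the standard
  pitch-halving correction: the 6–30-sample band spans a fivefold ratio, so
  for fast rates it necessarily contains 2T and 3T, and an integer multiple
  of a fractional period (e.g. 3 × 6.67 = 20 at 180 bpm) is sampled more
  coherently than the rounded period itself. Both constants are fixed
  design values.
* **Respiration validity guards.** A window's respiration estimate is
  reported valid only when the normalized autocorrelation peak reaches 0.25
  and the dominant spectral component of `s*` lies in the 6–30 breaths/min
  band. This flags breath-hold windows (no periodicity) and windows whose
  low-pass output is dominated by cardiac leakage, instead of reporting a
  spurious rate.
* **Degenerate inputs.** Constant signals cannot be normalized (error);
  windows with no in-band autocorrelation peak are flagged invalid rather
  than raised, so a 30 s run always returns a report; `estimate_period`
  ties break to the smaller lag (higher bpm), deterministically.
* **Quantization.** Counts use round-half-even onto 0..65535; the
  dequantization error is bounded by half an LSB, ~0.6 µm of equivalent
  chest displacement under the default sensor model — negligible against
  the 200 µm cardiac pulse.

## The synthetic generator

`inductive_scenario()` encodes the acquisition conditions: ~30 s recordings
at 20 Hz; respiration as raised-cosine cycles with 2% per-cycle period
jitter (a smooth quasi-sinusoid; real chest excursion is not far from
sinusoidal at rest), amplitude 4 mm; the apex pulse as a Gaussian bump per
beat (σ = 50 ms), amplitude 0.2 mm; uniform converter noise with
cardiac-to-noise ratio 5 when the coil is pressed and 1.2 when not (the
unpressed level is calibrated so that heart rate stays recoverable with
analysis windows longer than 10 s but degrades with short ones); optional
breath-hold intervals with 1 s ramps; and the coil model (3.5 µH baseline,
10 nH/mm sensitivity, 16-bit quantization over a 3.3–3.7 µH full scale).
`gen_ecg()` produces the paired reference lead: a Gaussian P–QRS–T template
on a beat grid, with P/T offsets scaling with √RR so high-rate templates do
not collide, plus optional wander and noise, returning ground-truth R-peak
indices.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: motion and muscle artifacts (the sensor is
specified for repose/sleep), contact-pressure drift, sensor geometry
changes, arrhythmic beat morphologies, apnea beyond simple breath-holds,
and strongly non-sinusoidal respiration waveforms. The last point is a real
limitation of the method, not only of the generator: respiration harmonics
near and above the 1 Hz cutoff survive the single-integer-lag subtraction
(each harmonic sees a different group delay) and can rival the cardiac
component when breathing is sharply asymmetric.

## The reference ECG chain

Software analogues of the amplifier settings (1 Hz high-pass, 35 Hz
low-pass, 50 Hz notch), a two-scale median-filter baseline (200 ms then
600 ms), and a Pan–Tompkins-style detector: 5–15 Hz band-pass, five-point
derivative, squaring, 150 ms moving-window integration, adaptive
signal/noise thresholds, 200 ms refractory period, and search-back over RR
gaps exceeding 1.66× the running median. R peaks are localized on the
wide-band signal; QRS duration is the envelope width above 15% of the local
peak. The refractory period and search-back factor are conventional values;
the detector's accuracy contract in the suite is zero misses and zero false
positives at ±40 ms on clean synthetic grids (45–150 bpm, tall-T variants).

## Alerts and agreement

The pre-diagnosis rules are pure, threshold-parameterized predicates with
the standard defaults: tachycardia above 130 bpm, bradycardia below 40 bpm
(strict; the ±10 bpm admitted calculus error is metadata, not hysteresis),
variation above 20% of the run mean over a configurable number of
complexes, at most nine acceptable missed QRS complexes, and a median QRS
duration alert strictly above 120 ms. Agreement between the inductive and
ECG chains uses classical Bland–Altman statistics (bias ± 1.96·SD limits)
on per-window rate pairs.

## Problem sizes used by the test-suite

The suite works at the chain's native scale: 30 s recordings, 15 s/5 s
window grids, a pressed-scenario recovery grid over
hr ∈ {48, 72, 120, 180} × resp period ∈ {3, 4, 5} s, a 20-seed Monte-Carlo
comparison of 12 s vs 3 s windows on unpressed scenarios, and a
45–150 bpm ECG grid — sizes a desk check can re-run in well under a minute.

## Known limitations

* Windowed rates only: no beat-to-beat intervals from the inductive signal,
  and rate resolution is limited by lag quantization (at 20 Hz, ±8.6 bpm
  at 180 bpm, sub-bpm at 48 bpm).
* Integer-lag alignment leaves a slow respiration residual in `d`
  (see above); sharply asymmetric breathing degrades separation.
* The unpressed-noise regime relies on windows above 10 s; 3 s windows
  fail often by design.
* No artifact rejection: any body motion invalidates the stream.
* The RestingECG XML dialect is implemented exactly as printed in its
  example record, including its truncated final hex token (parsed
  leniently and flagged); stored CRCs of such truncated payloads cannot
  verify.
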