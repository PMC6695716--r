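#' Run configuration for the pipeline commands
#'
#' Bundles and validates every knob the pipeline commands use. The defaults
#' reproduce the standard acquisition and processing settings: 20 Hz
#' inductive sampling, 15 s windows with a 5 s hop, order-7 Butterworth at
#' 1 Hz, and a 40-200 bpm search range.
#'
#' @param fs Inductive sampling rate (Hz).
#' @param window_s,hop_s Analysis window grid (seconds).
#' @param order,cutoff_hz Respiration low-pass design.
#' @param bpm_min,bpm_max Heart-rate search range.
#' @param seed Integer seed for synthetic generation.
#' @param scenario An [inductive_scenario()] (built from `seed` and defaults
#'   when omitted).
#' @param ecg_fs Reference ECG sampling rate (Hz).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(fs = 20, window_s = 15, hop_s = 5, order = 7L,
                       cutoff_hz = 1, bpm_min = 40, bpm_max = 200,
                       seed = 1L, scenario = NULL, ecg_fs = 200) {
  bounds <- lag_bounds(fs, bpm_min, bpm_max)  # validates rates + bounds
  if (!(cutoff_hz > 0 && cutoff_hz < fs / 2)) {
    abort("`cutoff_hz` must be in (0, fs/2)", class = "coilrate_range")
  }
  if (round(window_s * fs) < 2 * bounds[["t_max"]]) {
    abort("`window_s` must hold at least 2 * t_max samples",
          class = "coilrate_range")
  }
  if (hop_s <= 0) abort("`hop_s` must be positive")
  scenario <- scenario %||% inductive_scenario(fs = fs, seed = seed)
  structure(list(fs = fs, window_s = window_s, hop_s = hop_s,
                 order = as.integer(order), cutoff_hz = cutoff_hz,
                 bpm_min = bpm_min, bpm_max = bpm_max, seed = as.integer(seed),
                 scenario = scenario, ecg_fs = ecg_fs),
            class = "run_config")
}

#' Pipeline commands
#'
#' Thin orchestration over the package functions, mirroring the CLI
#' subcommands. `run_simulate()` writes a synthetic inductive stream (plus a
#' ground-truth sidecar and a matched reference ECG), `run_extract()` turns
#' a stream into a per-window rate report, `run_qrs()` runs the reference
#' ECG chain, and `run_validate()` pairs the two chains, computing
#' Bland-Altman agreement and the alert report.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return `run_simulate()`: tibble of written files (invisible).
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- config$scenario
  stream <- gen_inductive(sc)
  stream_path <- file.path(out_dir, "inductive.txt")
  write_inductive_text(stream, stream_path)
  truth_path <- file.path(out_dir, "inductive_truth.txt")
  writeLines(c(
    sprintf("hr_bpm=%g", sc$hr_bpm),
    sprintf("resp_period_s=%g", sc$resp_period_s),
    sprintf("resp_rate_bpm=%g", 60 / sc$resp_period_s),
    sprintf("fs_hz=%g", sc$fs),
    sprintf("duration_s=%g", sc$duration_s),
    sprintf("pressed=%s", sc$pressed),
    sprintf("seed=%d", sc$seed)
  ), truth_path)
  ecg <- gen_ecg(duration_s = sc$duration_s, fs = config$ecg_fs,
                 hr_bpm = sc$hr_bpm, seed = sc$seed)
  ecg_path <- file.path(out_dir, "ecg.csv")
  readr::write_csv(tibble(time_s = ecg$signal$time_s,
                          mv = ecg$signal$value), ecg_path)
  rpk_path <- file.path(out_dir, "ecg_r_peaks.txt")
  writeLines(as.character(ecg$r_peaks), rpk_path)
  invisible(tibble(kind = c("inductive", "truth", "ecg", "r_peaks"),
                   path = c(stream_path, truth_path, ecg_path, rpk_path)))
}

#' @rdname run_simulate
#' @param input Path to an inductive text stream.
#' @return `run_extract()`: the `hr_report` tibble (also written as
#'   `rate_report.csv`).
#' @export
run_extract <- function(config, input, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  s <- read_inductive_text(input, fs = config$fs)
  report <- estimate_heart_rate(s, window_s = config$window_s,
                                hop_s = config$hop_s, order = config$order,
                                cutoff_hz = config$cutoff_hz,
                                bpm_min = config$bpm_min,
                                bpm_max = config$bpm_max)
  write_hr_report(report, file.path(out_dir, "rate_report.csv"))
  report
}

#' @rdname run_simulate
#' @param ecg_csv Path to a two-column CSV (`time_s`, `mv`).
#' @return `run_qrs()`: the `qrs_result` (beats also written as
#'   `qrs_beats.csv`).
#' @export
run_qrs <- function(config, ecg_csv, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  df <- readr::read_csv(ecg_csv, show_col_types = FALSE)
  if (!all(c("time_s", "mv") %in% names(df))) {
    abort("ECG CSV needs columns time_s, mv", class = "coilrate_parse")
  }
  fs <- round(1 / median(diff(df$time_s)))
  ecg <- as_signal(df$mv, fs = fs, unit = "millivolt")
  q <- ecg_heart_rate(ecg)
  readr::write_csv(tidy(q), file.path(out_dir, "qrs_beats.csv"))
  q
}

#' @rdname run_simulate
#' @param inductive Path to the inductive stream.
#' @return `run_validate()`: list with `pairs`, `agreement`
#'   (`bland_altman`), `alerts` (`alert_report`), `inductive_report`, `qrs`.
#' @export
run_validate <- function(config, inductive, ecg_csv, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- run_extract(config, inductive, out_dir)
  q <- run_qrs(config, ecg_csv, out_dir)
  dur_i <- max(report$window_end_s)
  dur_e <- q$n / q$fs
  if (abs(dur_i - dur_e) > config$window_s) {
    abort("inductive and ECG recordings have misaligned durations",
          class = "coilrate_range")
  }
  ecg_win <- window_bpm(q, window_s = config$window_s, hop_s = config$hop_s,
                        duration_s = dur_e)
  pairs <- dplyr::inner_join(
    dplyr::select(as_tibble(report), "window_start_s", coil_bpm = "bpm",
                  coil_valid = "valid"),
    dplyr::select(ecg_win, "window_start_s", ecg_bpm = "bpm"),
    by = "window_start_s")
  usable <- dplyr::filter(pairs, .data$coil_valid, is.finite(.data$ecg_bpm))
  if (nrow(usable) < 2) {
    abort("fewer than two pairable windows", class = "coilrate_range")
  }
  ba <- bland_altman(usable, .data$coil_bpm, .data$ecg_bpm)
  expected <- max(length(q$r_peaks),
                  if (length(q$rr_intervals) > 0)
                    floor(dur_e / (median(q$rr_intervals) / q$fs)) else 0L)
  alerts <- alert_report(usable$ecg_bpm, qrs = q, expected_beats = expected)
  write_agreement(ba, file.path(out_dir, "agreement.csv"))
  write_alert_report(alerts, file.path(out_dir, "alerts.json"))
  readr::write_csv(pairs, file.path(out_dir, "window_pairs.csv"))
  list(pairs = pairs, agreement = ba, alerts = alerts,
       inductive_report = report, qrs = q)
}
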