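#' Rule-based pre-diagnosis alerts on a heart-rate series
#'
#' `check_rate_alerts()` flags tachycardia (bpm strictly above
#' `tachy_above`, default 130) and bradycardia (strictly below `brady_below`,
#' default 40). The admitted calculus error of +/- 10 bpm is reported as
#' metadata, not used to widen the thresholds.
#'
#' @param bpm Numeric vector of heart rates, or an `hr_report` tibble (its
#'   valid windows are used).
#' @param tachy_above,brady_below Alert thresholds in bpm.
#' @return Tibble with `index`, `bpm`, `kind` (one row per alert).
#' @export
check_rate_alerts <- function(bpm, tachy_above = 130, brady_below = 40) {
  bpm <- alert_series(bpm)
  if (length(bpm) == 0) abort("empty heart-rate series", class = "coilrate_empty")
  kind <- ifelse(bpm > tachy_above, "tachy",
                 ifelse(bpm < brady_below, "brady", NA_character_))
  out <- tibble(index = seq_along(bpm), bpm = bpm, kind = kind)
  dplyr::filter(out, !is.na(.data$kind))
}

#' Heart-rate variation alert over runs of complexes
#'
#' Over each sliding run of `n_complexes` consecutive rates, alerts when the
#' peak-to-peak spread exceeds `threshold` (default 20%) of the run mean.
#'
#' @inheritParams check_rate_alerts
#' @param n_complexes Run length (>= 2).
#' @param threshold Relative variation limit.
#' @return Tibble with `start_index`, `end_index`, `variation` per alert.
#' @export
check_variation_alert <- function(bpm, n_complexes = 2L, threshold = 0.20) {
  bpm <- alert_series(bpm)
  if (n_complexes < 2L) abort("`n_complexes` must be >= 2")
  if (length(bpm) < n_complexes) {
    abort("series shorter than `n_complexes`", class = "coilrate_range")
  }
  starts <- seq_len(length(bpm) - n_complexes + 1L)
  rows <- map_dfr(starts, function(i) {
    w <- bpm[i:(i + n_complexes - 1L)]
    tibble(start_index = i, end_index = i + n_complexes - 1L,
           variation = (max(w) - min(w)) / mean(w))
  })
  dplyr::filter(rows, .data$variation > threshold)
}

#' Acceptability of missed QRS complexes
#'
#' A recording is acceptable when at most `max_misses` (default 9) expected
#' complexes were not detected.
#'
#' @param expected,detected Beat counts, `expected >= detected >= 0`.
#' @param max_misses Largest acceptable miss count.
#' @return Logical.
#' @export
check_qrs_miss <- function(expected, detected, max_misses = 9L) {
  if (detected < 0 || expected < 0) abort("counts must be non-negative")
  if (detected > expected) {
    abort("detected > expected: reconcile false positives before this check",
          class = "coilrate_range")
  }
  (expected - detected) <= max_misses
}

#' QRS duration alert
#'
#' Alerts when the median QRS duration strictly exceeds `threshold_ms`
#' (default 120 ms). Even-length series use the mean of the two central
#' values.
#'
#' @param durations_ms Numeric vector of per-beat QRS durations (ms).
#' @param threshold_ms Alert threshold.
#' @return Logical.
#' @export
check_qrs_duration <- function(durations_ms, threshold_ms = 120) {
  if (length(durations_ms) == 0) abort("empty duration series",
                                       class = "coilrate_empty")
  median(durations_ms) > threshold_ms
}

alert_series <- function(bpm) {
  if (is.data.frame(bpm)) {
    if (!is.null(bpm$valid)) bpm <- bpm[bpm$valid, , drop = FALSE]
    bpm <- bpm$bpm
  }
  as.numeric(bpm)
}

#' Combined pre-diagnosis alert report
#'
#' Evaluates all four alert rules and echoes the thresholds used.
#'
#' @inheritParams check_rate_alerts
#' @param qrs Optional `qrs_result` (for duration and miss checks).
#' @param expected_beats Optional expected beat count for the miss check.
#' @param n_complexes Run length for the variation rule.
#' @param tachy_above,brady_below,variation_threshold,max_misses,qrs_ms
#'   Thresholds; defaults are the standard rule set.
#' @return Object of class `alert_report`.
#' @export
alert_report <- function(bpm, qrs = NULL, expected_beats = NULL,
                         n_complexes = 2L, tachy_above = 130,
                         brady_below = 40, variation_threshold = 0.20,
                         max_misses = 9L, qrs_ms = 120) {
  series <- alert_series(bpm)
  rate <- check_rate_alerts(series, tachy_above, brady_below)
  variation <- if (length(series) >= n_complexes) {
    check_variation_alert(series, n_complexes, variation_threshold)
  } else tibble(start_index = integer(), end_index = integer(),
                variation = numeric())
  detected <- if (!is.null(qrs)) length(qrs$r_peaks) else NA_integer_
  miss_ok <- if (!is.null(qrs) && !is.null(expected_beats)) {
    check_qrs_miss(max(expected_beats, detected), detected, max_misses)
  } else NA
  dur_alert <- if (!is.null(qrs) && length(qrs$qrs_durations_ms) > 0) {
    check_qrs_duration(qrs$qrs_durations_ms, qrs_ms)
  } else NA
  structure(
    list(rate_alerts = rate, variation_alerts = variation,
         qrs_miss_acceptable = miss_ok, qrs_duration_alert = dur_alert,
         tolerances = list(tachy_above = tachy_above,
                           brady_below = brady_below,
                           admitted_error_bpm = 10,
                           variation_threshold = variation_threshold,
                           max_misses = max_misses,
                           qrs_duration_ms = qrs_ms)),
    class = "alert_report"
  )
}

#' @export
print.alert_report <- function(x, ...) {
  cat("<alert_report>\n")
  cat(sprintf("  rate alerts:      %d (tachy > %g, brady < %g bpm)\n",
              nrow(x$rate_alerts), x$tolerances$tachy_above,
              x$tolerances$brady_below))
  cat(sprintf("  variation alerts: %d (> %.0f%% of run mean)\n",
              nrow(x$variation_alerts), 100 * x$tolerances$variation_threshold))
  cat(sprintf("  QRS misses OK:    %s; duration alert: %s\n",
              format(x$qrs_miss_acceptable), format(x$qrs_duration_alert)))
  invisible(x)
}

#' @export
tidy.alert_report <- function(x, ...) {
  bind_rows(
    mutate(x$rate_alerts, rule = "rate"),
    if (nrow(x$variation_alerts) > 0)
      tibble(index = x$variation_alerts$start_index,
             bpm = NA_real_, kind = "variation", rule = "variation")
  )
}

#' Serialize an alert report as flat JSON
#'
#' @param report An `alert_report`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_alert_report <- function(report, path) {
  flat <- c(
    list(n_rate_alerts = nrow(report$rate_alerts),
         n_variation_alerts = nrow(report$variation_alerts),
         qrs_miss_acceptable = report$qrs_miss_acceptable,
         qrs_duration_alert = report$qrs_duration_alert),
    report$tolerances
  )
  jsonlite::write_json(flat, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}
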