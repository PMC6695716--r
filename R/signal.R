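#' Uniformly sampled signal tibbles
#'
#' A signal is represented as a tibble with columns `time_s` and `value`,
#' carrying the sampling rate (`fs`, Hz) and a physical unit tag as
#' attributes. All processing verbs in the package take such a tibble as
#' their first argument and return one, so pipelines chain with the pipe.
#'
#' @param value Numeric vector of samples (finite, length >= 1).
#' @param fs Sampling rate in Hz (> 0).
#' @param unit One of `"counts"`, `"adimensional"`, `"millivolt"`, `"henry"`,
#'   `"meter"`.
#' @return A tibble of class `coil_signal` with columns `time_s`, `value`.
#' @examples
#' s <- as_signal(sin(2 * pi * 0.25 * seq(0, 10, by = 0.05)), fs = 20)
#' signal_fs(s)
#' @export
as_signal <- function(value,
                      fs,
                      unit = c("counts", "adimensional", "millivolt",
                               "henry", "meter")) {
  unit <- match.arg(unit)
  value <- as.numeric(value)
  if (length(value) < 1L) {
    abort("a signal needs at least one sample", class = "coilrate_empty")
  }
  if (!all(is.finite(value))) {
    abort("signal samples must all be finite", class = "coilrate_nonfinite")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number (Hz)")
  }
  out <- tibble(time_s = (seq_along(value) - 1) / fs, value = value)
  attr(out, "fs") <- as.numeric(fs)
  attr(out, "unit") <- unit
  class(out) <- c("coil_signal", class(out))
  out
}

#' @rdname as_signal
#' @param x A `coil_signal` tibble.
#' @export
signal_fs <- function(x) {
  fs <- attr(x, "fs")
  if (is.null(fs)) abort("`x` carries no sampling rate; build it with as_signal()")
  fs
}

#' @rdname as_signal
#' @export
signal_unit <- function(x) attr(x, "unit") %||% "adimensional"

# internal: pull samples from a signal tibble or accept a bare numeric vector
sig_values <- function(x) {
  if (inherits(x, "coil_signal") || is.data.frame(x)) {
    v <- x[["value"]]
    if (is.null(v)) abort("data frame has no `value` column")
    return(as.numeric(v))
  }
  as.numeric(x)
}

# internal: rebuild a signal with the same fs, new samples/unit
sig_rewrap <- function(template, value, unit = signal_unit(template)) {
  as_signal(value, fs = signal_fs(template), unit = unit)
}

#' @export
print.coil_signal <- function(x, ...) {
  cat(sprintf("<coil_signal> %d samples @ %g Hz [%s], %.2f s\n",
              nrow(x), signal_fs(x), signal_unit(x),
              nrow(x) / signal_fs(x)))
  NextMethod()
}

#' Remove the amplitude offset (mean) from a signal
#'
#' First step of the extraction chain: subtracts the sample mean so the
#' stream is centred at zero before filtering.
#'
#' @param s A `coil_signal` tibble.
#' @return The zero-mean signal, same length and unit.
#' @export
remove_offset <- function(s) {
  v <- sig_values(s)
  if (length(v) < 1L) abort("empty signal", class = "coilrate_empty")
  sig_rewrap(s, v - mean(v))
}

#' Normalize a signal to zero mean and unit peak amplitude
#'
#' Used for plotting and export: after mean removal the samples are scaled by
#' their maximum absolute value, so the result is adimensional in \[-1, 1\].
#'
#' @param s A `coil_signal` tibble; must not be constant.
#' @return Adimensional signal with zero mean and `max(abs(value)) == 1`.
#' @export
normalize_signal <- function(s) {
  v <- sig_values(s)
  v <- v - mean(v)
  m <- max(abs(v))
  if (m == 0) {
    abort("cannot normalize a constant (all-zero after mean removal) signal",
          class = "coilrate_degenerate")
  }
  sig_rewrap(s, v / m, unit = "adimensional")
}

#' @export
autoplot.coil_signal <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)",
                  y = sprintf("amplitude (%s)", signal_unit(object)))
}

#' @importFrom rlang .data
NULL
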