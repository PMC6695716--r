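#' Bland-Altman agreement between two rate series
#'
#' Classical limits-of-agreement analysis for paired measurements (e.g.
#' inductive-sensor bpm vs ECG-derived bpm per analysis window): bias is the
#' mean of the differences `a - b`, and the limits are
#' `bias +/- 1.96 * SD` with the sample (n-1) standard deviation.
#'
#' @param data A data frame holding the paired measurements.
#' @param a,b Columns (tidy-eval) with the two methods' values.
#' @return Object of class `bland_altman` with `pairs` (tibble of `a`, `b`,
#'   `mean`, `diff`), `bias`, `sd_diff`, `loa_low`, `loa_high`, `n_pairs`.
#' @examples
#' df <- tibble::tibble(coil = c(70, 72, 68), ecg = c(71, 70, 69))
#' glance(bland_altman(df, coil, ecg))
#' @export
bland_altman <- function(data, a, b) {
  va <- eval_tidy(enquo(a), data)
  vb <- eval_tidy(enquo(b), data)
  keep <- is.finite(va) & is.finite(vb)
  va <- va[keep]; vb <- vb[keep]
  if (length(va) < 2) {
    abort("need at least 2 complete pairs", class = "coilrate_range")
  }
  d <- va - vb
  bias <- mean(d)
  sd_d <- stats::sd(d)
  structure(
    list(pairs = tibble(a = va, b = vb, mean = (va + vb) / 2, diff = d),
         bias = bias, sd_diff = sd_d,
         loa_low = bias - 1.96 * sd_d, loa_high = bias + 1.96 * sd_d,
         n_pairs = length(d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n = %d, bias = %.3f, SD = %.3f, LoA [%.3f, %.3f]\n",
    x$n_pairs, x$bias, x$sd_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
tidy.bland_altman <- function(x, ...) x$pairs

#' @export
glance.bland_altman <- function(x, ...) {
  tibble(bias = x$bias, sd_diff = x$sd_diff,
         loa_low = x$loa_low, loa_high = x$loa_high, n_pairs = x$n_pairs)
}

#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(.data$mean, .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$bias, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = 2) +
    ggplot2::labs(x = "mean of methods", y = "difference (a - b)")
}

#' Write Bland-Altman statistics as CSV
#'
#' @param x A `bland_altman` object.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_agreement <- function(x, path) {
  readr::write_csv(glance(x), path)
  invisible(path)
}
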