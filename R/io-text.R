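#' Read a raw inductive sample stream from plain text
#'
#' Streams are whitespace/newline-separated non-negative integer counts.
#' Lines starting with `#` are provenance comments and are skipped. Any
#' other token fails the parse with its line number.
#'
#' @param path File path (or a connection readable by [readLines()]).
#' @param fs Sampling rate to attach (Hz), 20 by default.
#' @return A `coil_signal` of counts.
#' @export
read_inductive_text <- function(path, fs = 20) {
  lines <- readLines(path, warn = FALSE)
  values <- numeric(0)
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "" || startsWith(line, "#")) next
    tokens <- strsplit(line, "\\s+")[[1]]
    bad <- which(!grepl("^[0-9]+$", tokens))
    if (length(bad) > 0) {
      abort(sprintf("line %d: token '%s' is not a non-negative integer",
                    ln, tokens[bad[1]]),
            class = "coilrate_parse")
    }
    values <- c(values, as.numeric(tokens))
  }
  if (length(values) == 0) {
    abort("no samples found in input", class = "coilrate_empty")
  }
  as_signal(values, fs = fs, unit = "counts")
}

#' Write an inductive sample stream as plain text
#'
#' One integer count per line, preceded by `#` comment lines recording the
#' sampling rate and unit so the stream is self-describing.
#'
#' @param s A `coil_signal` of counts.
#' @param path Output file.
#' @param header Write the provenance header?
#' @return The path, invisibly.
#' @export
write_inductive_text <- function(s, path, header = TRUE) {
  v <- sig_values(s)
  lines <- format(v, scientific = FALSE, trim = TRUE)
  if (header) {
    lines <- c(sprintf("# fs_hz=%g unit=%s n=%d",
                       signal_fs(s), signal_unit(s), length(v)),
               lines)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Timestamped ECG record file names
#'
#' Records are named `YYYY_MM_DD-HH_MM_SS.xml` after their acquisition time.
#'
#' @param timestamp A `POSIXct` (or anything `format()`-able by strftime).
#' @return File name string.
#' @examples
#' make_ecg_filename(as.POSIXct("2018-07-26 14:01:20", tz = "UTC"))
#' @export
make_ecg_filename <- function(timestamp) {
  format(timestamp, "%Y_%m_%d-%H_%M_%S.xml")
}

#' @rdname make_ecg_filename
#' @param filename A name produced by `make_ecg_filename()`.
#' @param tz Time zone for the recovered timestamp.
#' @return `parse_ecg_filename()`: the `POSIXct` timestamp.
#' @export
parse_ecg_filename <- function(filename, tz = "UTC") {
  stem <- sub("\\.xml$", "", basename(filename))
  ts <- as.POSIXct(stem, format = "%Y_%m_%d-%H_%M_%S", tz = tz)
  if (is.na(ts)) abort("file name does not match YYYY_MM_DD-HH_MM_SS.xml",
                       class = "coilrate_parse")
  ts
}
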