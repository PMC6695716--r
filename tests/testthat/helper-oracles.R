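# Independent brute-force oracles: plain double loops over the printed
# definitions, kept deliberately separate from the package implementations.

brute_cxy <- function(x, y, max_lag) {
  n <- length(x)
  out <- numeric(max_lag + 1)
  for (k in 0:max_lag) {
    acc <- 0
    for (i in 1:(n - k)) acc <- acc + x[i] * y[i + k]
    out[k + 1] <- acc
  }
  out
}

brute_dxy <- function(x, y, max_lag) {
  n <- length(x)
  out <- numeric(max_lag + 1)
  for (k in 0:max_lag) {
    acc <- 0
    for (i in 1:(n - k)) acc <- acc + abs(x[i] - y[i + k])
    out[k + 1] <- acc
  }
  out
}

brute_cxx <- function(x, max_lag) brute_cxy(x, x, max_lag)

# sample-by-sample evaluation of the ARMA difference equation,
# zero initial conditions
brute_arma <- function(b, a, x) {
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in seq_along(b)) {
      if (i - k + 1 >= 1) acc <- acc + b[k] * x[i - k + 1]
    }
    for (j in seq_along(a)[-1]) {
      if (i - j + 1 >= 1) acc <- acc - a[j] * y[i - j + 1]
    }
    y[i] <- acc / a[1]
  }
  y
}

# match detected events to ground truth within a tolerance (samples);
# returns misses and false positives
match_peaks <- function(truth, detected, tol) {
  miss <- sum(!vapply(truth, function(p) any(abs(detected - p) <= tol),
                      logical(1)))
  fp <- sum(!vapply(detected, function(p) any(abs(truth - p) <= tol),
                    logical(1)))
  list(miss = miss, fp = fp)
}

dominant_freq <- function(v, fs) {
  v <- v - mean(v)
  sp <- Mod(stats::fft(v))[seq_len(floor(length(v) / 2)) + 1L]
  which.max(sp) / length(v) * fs
}
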