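#' Planar spiral coil specification
#'
#' Current-sheet description of the textile coil: layout coefficients default
#' to the standard values for each layout and can be overridden.
#'
#' @param n_turns Number of turns N (integer >= 0).
#' @param d_avg_m Average coil diameter in meters.
#' @param fill_factor Fill factor phi = (d_out - d_in) / (d_out + d_in),
#'   in \[0, 1).
#' @param layout One of `"square"`, `"hexagonal"`, `"octagonal"`, `"circular"`.
#' @param k1,k2 Layout coefficients; defaults per layout.
#' @return A list of class `coil_spec`.
#' @export
coil_spec <- function(n_turns, d_avg_m, fill_factor,
                      layout = c("square", "hexagonal", "octagonal", "circular"),
                      k1 = NULL, k2 = NULL) {
  layout <- match.arg(layout)
  defaults <- list(
    square    = c(2.34, 2.75),
    hexagonal = c(2.33, 3.82),
    octagonal = c(2.25, 3.55),
    circular  = c(2.25, 3.55)
  )[[layout]]
  k1 <- k1 %||% defaults[1]
  k2 <- k2 %||% defaults[2]
  if (n_turns < 0 || n_turns != round(n_turns)) abort("`n_turns` must be a non-negative integer")
  if (!(fill_factor >= 0 && fill_factor < 1)) abort("`fill_factor` must be in [0, 1)")
  if (!(k1 > 0 && k2 > 0)) abort("layout coefficients must be positive")
  if (d_avg_m <= 0) abort("`d_avg_m` must be positive")
  structure(list(n_turns = as.integer(n_turns), d_avg_m = d_avg_m,
                 fill_factor = fill_factor, layout = layout, k1 = k1, k2 = k2),
            class = "coil_spec")
}

MU0 <- 4e-7 * pi  # vacuum permeability, H/m

#' Inductance of a planar spiral coil
#'
#' Current-sheet approximation
#' `L = k1 * mu0 * N^2 * D_avg / (1 + k2 * phi)`, evaluated strictly in SI
#' units (henries, meters).
#'
#' @param coil A [coil_spec()].
#' @return Inductance in henries.
#' @examples
#' spiral_inductance(coil_spec(10, 20e-3, 0.5, "square"))  # ~2.48e-06 H
#' @export
spiral_inductance <- function(coil) {
  stopifnot(inherits(coil, "coil_spec"))
  coil$k1 * MU0 * coil$n_turns^2 * coil$d_avg_m / (1 + coil$k2 * coil$fill_factor)
}

#' Chest displacement to inductance modulation
#'
#' First-order model of the proximity effect: tissue is diamagnetic, so the
#' coil inductance drops as the chest wall approaches the sensor.
#' `L(t) = baseline - sensitivity * displacement(t)`.
#'
#' @param displacement A `coil_signal` in meters (positive towards the coil).
#' @param baseline_h Resting inductance in henries (> 0).
#' @param sensitivity_h_per_m Henries of inductance change per meter of
#'   approach (> 0).
#' @return Signal of inductance values (henries).
#' @export
modulate_inductance <- function(displacement, baseline_h, sensitivity_h_per_m) {
  if (!(baseline_h > 0)) abort("`baseline_h` must be positive")
  if (!(sensitivity_h_per_m > 0)) abort("`sensitivity_h_per_m` must be positive")
  l <- baseline_h - sensitivity_h_per_m * sig_values(displacement)
  if (any(l <= 0)) {
    abort("displacement drives the modelled inductance to zero or below",
          class = "coilrate_range")
  }
  sig_rewrap(displacement, l, unit = "henry")
}

#' Quantize an inductance signal to 16-bit converter counts
#'
#' Affine map of `[full_scale[1], full_scale[2]]` onto integer counts
#' 0..65535 with round-half-even, mirroring keeping the 16 most significant
#' bits of the converter output.
#'
#' @param l Signal of inductances (henries).
#' @param full_scale Length-2 numeric, `c(Lmin, Lmax)` with `Lmin < Lmax`.
#' @return Signal of integer counts (unit `"counts"`).
#' @export
quantize_counts <- function(l, full_scale) {
  if (length(full_scale) != 2L || !(full_scale[1] < full_scale[2])) {
    abort("`full_scale` must be c(Lmin, Lmax) with Lmin < Lmax")
  }
  v <- sig_values(l)
  if (any(v < full_scale[1] | v > full_scale[2])) {
    abort("inductance sample outside the converter full scale",
          class = "coilrate_range")
  }
  counts <- round((v - full_scale[1]) / diff(full_scale) * 65535)
  sig_rewrap(l, counts, unit = "counts")
}

#' @rdname quantize_counts
#' @param counts Signal of counts.
#' @return `dequantize_counts()`: signal of henries (mid-step reconstruction).
#' @export
dequantize_counts <- function(counts, full_scale) {
  v <- sig_values(counts)
  l <- full_scale[1] + v / 65535 * diff(full_scale)
  sig_rewrap(counts, l, unit = "henry")
}
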