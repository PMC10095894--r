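#' Construct a titration series
#'
#' A titration series is the unit of analysis: one fluorescence titration of a
#' fixed protein concentration against increasing total quencher (ligand)
#' concentration, at one temperature and under one condition (free protein or
#' protein pre-incubated with a site marker). The first point must be the
#' quencher-free measurement, which defines `F0`.
#'
#' @param condition condition label; one of `"free"`, `"warfarin"`,
#'   `"ibuprofen"`, `"hemin"`, `"warfarin+hemin"`, or a custom string.
#' @param temperature_C temperature in degrees Celsius.
#' @param points a data frame with columns `quencher_M` (total quencher,
#'   mol/L) and `intensity` (fluorescence, arbitrary units), optionally
#'   `absorbance_ex` and `absorbance_em` (absorbance at the excitation and
#'   emission wavelengths, AU). Rows are sorted by `quencher_M` on
#'   construction, so input order does not matter.
#' @param protein_conc_M total protein concentration, mol/L.
#' @return an object of class `titration_series`.
#' @examples
#' ts <- titration_series("free", 25,
#'   tibble::tibble(quencher_M = c(0, 1e-6, 2e-6), intensity = c(100, 80, 65)))
#' ts
#' @export
titration_series <- function(condition, temperature_C, points,
                             protein_conc_M = 3e-6) {
  stopifnot(is.character(condition), length(condition) == 1L)
  stopifnot(is.numeric(temperature_C), length(temperature_C) == 1L)
  points <- tibble::as_tibble(points)
  required <- c("quencher_M", "intensity")
  missing_cols <- setdiff(required, names(points))
  if (length(missing_cols) > 0L) {
    stop("titration points are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  points <- points[order(points$quencher_M), , drop = FALSE]
  obj <- structure(
    list(condition = condition,
         temperature_C = temperature_C,
         protein_conc_M = protein_conc_M,
         points = points),
    class = "titration_series")
  validate_titration_series(obj)
}

#' Validate a titration series
#'
#' Checks the invariants the downstream analysis relies on: non-negative,
#' strictly increasing quencher concentrations; strictly positive, finite
#' intensities; and the presence of a zero-quencher point defining `F0`.
#'
#' @param x a `titration_series`.
#' @return `x`, invisibly validated (returned unchanged on success).
#' @export
validate_titration_series <- function(x) {
  p <- x$points
  if (nrow(p) < 1L) stop("titration series has no points", call. = FALSE)
  if (any(!is.finite(p$quencher_M)) || any(p$quencher_M < 0)) {
    stop("quencher concentrations must be finite and >= 0", call. = FALSE)
  }
  if (any(duplicated(p$quencher_M))) {
    stop("duplicate quencher concentration in series '", x$condition,
         "' at ", x$temperature_C, " degC; duplicates are an error, not averaged",
         call. = FALSE)
  }
  if (p$quencher_M[1L] != 0) {
    stop("titration series '", x$condition, "' at ", x$temperature_C,
         " degC has no zero-quencher point; F0 is undefined", call. = FALSE)
  }
  if (any(!is.finite(p$intensity)) || any(p$intensity <= 0)) {
    stop("intensities must be finite and > 0", call. = FALSE)
  }
  for (col in c("absorbance_ex", "absorbance_em")) {
    if (col %in% names(p) && any(stats::na.omit(p[[col]]) < 0)) {
      stop(col, " must be >= 0", call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration_series> condition '%s', %.4g degC, [P] = %.3g M, %d points\n",
              x$condition, x$temperature_C, x$protein_conc_M, nrow(x$points)))
  cat(sprintf("  [Q] %.3g to %.3g M, F0 = %.6g\n",
              min(x$points$quencher_M), max(x$points$quencher_M), f_zero(x)))
  invisible(x)
}

#' Unquenched intensity of a series
#'
#' @param series a `titration_series`.
#' @return the intensity at zero quencher (`F0`).
#' @export
f_zero <- function(series) {
  series$points$intensity[series$points$quencher_M == 0][1L]
}

#' Construct an emission spectrum
#'
#' A single emission scan: intensities on a strictly increasing wavelength
#' grid. Used to reduce spectral (long-format) input to a single analysis
#' intensity per titration point.
#'
#' @param wavelength_nm emission wavelengths, nm, strictly increasing.
#' @param intensity fluorescence intensities, same length, finite and >= 0.
#' @param temperature_C temperature, degrees Celsius (optional metadata).
#' @param excitation_nm excitation wavelength, nm (optional metadata).
#' @return an object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelength_nm, intensity, temperature_C = NA_real_,
                              excitation_nm = NA_real_) {
  if (length(wavelength_nm) != length(intensity)) {
    stop("wavelength and intensity must have the same length", call. = FALSE)
  }
  if (length(wavelength_nm) < 2L) stop("spectrum needs >= 2 points", call. = FALSE)
  if (any(diff(wavelength_nm) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("intensities must be finite and >= 0", call. = FALSE)
  }
  structure(list(wavelength_nm = as.numeric(wavelength_nm),
                 intensity = as.numeric(intensity),
                 temperature_C = temperature_C,
                 excitation_nm = excitation_nm),
            class = "emission_spectrum")
}

#' Intensity of an emission spectrum at a wavelength
#'
#' Linear interpolation at a fixed wavelength, or the band maximum with
#' `wavelength = "peak"`. Fixed-wavelength reduction (default 340 nm at the
#' analysis layer, the tryptophan emission maximum) is reproducible under
#' band shifts; peak mode follows the maximum.
#'
#' @param spectrum an `emission_spectrum`.
#' @param wavelength a wavelength in nm inside the spectral range, or
#'   `"peak"` for the maximum intensity.
#' @return a single intensity.
#' @export
intensity_at <- function(spectrum, wavelength = "peak") {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  if (identical(wavelength, "peak")) {
    return(max(spectrum$intensity))
  }
  stopifnot(is.numeric(wavelength), length(wavelength) == 1L)
  rng <- range(spectrum$wavelength_nm)
  if (wavelength < rng[1L] || wavelength > rng[2L]) {
    stop(sprintf("wavelength %.6g nm outside spectral range [%.6g, %.6g]",
                 wavelength, rng[1L], rng[2L]), call. = FALSE)
  }
  stats::approx(spectrum$wavelength_nm, spectrum$intensity,
                xout = wavelength, method = "linear")$y
}
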