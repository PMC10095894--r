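#' Inner filter effect correction factor
#'
#' Attenuation of both the excitation beam and the emitted light by absorbing
#' species in the cuvette biases observed fluorescence downward. For a 1 cm
#' cuvette with centred observation the standard path-averaged correction is
#' `F_corr = F_obs * 10^((A_ex + A_em) / 2)`, where `A_ex` and `A_em` are the
#' solution absorbances at the excitation and emission wavelengths.
#'
#' @param absorbance_ex absorbance at the excitation wavelength, AU (>= 0).
#' @param absorbance_em absorbance at the emission wavelength, AU (>= 0).
#' @param path_weight weight on the summed absorbances; 0.5 is the
#'   half-path-length average for a standard right-angle geometry.
#' @param ceiling absorbance above which the correction is considered
#'   unreliable; exceeding it raises a warning (the factor is still
#'   returned).
#' @return the multiplicative correction factor(s), always >= 1, with an
#'   `unreliable` attribute flagging points beyond the ceiling.
#' @examples
#' ife_factor(0, 0)        # 1: nothing absorbs, nothing to correct
#' ife_factor(0.1, 0.1)    # 10^0.1
#' @export
ife_factor <- function(absorbance_ex, absorbance_em, path_weight = 0.5,
                       ceiling = 2) {
  if (any(!is.finite(absorbance_ex)) || any(!is.finite(absorbance_em)) ||
      any(absorbance_ex < 0) || any(absorbance_em < 0)) {
    stop("absorbances must be finite and >= 0", call. = FALSE)
  }
  unreliable <- absorbance_ex > ceiling | absorbance_em > ceiling
  if (any(unreliable)) {
    warning("absorbance above ", ceiling,
            " AU: inner filter correction unreliable", call. = FALSE)
  }
  out <- 10^(path_weight * (absorbance_ex + absorbance_em))
  attr(out, "unreliable") <- unreliable
  out
}

#' Correct a titration series for the inner filter effect
#'
#' Multiplies every observed intensity (including the zero-quencher `F0`,
#' with its own absorbance pair) by its [ife_factor()]. Absorbances are
#' taken from the per-point `absorbance_ex`/`absorbance_em` columns when
#' present; otherwise a linear absorbance model
#' `A = epsilon * [Q] + baseline` may be supplied (extinction coefficients
#' in L mol^-1 cm^-1).
#'
#' @param series a [titration_series].
#' @param epsilon_ex,epsilon_em quencher extinction coefficients at the
#'   excitation and emission wavelengths, used only when the series carries
#'   no absorbance columns.
#' @param baseline_ex,baseline_em constant absorbance offsets for the linear
#'   model (e.g. protein absorbance at the excitation wavelength).
#' @param path_weight passed to [ife_factor()].
#' @param ceiling passed to [ife_factor()].
#' @return the corrected [titration_series]; ordering and condition are
#'   preserved and an attribute `ife_corrected` is set.
#' @export
correct_series <- function(series, epsilon_ex = NULL, epsilon_em = NULL,
                           baseline_ex = 0, baseline_em = 0,
                           path_weight = 0.5, ceiling = 2) {
  stopifnot(inherits(series, "titration_series"))
  p <- series$points
  has_cols <- all(c("absorbance_ex", "absorbance_em") %in% names(p)) &&
    !anyNA(p$absorbance_ex) && !anyNA(p$absorbance_em)
  if (has_cols) {
    a_ex <- p$absorbance_ex
    a_em <- p$absorbance_em
  } else if (!is.null(epsilon_ex) && !is.null(epsilon_em)) {
    a_ex <- epsilon_ex * p$quencher_M + baseline_ex
    a_em <- epsilon_em * p$quencher_M + baseline_em
  } else {
    stop("no absorbances on the series and no linear absorbance model ",
         "(epsilon_ex/epsilon_em) supplied", call. = FALSE)
  }
  series$points$intensity <- p$intensity *
    as.numeric(ife_factor(a_ex, a_em, path_weight = path_weight,
                          ceiling = ceiling))
  attr(series, "ife_corrected") <- TRUE
  validate_titration_series(series)
  series
}
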