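#' Stern-Volmer ratios of a titration series
#'
#' Computes the ordered pairs `([Q], F0/F)` that the Stern-Volmer analysis is
#' built on. The series should already be corrected for the inner filter
#' effect where absorbances are available (see [correct_series()]).
#'
#' @param series a [titration_series].
#' @return a tibble with columns `quencher_M` and `ratio`; the first row is
#'   `(0, 1)` by construction.
#' @export
sv_ratios <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  p <- series$points
  if (nrow(p) < 3L) {
    stop("need at least 3 titration points for Stern-Volmer analysis",
         call. = FALSE)
  }
  if (any(p$intensity <= 0)) stop("intensities must be > 0", call. = FALSE)
  tibble::tibble(quencher_M = p$quencher_M,
                 ratio = f_zero(series) / p$intensity)
}

#' Stern-Volmer segmented fit of a series
#'
#' Convenience wrapper: computes [sv_ratios()] and runs [fit_piecewise()].
#' Downward curvature (a shallower second segment) is the only two-site
#' signature admitted for Stern-Volmer data; if the selected two-regime model
#' has `slope2 >= slope1` (an upward kink) it is demoted to the single line.
#'
#' @param series a [titration_series].
#' @param min_segment,alpha passed to [fit_piecewise()].
#' @return a `piecewise_fit` of `F0/F` against `[Q]`.
#' @export
sv_fit <- function(series, min_segment = 3, alpha = 0.05) {
  pts <- sv_ratios(series)
  fit <- fit_piecewise(pts$quencher_M, pts$ratio,
                       min_segment = min_segment, alpha = alpha)
  if (fit$two_segment && fit$slope2 >= fit$slope1) fit <- .as_single_fit(fit)
  fit
}

#' Quenching constants from a Stern-Volmer fit
#'
#' Per-segment Stern-Volmer constants `K_SV` are the fitted slopes; the
#' bimolecular quenching constant is `K_q = K_SV / tau0` with `tau0` the
#' unquenched fluorophore lifetime. `K_q` far above the diffusion-controlled
#' limit (~1e10 L mol^-1 s^-1) indicates static, complex-forming quenching.
#'
#' @param fit a `piecewise_fit` of Stern-Volmer ratios (see [sv_fit()]).
#' @param tau0 unquenched fluorophore lifetime in seconds (default 5.9 ns,
#'   the HSA tryptophan lifetime).
#' @return an object of class `quenching_result`: `ksv1`, `ksv2` (`NA` for a
#'   single line), `kq1`, `kq2`, `tau0`, `mechanism` (filled by
#'   [classify_mechanism()], `"indeterminate"` until then), and `fit`.
#' @export
quenching_constants <- function(fit, tau0 = .TAU0_DEFAULT) {
  stopifnot(inherits(fit, "piecewise_fit"))
  if (!is.numeric(tau0) || tau0 <= 0) stop("tau0 must be > 0", call. = FALSE)
  if (fit$two_segment && fit$slope2 >= fit$slope1) fit <- .as_single_fit(fit)
  if (fit$slope1 <= 0) {
    stop("non-positive Stern-Volmer slope: the ligand does not quench",
         call. = FALSE)
  }
  ksv1 <- fit$slope1
  ksv2 <- if (fit$two_segment) fit$slope2 else NA_real_
  if (fit$two_segment && ksv2 <= 0) {
    stop("non-positive second-segment Stern-Volmer slope", call. = FALSE)
  }
  structure(list(
    ksv1 = ksv1, ksv2 = ksv2,
    kq1 = ksv1 / tau0, kq2 = ksv2 / tau0,
    tau0 = tau0,
    mechanism = "indeterminate",
    fit = fit),
    class = "quenching_result")
}

#' @export
print.quenching_result <- function(x, ...) {
  cat(sprintf("<quenching_result> KSV1 = %.4g L/mol (Kq1 = %.4g L/mol/s)\n",
              x$ksv1, x$kq1))
  if (!is.na(x$ksv2)) {
    cat(sprintf("  KSV2 = %.4g L/mol (Kq2 = %.4g L/mol/s)\n", x$ksv2, x$kq2))
  }
  cat(sprintf("  tau0 = %.3g s, mechanism: %s\n", x$tau0, x$mechanism))
  invisible(x)
}

#' Classify the quenching mechanism from a temperature ladder
#'
#' Static (ground-state complex) quenching shows `K_SV` decreasing with
#' temperature and apparent `K_q` far above the diffusion limit; collisional
#' (dynamic) quenching shows the converse. Anything else is reported as
#' indeterminate rather than forced into a class.
#'
#' @param results_by_temperature a list of `quenching_result` named by
#'   temperature (any unit with the correct ordering; degrees Celsius in the
#'   standard pipeline).
#' @param diffusion_limit diffusion-controlled quenching limit,
#'   L mol^-1 s^-1.
#' @return `"static"`, `"dynamic"` or `"indeterminate"`.
#' @export
classify_mechanism <- function(results_by_temperature,
                               diffusion_limit = .DIFFUSION_LIMIT) {
  stopifnot(is.list(results_by_temperature))
  temps <- suppressWarnings(as.numeric(names(results_by_temperature)))
  if (length(results_by_temperature) < 2L || anyNA(temps)) {
    warning("mechanism classification needs results at >= 2 temperatures",
            call. = FALSE)
    return("indeterminate")
  }
  ord <- order(temps)
  ksv1 <- vapply(results_by_temperature[ord], function(r) r$ksv1, numeric(1L))
  kq1 <- vapply(results_by_temperature[ord], function(r) r$kq1, numeric(1L))
  decreasing <- all(diff(ksv1) < 0)
  increasing <- all(diff(ksv1) > 0)
  if (decreasing && all(kq1 > diffusion_limit)) return("static")
  if (increasing && all(kq1 <= diffusion_limit)) return("dynamic")
  "indeterminate"
}
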