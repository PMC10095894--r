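#' Double-logarithmic binding coordinates
#'
#' For static quenching the double-log relation
#' `log10((F0 - F)/F) = log10(kb) + n * log10([Q])` linearises the binding
#' isotherm: the intercept gives the binding constant and the slope the
#' apparent number of binding sites. Points that cannot enter the transform
#' are dropped: the zero-quencher point (log of zero), points with `F >= F0`
#' (no quenching; warned about), and points with `(F0 - F)/F` below
#' `quench_floor`, where the log of near-zero quenching is numerically
#' meaningless (warned about).
#'
#' @param series a [titration_series] (corrected upstream when applicable).
#' @param quench_floor minimum relative quenching `(F0 - F)/F` a point must
#'   show to be usable (default `1e-3`).
#' @return a tibble with columns `log_quencher` and `log_ratio`
#'   (base-10 logs).
#' @export
double_log_points <- function(series, quench_floor = 1e-3) {
  stopifnot(inherits(series, "titration_series"))
  p <- series$points
  F0 <- f_zero(series)
  q <- p$quencher_M
  r <- (F0 - p$intensity) / p$intensity

  usable <- q > 0
  unquenched <- usable & r <= 0
  if (any(unquenched)) {
    warning(sum(unquenched), " point(s) with F >= F0 excluded from the ",
            "double-log analysis", call. = FALSE)
  }
  below_floor <- usable & r > 0 & r < quench_floor
  if (any(below_floor)) {
    warning(sum(below_floor), " point(s) with relative quenching below ",
            quench_floor, " excluded from the double-log analysis",
            call. = FALSE)
  }
  keep <- usable & r >= quench_floor
  if (sum(keep) < 3L) {
    stop("fewer than 3 usable points for the double-log analysis",
         call. = FALSE)
  }
  tibble::tibble(log_quencher = log10(q[keep]), log_ratio = log10(r[keep]))
}

#' Binding constants and site numbers from the double-log plot
#'
#' Runs the segmented fit on double-log coordinates and transforms each
#' segment back: `kb = 10^intercept`, `n = slope`. Segment 1 is the
#' low-concentration block and describes the primary (high-affinity) site;
#' segment 2 the secondary site. A two-regime fit whose back-transformed
#' constants violate `kb1 > kb2` does not describe a primary/secondary site
#' pair and is demoted to the single line with a warning.
#'
#' `kb` is reported in L/mol even when `n != 1` (formally `(L/mol)^n`); `n`
#' is carried alongside.
#'
#' Both diagnostic plots of one titration — Stern-Volmer and double-log —
#' reflect the same two occupancy regimes, and the Stern-Volmer scale is far
#' better conditioned at low quenching than the log-log scale. The pipeline
#' therefore parts the double-log points at the concentration where the
#' Stern-Volmer fit found its breakpoint, by passing `breakpoint_x`; called
#' without it, the function selects the split itself via [fit_piecewise()].
#'
#' @param points a tibble from [double_log_points()] (or any two-column
#'   data frame of base-10 log coordinates).
#' @param min_segment,alpha passed to [fit_piecewise()].
#' @param breakpoint_x optional fixed split position on the `log10([Q])`
#'   axis: points at or below it form the primary-site segment. Ignored
#'   (with fallback to free selection) when either side would keep fewer
#'   than 2 points.
#' @return an object of class `binding_result`: `kb1`, `kb2`, `n1`, `n2`
#'   (`NA` where absent) and the underlying `fit`.
#' @export
fit_binding <- function(points, min_segment = 3, alpha = 0.05,
                        breakpoint_x = NULL) {
  points <- as.data.frame(points)
  stopifnot(ncol(points) >= 2L)
  fit <- NULL
  if (!is.null(breakpoint_x)) {
    k <- sum(points[[1L]] <= breakpoint_x)
    if (k >= 2L && nrow(points) - k >= 2L) {
      fit <- .fixed_breakpoint_fit(points[[1L]], points[[2L]], k)
    }
  }
  if (is.null(fit)) {
    fit <- fit_piecewise(points[[1L]], points[[2L]],
                         min_segment = min_segment, alpha = alpha)
  }
  if (fit$two_segment && 10^fit$intercept1 <= 10^fit$intercept2) {
    warning("two-regime double-log fit without kb1 > kb2; ",
            "reporting the single-line fit", call. = FALSE)
    fit <- .as_single_fit(fit)
  }
  kb1 <- 10^fit$intercept1
  n1 <- fit$slope1
  kb2 <- if (fit$two_segment) 10^fit$intercept2 else NA_real_
  n2 <- if (fit$two_segment) fit$slope2 else NA_real_
  if (!is.finite(kb1) || kb1 <= 0 || n1 <= 0) {
    stop("degenerate binding fit (kb or n not positive)", call. = FALSE)
  }
  structure(list(kb1 = kb1, kb2 = kb2, n1 = n1, n2 = n2, fit = fit),
            class = "binding_result")
}

#' @export
print.binding_result <- function(x, ...) {
  cat(sprintf("<binding_result> kb1 = %.4g L/mol, n1 = %.3f\n", x$kb1, x$n1))
  if (!is.na(x$kb2)) {
    cat(sprintf("  kb2 = %.4g L/mol, n2 = %.3f\n", x$kb2, x$n2))
  }
  invisible(x)
}
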