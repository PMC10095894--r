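# Ordinary least squares of y on x for one segment; NULL if x is degenerate.
.ols_line <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx <= 0) return(NULL)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  syy <- sum((y - my)^2)
  list(slope = slope, intercept = intercept, sse = sum(res^2),
       r2 = if (syy > 0) 1 - sum(res^2) / syy else 1)
}

#' Segmented (one- or two-regime) linear fit with exhaustive breakpoint search
#'
#' Fits `y` against `x` either as a single straight line or as two lines split
#' at a breakpoint between observed abscissae. Every admissible breakpoint
#' (each segment keeping at least `min_segment` points) is evaluated; both
#' blocks are fit by ordinary least squares with free intercepts and the
#' breakpoint minimising the total sum of squared errors is selected, ties
#' going to the earlier breakpoint so the result is deterministic. The
#' two-regime model is accepted only when it survives an extra-parameters
#' F-test (2 extra parameters) against the single line at level `alpha`; the
#' p-value is Bonferroni-corrected for the number of breakpoints searched,
#' which keeps the false two-regime rate on straight-line data at the nominal
#' level despite the best-of-many selection.
#'
#' With at most a dozen titration points the exhaustive search is exact and
#' cheap; no continuous breakpoint optimisation is attempted.
#'
#' @param x strictly increasing abscissae.
#' @param y ordinates, same length.
#' @param min_segment minimum number of points per segment (default 3).
#' @param alpha significance level for accepting the two-regime model.
#' @return an object of class `piecewise_fit` with elements
#'   `two_segment`, `breakpoint_index` (last point of the first segment; `NA`
#'   for a single line), `breakpoint_x`, `slope1`, `intercept1`, `slope2`,
#'   `intercept2`, `r2_segment1`, `r2_segment2`, `sse_total`, `f_statistic`,
#'   `p_value`, `n_points`, and `single` (the single-line fit, always
#'   available for fallback).
#' @export
fit_piecewise <- function(x, y, min_segment = 3, alpha = 0.05) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have the same length", call. = FALSE)
  if (n < min_segment) {
    stop("need at least ", min_segment, " points, got ", n, call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("x and y must be finite", call. = FALSE)
  }
  if (any(diff(x) <= 0)) {
    stop("x must be strictly increasing (degenerate or unsorted abscissae)",
         call. = FALSE)
  }

  single <- .ols_line(x, y)
  if (is.null(single)) stop("zero variance in x", call. = FALSE)

  best <- NULL
  n_candidates <- 0L
  if (n >= 2L * min_segment) {
    for (k in seq.int(min_segment, n - min_segment)) {
      left <- .ols_line(x[seq_len(k)], y[seq_len(k)])
      right <- .ols_line(x[seq.int(k + 1L, n)], y[seq.int(k + 1L, n)])
      if (is.null(left) || is.null(right)) next
      n_candidates <- n_candidates + 1L
      sse <- left$sse + right$sse
      if (is.null(best) || sse < best$sse) {
        best <- list(k = k, left = left, right = right, sse = sse)
      }
    }
  }

  # Scale for "perfectly collinear": residuals negligible against the spread
  # of y (or against y itself for constant data).
  tol <- 1e-18 * max(sum((y - mean(y))^2), sum(y^2), .Machine$double.xmin)

  f_statistic <- NA_real_
  p_value <- NA_real_
  two_segment <- FALSE
  if (!is.null(best) && single$sse > tol) {
    if (best$sse <= tol) {
      f_statistic <- Inf
      p_value <- 0
    } else {
      f_statistic <- ((single$sse - best$sse) / 2) / (best$sse / (n - 4))
      p_value <- min(1, n_candidates *
                       stats::pf(f_statistic, 2, n - 4, lower.tail = FALSE))
    }
    two_segment <- p_value < alpha
  }

  cand_k <- if (!is.null(best)) best$k else NA_integer_
  cand_sse <- if (!is.null(best)) best$sse else NA_real_
  if (two_segment) {
    structure(list(
      two_segment = TRUE,
      candidate_breakpoint = cand_k, candidate_sse = cand_sse,
      breakpoint_index = best$k,
      breakpoint_x = x[best$k],
      slope1 = best$left$slope, intercept1 = best$left$intercept,
      slope2 = best$right$slope, intercept2 = best$right$intercept,
      r2_segment1 = best$left$r2, r2_segment2 = best$right$r2,
      sse_total = best$sse,
      f_statistic = f_statistic, p_value = p_value,
      n_points = n,
      single = single,
      x = x, y = y),
      class = "piecewise_fit")
  } else {
    structure(list(
      two_segment = FALSE,
      candidate_breakpoint = cand_k, candidate_sse = cand_sse,
      breakpoint_index = NA_integer_,
      breakpoint_x = NA_real_,
      slope1 = single$slope, intercept1 = single$intercept,
      slope2 = NA_real_, intercept2 = NA_real_,
      r2_segment1 = single$r2, r2_segment2 = NA_real_,
      sse_total = single$sse,
      f_statistic = f_statistic, p_value = p_value,
      n_points = n,
      single = single,
      x = x, y = y),
      class = "piecewise_fit")
  }
}

# Demote a two-segment fit to its single-line version (used when a layer
# rejects the two-regime interpretation, e.g. an upward kink where downward
# curvature is the only admissible two-site signature).
.as_single_fit <- function(fit) {
  s <- fit$single
  structure(list(
    two_segment = FALSE,
    breakpoint_index = NA_integer_, breakpoint_x = NA_real_,
    slope1 = s$slope, intercept1 = s$intercept,
    slope2 = NA_real_, intercept2 = NA_real_,
    r2_segment1 = s$r2, r2_segment2 = NA_real_,
    sse_total = s$sse,
    f_statistic = fit$f_statistic, p_value = fit$p_value,
    n_points = fit$n_points, single = s,
    x = fit$x, y = fit$y),
    class = "piecewise_fit")
}

# Two-segment fit with the split position fixed from outside (e.g. carried
# over from the Stern-Volmer segmentation of the same titration). k is the
# number of points in the first segment.
.fixed_breakpoint_fit <- function(x, y, k) {
  n <- length(x)
  stopifnot(k >= 2L, n - k >= 2L)
  left <- .ols_line(x[seq_len(k)], y[seq_len(k)])
  right <- .ols_line(x[seq.int(k + 1L, n)], y[seq.int(k + 1L, n)])
  if (is.null(left) || is.null(right)) {
    stop("degenerate abscissae in a fixed-breakpoint segment", call. = FALSE)
  }
  single <- .ols_line(x, y)
  structure(list(
    two_segment = TRUE,
    breakpoint_index = as.integer(k),
    breakpoint_x = x[k],
    slope1 = left$slope, intercept1 = left$intercept,
    slope2 = right$slope, intercept2 = right$intercept,
    r2_segment1 = left$r2, r2_segment2 = right$r2,
    sse_total = left$sse + right$sse,
    f_statistic = NA_real_, p_value = NA_real_,
    n_points = n, single = single,
    x = x, y = y),
    class = "piecewise_fit")
}

#' @export
print.piecewise_fit <- function(x, ...) {
  if (x$two_segment) {
    cat(sprintf("<piecewise_fit> two segments, breakpoint after point %d (x = %.4g)\n",
                x$breakpoint_index, x$breakpoint_x))
    cat(sprintf("  segment 1: slope %.6g, intercept %.6g (R2 = %.4f)\n",
                x$slope1, x$intercept1, x$r2_segment1))
    cat(sprintf("  segment 2: slope %.6g, intercept %.6g (R2 = %.4f)\n",
                x$slope2, x$intercept2, x$r2_segment2))
  } else {
    cat(sprintf("<piecewise_fit> single line: slope %.6g, intercept %.6g (R2 = %.4f)\n",
                x$slope1, x$intercept1, x$r2_segment1))
  }
  if (is.finite(x$p_value)) {
    cat(sprintf("  two-regime F = %.4g, corrected p = %.4g\n",
                x$f_statistic, x$p_value))
  }
  invisible(x)
}
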