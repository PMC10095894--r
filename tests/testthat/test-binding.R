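test_that("a perfect single-site isotherm linearises with slope 1 and intercept log10(K)", {
  K <- 5.9e5
  s <- single_site_series(K)
  pts <- double_log_points(s)
  expect_equal(nrow(pts), 10L)  # zero-quencher point excluded
  # exactly collinear: (F0 - F)/F = K [Q]
  fit <- fit_piecewise(pts$log_quencher, pts$log_ratio)
  expect_false(fit$two_segment)
  expect_equal(fit$slope1, 1, tolerance = 1e-10)
  expect_equal(fit$intercept1, log10(5.9e5), tolerance = 1e-10)
  expect_equal(fit$intercept1, 5.77085201164214, tolerance = 1e-10)

  b <- fit_binding(pts)
  expect_equal(b$kb1, K, tolerance = 1e-9)
  expect_equal(b$n1, 1, tolerance = 1e-10)
  expect_true(is.na(b$kb2))
})

test_that("unquenched and sub-floor points are excluded with warnings", {
  s <- titration_series("free", 25, tibble::tibble(
    quencher_M = c(0, 1e-6, 2e-6, 3e-6, 4e-6, 5e-6),
    intensity = c(1000, 1001, 999.9999, 800, 700, 600)))
  expect_warning(expect_warning(pts <- double_log_points(s), "F >= F0"),
                 "below")
  expect_equal(nrow(pts), 3L)

  few <- titration_series("free", 25, tibble::tibble(
    quencher_M = c(0, 1e-6, 2e-6), intensity = c(1000, 1005, 1002)))
  expect_error(suppressWarnings(double_log_points(few)), "fewer than 3")
})

test_that("kb estimates are invariant to uniform intensity scaling", {
  gt <- ground_truth(noise_cv = 0)
  s <- correct_series(simulate_series(gt, "free", 25))
  scaled <- s
  scaled$points$intensity <- 41.3 * s$points$intensity
  b1 <- fit_binding(double_log_points(s))
  b2 <- fit_binding(double_log_points(scaled))
  expect_equal(b2$kb1, b1$kb1)
  expect_equal(b2$n1, b1$n1)
})

test_that("noiseless two-site output orders the sites correctly", {
  gt <- ground_truth(noise_cv = 0)
  s <- correct_series(simulate_series(gt, "free", 25))
  b <- fit_binding(double_log_points(s))
  expect_true(b$fit$two_segment)
  expect_gt(b$kb1, b$kb2)
  expect_gt(b$n1, b$n2)
})

test_that("primary-segment assignment is stable under added high-concentration points", {
  # two exact log-log regimes; extending the second block must not move the
  # first segment's parameters
  lx <- log10(seq(1e-6, 10e-6, 1e-6))
  ly <- ifelse(lx <= log10(4e-6), 5.7 + 1.0 * (lx + 6), 4.9 + 0.6 * (lx + 6))
  base <- fit_binding(tibble::tibble(lx, ly))
  more_x <- c(lx, log10(c(12e-6, 15e-6)))
  more_y <- c(ly, 4.9 + 0.6 * (more_x[11:12] + 6))
  extended <- fit_binding(tibble::tibble(more_x, more_y))
  expect_equal(extended$fit$breakpoint_index, base$fit$breakpoint_index)
  expect_equal(extended$kb1, base$kb1, tolerance = 1e-9)
  expect_equal(extended$n1, base$n1, tolerance = 1e-9)
})

test_that("a fixed breakpoint carried from the Stern-Volmer fit is honoured", {
  lx <- log10(seq(1e-6, 10e-6, 1e-6))
  ly <- ifelse(lx <= log10(5e-6), 5.7 + 1.0 * (lx + 6), 5.0 + 0.6 * (lx + 6))
  forced <- fit_binding(tibble::tibble(lx, ly), breakpoint_x = log10(5e-6))
  expect_true(forced$fit$two_segment)
  expect_equal(forced$fit$breakpoint_index, 5L)
  # an unusable split (too few points on one side) falls back to free search
  fallback <- fit_binding(tibble::tibble(lx, ly), breakpoint_x = log10(9.5e-6))
  expect_equal(fallback$fit$breakpoint_index,
               fit_binding(tibble::tibble(lx, ly))$fit$breakpoint_index)
})
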