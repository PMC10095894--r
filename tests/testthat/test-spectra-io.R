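test_that("summary CSV parses to one validated series per condition/temperature", {
  q <- seq(0, 10e-6, 1e-6)
  f <- 1000 / (1 + 3e5 * q)
  txt <- titration_csv_text(q, f)
  series <- read_titration_csv(I(txt))
  expect_length(series, 1L)
  s <- series[[1L]]
  expect_s3_class(s, "titration_series")
  expect_equal(nrow(s$points), 11L)
  expect_equal(s$condition, "free")
  expect_equal(s$temperature_C, 25)
  expect_equal(s$points$quencher_M, q)
  expect_equal(f_zero(s), 1000)
})

test_that("parsing is invariant to row order", {
  q <- seq(0, 10e-6, 1e-6)
  f <- 1000 / (1 + 3e5 * q)
  set.seed(11)
  perm <- sample(seq_along(q))
  sorted <- read_titration_csv(I(titration_csv_text(q, f)))
  shuffled <- read_titration_csv(I(titration_csv_text(q[perm], f[perm])))
  expect_equal(shuffled, sorted)
})

test_that("malformed titration input is rejected with a named reason", {
  q <- seq(0, 5e-6, 1e-6)
  f <- 1000 / (1 + 3e5 * q)
  # missing required column, named in the error
  bad <- sub("intensity", "signal", titration_csv_text(q, f))
  expect_error(read_titration_csv(I(bad)), "intensity")
  # no zero-quencher row
  expect_error(read_titration_csv(I(titration_csv_text(q[-1], f[-1]))),
               "zero-quencher")
  # duplicated quencher row
  expect_error(
    read_titration_csv(I(titration_csv_text(c(q, 1e-6), c(f, 750)))),
    "duplicate")
})

test_that("micromolar concentration columns convert to mol/L on read", {
  txt <- paste("condition,temperature_C,quencher_total_uM,intensity",
               "free,25,0,1000", "free,25,1,800", "free,25,2,650",
               sep = "\n")
  s <- read_titration_csv(I(txt))[[1L]]
  expect_equal(s$points$quencher_M, c(0, 1e-6, 2e-6))
})

test_that("spectral long format reduces to fixed-wavelength intensities", {
  wl <- seq(300, 400, 5)
  rows <- character(0)
  for (q_um in 0:3) {
    band <- (1000 - 100 * q_um) * exp(-(wl - 340)^2 / (2 * 20^2))
    rows <- c(rows, sprintf("free,25,%.10g,%g,%.8g", q_um * 1e-6, wl, band))
  }
  txt <- paste(c("condition,temperature_C,quencher_total_M,wavelength_nm,intensity",
                 rows), collapse = "\n")
  s340 <- read_titration_csv(I(txt), wavelength = 340)[[1L]]
  expect_equal(s340$points$intensity, c(1000, 900, 800, 700))
  speak <- read_titration_csv(I(txt), wavelength = "peak")[[1L]]
  expect_equal(speak$points$intensity, c(1000, 900, 800, 700))
})

test_that("intensity_at interpolates linearly, honours peak mode and range", {
  flat <- emission_spectrum(seq(300, 400, 10), rep(100, 11))
  expect_equal(intensity_at(flat, 333), 100)
  expect_equal(intensity_at(flat, "peak"), 100)

  ramp <- emission_spectrum(c(300, 310, 320), c(10, 30, 50))
  expect_equal(intensity_at(ramp, 305), 20)  # mean of the neighbours

  wl <- seq(300, 400, 2)
  band <- emission_spectrum(wl, exp(-(wl - 340)^2 / 800))
  expect_equal(intensity_at(band, "peak"), intensity_at(band, 340))
  expect_error(intensity_at(band, 250), "range")
  # peak dominates every fixed wavelength
  for (w in seq(302, 398, 7)) {
    expect_gte(intensity_at(band, "peak"), intensity_at(band, w))
  }
})

test_that("read -> write -> read is the identity on validated series", {
  gt <- ground_truth(noise_cv = 0)
  panel <- simulate_panel(gt, panel_design(conditions = c("free", "hemin"),
                                           temperatures_C = c(25, 35)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_titration_csv(panel$series, path)
  back <- read_titration_csv(path)
  expect_equal(back[sort(names(panel$series))],
               lapply(panel$series[sort(names(panel$series))], function(s) {
                 attr(s, "truth") <- NULL
                 s
               }))
})

test_that("reports round-trip through JSON at full precision", {
  gt <- ground_truth(noise_cv = 0)
  panel <- simulate_panel(gt, panel_design(conditions = "free",
                                           temperatures_C = c(25, 35, 45)))
  report <- run_analysis(panel$series)
  expect_true(all(c("ksv1", "kq1") %in%
                    names(report$conditions[[1L]]$stern_volmer)))
  expect_true("kb1" %in% names(report$conditions[[1L]]$binding))
  path <- withr::local_tempfile(fileext = ".json")
  write_report(report, path)
  back <- read_report(path)
  expect_equal(back$conditions[[1L]]$stern_volmer$ksv1,
               report$conditions[[1L]]$stern_volmer$ksv1)
  expect_equal(back$thermodynamics$site1$dH_kJ_mol,
               report$thermodynamics$site1$dH_kJ_mol)
  expect_equal(back$mechanism, report$mechanism)
})

test_that("an empty report is refused", {
  expect_error(write_report(list(), tempfile()), "empty")
})
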