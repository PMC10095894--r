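test_that("site occupancy follows the one-site isotherm", {
  expect_equal(site_occupancy(0, c(0, 1e-6, 1)), c(0, 0, 0))
  expect_equal(site_occupancy(2e5, 1 / 2e5), 0.5)
  expect_equal(site_occupancy(1e6, 9e-6), 0.9)
  expect_error(site_occupancy(-1, 1e-6), ">= 0")
})

test_that("free-ligand mass balance matches an independent root finder", {
  # trivial limits
  expect_equal(free_ligand(0, 0, 3e-6, 5e-6), 5e-6, tolerance = 1e-10)
  expect_equal(free_ligand(1e6, 1e5, 0, 5e-6), 5e-6, tolerance = 1e-10)
  expect_equal(free_ligand(1e6, 1e5, 3e-6, 0), 0)
  # worked example against uniroot
  qf <- free_ligand(1e6, 0, 3e-6, 5e-6)
  expect_equal(qf, 2.79128784747792e-06, tolerance = 1e-9)
  expect_equal(qf, free_ligand_oracle(1e6, 0, 3e-6, 5e-6), tolerance = 1e-9)
  # random draws: residual below the advertised tolerance
  set.seed(31)
  for (i in 1:25) {
    K1 <- 10^runif(1, 3, 7)
    K2 <- K1 * runif(1, 0.001, 0.9)
    P <- runif(1, 0, 1e-5)
    Qt <- runif(1, 0, 2e-5)
    qf <- free_ligand(K1, K2, P, Qt)
    resid <- qf + P * (site_occupancy(K1, qf) + site_occupancy(K2, qf)) - Qt
    expect_lt(abs(resid), 1e-12 * max(Qt, 1e-9))
  }
})

test_that("the noise-free intensity model honours its limits", {
  gt <- ground_truth(noise_cv = 0)
  expect_equal(true_intensity(gt, 0), gt$F0)

  half <- ground_truth(q1 = 0.5, q2 = 0, noise_cv = 0, ligand_depletion = "off")
  expect_equal(true_intensity(half, 100), gt$F0 / 2, tolerance = 1e-6)

  both <- ground_truth(q1 = 0.6, q2 = 0.2, noise_cv = 0,
                       ligand_depletion = "off")
  expect_equal(true_intensity(both, 1e4), 0.2 * gt$F0, tolerance = 1e-6)
})

test_that("intensity is monotone non-increasing in quencher concentration", {
  set.seed(41)
  for (i in 1:10) {
    q1 <- runif(1, 0.2, 0.9)
    gt <- ground_truth(q1 = q1, q2 = runif(1, 0, 1 - q1),
                       delta_S2 = runif(1, 10, 50),
                       noise_cv = 0,
                       ligand_depletion = sample(c("exact", "off"), 1))
    f <- true_intensity(gt, seq(0, 2e-5, 1e-6))
    expect_true(all(diff(f) <= 1e-12))
  }
})

test_that("total-concentration isotherms give concave Stern-Volmer curves", {
  # downward curvature (negative second differences of F0/F on an even grid)
  # whenever the primary site quenches more efficiently
  gt <- ground_truth(q1 = 0.8, q2 = 0.1, noise_cv = 0, ligand_depletion = "off")
  f <- true_intensity(gt, seq(0, 10e-6, 1e-6))
  ratio <- f[1] / f
  expect_true(all(diff(diff(ratio)) <= 1e-12))
})

test_that("the instrument model attenuates and perturbs as configured", {
  clean <- ground_truth(epsilon_ex = 0, epsilon_em = 0, baseline_ex = 0,
                        noise_cv = 0)
  obs <- observe(clean, 1000, 5e-6)
  expect_equal(obs$intensity, 1000)
  expect_equal(obs$absorbance_ex, 0)

  gt <- ground_truth(noise_cv = 0)
  obs <- observe(gt, 1000, 5e-6)
  expect_equal(obs$absorbance_ex, gt$epsilon_ex * 5e-6 + gt$baseline_ex)
  expect_equal(obs$intensity,
               1000 * 10^(-(obs$absorbance_ex + obs$absorbance_em) / 2))
})

test_that("identical seeds give identical panels; seeds move only the noise", {
  gt <- ground_truth()
  p1 <- simulate_panel(gt, seed = 7)
  p2 <- simulate_panel(gt, seed = 7)
  expect_identical(p1$series, p2$series)
  p3 <- simulate_panel(gt, seed = 8)
  s1 <- p1$series$free_25$points
  s3 <- p3$series$free_25$points
  expect_identical(s1$quencher_M, s3$quencher_M)
  expect_identical(s1$absorbance_ex, s3$absorbance_ex)
  expect_false(identical(s1$intensity, s3$intensity))
})

test_that("written panels are byte-identical under a fixed seed", {
  gt <- ground_truth()
  des <- panel_design(conditions = c("free", "warfarin"),
                      temperatures_C = 25)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- generate_panel(gt, des, d1, seed = 5)
  f2 <- generate_panel(gt, des, d2, seed = 5)
  for (nm in names(f1)) {
    expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]))
  }
  # default full design: 11 points x 3 temperatures x 5 conditions
  full <- simulate_panel(gt)
  expect_length(full$series, 15L)
  expect_true(all(vapply(full$series, function(s) nrow(s$points),
                         integer(1L)) == 11L))
})

test_that("invalid ground truth is rejected", {
  expect_error(ground_truth(q1 = 0.7, q2 = 0.5), "q1 \\+ q2")
  expect_error(ground_truth(q1 = 1.2), "\\[0, 1\\]")
  expect_error(ground_truth(noise_cv = -0.1), ">= 0")
  expect_error(ground_truth(delta_S1 = -200), "K1 > K2")
})
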