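# Build a competition panel from the generator and run the analysis layer.
panel_report <- function(gt, conditions, temperature_C = 25, seed = NULL) {
  p <- simulate_panel(gt, panel_design(conditions = conditions,
                                       temperatures_C = temperature_C),
                      seed = seed)
  suppressWarnings(analyze_panel(lapply(p$series, correct_series)))
}

test_that("conditions with both sites free show the two-regime signature", {
  gt <- ground_truth(noise_cv = 0)
  rep <- panel_report(gt, c("free", "ibuprofen"))
  expect_equal(rep$table$curvature_class[rep$table$condition == "free"],
               "downward")
  expect_equal(rep$table$curvature_class[rep$table$condition == "ibuprofen"],
               "downward")
  # ibuprofen blocks neither modelled site: constants match the free protein
  free_ksv <- rep$table$ksv1[rep$table$condition == "free"]
  ibu_ksv <- rep$table$ksv1[rep$table$condition == "ibuprofen"]
  expect_equal(ibu_ksv, free_ksv, tolerance = 1e-9)
})

test_that("marker occupancy never raises the apparent primary constant", {
  # total-concentration isotherms: blocking a site can only remove quenching.
  # (With exact ligand depletion a blocked site slightly raises the free
  # ligand available to the other site, so the dominance is only
  # approximate there.)
  gt <- ground_truth(noise_cv = 0, allosteric_factor = 1,
                     ligand_depletion = "off")
  conditions <- c("free", "warfarin", "ibuprofen", "hemin", "warfarin+hemin")
  p <- simulate_panel(gt, panel_design(conditions = conditions,
                                       temperatures_C = 25))
  free_ratio <- sv_ratios(correct_series(p$series$free_25))$ratio
  for (cond in setdiff(conditions, "free")) {
    r <- sv_ratios(correct_series(p$series[[paste0(cond, "_25")]]))$ratio
    expect_true(all(r <= free_ratio * (1 + 1e-12)))
  }
  rep <- panel_report(gt, conditions)
  free_ksv <- rep$table$ksv1[rep$table$condition == "free"]
  others <- rep$table$ksv1[rep$table$condition != "free"]
  expect_true(all(others <= free_ksv * (1 + 1e-6), na.rm = TRUE))
})

test_that("the weak-site-only condition reads as linear at realistic noise", {
  gt <- ground_truth()  # default 1% noise, default seed
  rep <- panel_report(gt, c("free", "warfarin"))
  expect_equal(rep$table$curvature_class[rep$table$condition == "warfarin"],
               "linear")
  expect_equal(rep$table$curvature_class[rep$table$condition == "free"],
               "downward")
})

test_that("panel preconditions are enforced", {
  gt <- ground_truth(noise_cv = 0)
  p <- simulate_panel(gt, panel_design(conditions = c("warfarin", "hemin"),
                                       temperatures_C = 25))
  expect_error(analyze_panel(lapply(p$series, correct_series)), "free")
  mixed <- simulate_panel(gt, panel_design(conditions = "free",
                                           temperatures_C = c(25, 35)))
  expect_error(analyze_panel(lapply(mixed$series, correct_series)),
               "single temperature")
})

test_that("a free-only panel is analysed but yields no site verdict", {
  gt <- ground_truth(noise_cv = 0)
  rep <- panel_report(gt, "free")
  expect_equal(nrow(rep$table), 1L)
  expect_false(rep$allosteric_flag)
  verdict <- infer_sites(rep)
  expect_false(verdict$conclusive)
  expect_match(verdict$assignment, "free condition only")
})

test_that("the classical displacement pattern maps to the two-site assignment", {
  # linear under the site-1 marker and the site-2 marker, unchanged under
  # the DS2 control, weakest under the double marker
  tb <- tibble::tibble(
    condition = c("free", "warfarin", "ibuprofen", "hemin", "warfarin+hemin"),
    curvature_class = c("downward", "linear", "downward", "linear", "downward"),
    inferred_free_sites = c(2L, 1L, 2L, 1L, 2L),
    ksv1 = c(3.0e5, 1.2e5, 2.8e5, 2.1e5, 1.1e5),
    ksv2 = c(1.5e5, NA, 1.6e5, NA, 6.0e4),
    kq1 = c(3.0e5, 1.2e5, 2.8e5, 2.1e5, 1.1e5) / 5.9e-9,
    kq2 = c(1.5e5, NA, 1.6e5, NA, 6.0e4) / 5.9e-9,
    kb1 = c(5.9e5, 2.8e4, 4.7e5, 1.4e5, 3.4e3),
    kb2 = c(1.9e3, NA, 1.5e3, NA, 9.8e2),
    n1 = c(1.05, 0.9, 1.04, 0.97, 0.8),
    n2 = c(0.6, NA, 0.6, NA, 0.55))
  report <- structure(list(table = tb, temperature_C = 25,
                           allosteric_flag = tb$kb1[2] > tb$kb2[1],
                           details = list(), warnings = character(0)),
                      class = "competition_report")
  verdict <- infer_sites(report)
  expect_true(verdict$conclusive)
  expect_match(verdict$assignment, "drug site 1")
  expect_match(verdict$assignment, "hemin")
  expect_match(verdict$assignment, "drug site 2 not used")
  expect_true(any(grepl("allosteric", verdict$evidence)))
  expect_true(any(grepl("more strongly", verdict$evidence)))
})

test_that("uninformative and contradictory panels resolve without errors", {
  base <- tibble::tibble(
    condition = c("free", "warfarin", "hemin"),
    curvature_class = c("downward", "downward", "downward"),
    inferred_free_sites = 2L,
    ksv1 = 3.0e5, ksv2 = 1.5e5, kq1 = 3.0e5 / 5.9e-9, kq2 = 1.5e5 / 5.9e-9,
    kb1 = 5.9e5, kb2 = 1.9e3, n1 = 1.05, n2 = 0.6)
  same <- structure(list(table = base, temperature_C = 25,
                         allosteric_flag = FALSE, details = list(),
                         warnings = character(0)),
                    class = "competition_report")
  v <- infer_sites(same)
  expect_true(v$conclusive)
  expect_match(v$assignment, "no modeled site")

  contra <- base
  contra$curvature_class <- c("linear", "downward", "linear")
  v2 <- infer_sites(structure(list(table = contra, temperature_C = 25,
                                   allosteric_flag = FALSE, details = list(),
                                   warnings = character(0)),
                              class = "competition_report"))
  expect_false(v2$conclusive)
  expect_match(v2$assignment, "contradictory")
})

test_that("allosteric coupling in the generator surfaces in the report", {
  # a strong-secondary-site configuration where the site-2 signal under
  # warfarin is measurable
  coupled <- ground_truth(q1 = 0.6, q2 = 0.4, delta_S2 = 37.7,
                          allosteric_factor = 50, noise_cv = 0)
  rep_on <- panel_report(coupled, c("free", "warfarin"))
  expect_true(rep_on$allosteric_flag)

  uncoupled <- ground_truth(q1 = 0.6, q2 = 0.4, delta_S2 = 37.7,
                            allosteric_factor = 1, noise_cv = 0)
  rep_off <- panel_report(uncoupled, c("free", "warfarin"))
  # the coupling multiplies the apparent secondary-site constant several-fold
  expect_gt(rep_on$table$kb1[rep_on$table$condition == "warfarin"],
            3 * rep_off$table$kb1[rep_off$table$condition == "warfarin"])
})
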