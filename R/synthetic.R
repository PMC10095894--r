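#' Ground truth for the two-site titration simulator
#'
#' Collects the hidden parameters of the forward model: per-site association
#' constants driven by their own thermodynamics, quench efficiencies, the
#' quencher's optical properties (which generate the inner filter effect),
#' the noise level, and marker-occupancy behaviour. The defaults are
#' calibrated so that running the full analysis pipeline on a simulated
#' 25 degC panel reproduces the scale of published HSA-indomethacin
#' constants (primary-site kb near 5.9e5 L/mol with n near 1.05, second
#' Stern-Volmer segment near 1.5e5 L/mol).
#'
#' Site association constants at temperature `T` follow
#' `K_i(T) = exp(-dH_i/(R T) + dS_i/R)`, so a panel simulated across
#' temperatures is exactly Van't Hoff-linear by construction.
#'
#' @param delta_H1,delta_S1 primary-site binding enthalpy (kJ/mol) and
#'   entropy (J/mol/K). Defaults -47.4 and -48.9 give
#'   `K1(298.15 K) = 5.6e5` L/mol.
#' @param delta_H2,delta_S2 secondary-site thermodynamics; defaults -11.6
#'   and 23.9 give `K2(298.15 K) = 1.9e3` L/mol.
#' @param q1,q2 quench efficiencies of the two sites, in `[0, 1]` with
#'   `q1 + q2 <= 1`: the fraction of the intrinsic fluorescence removed when
#'   the corresponding site is fully occupied.
#' @param F0 unquenched intensity, arbitrary units.
#' @param epsilon_ex,epsilon_em quencher extinction coefficients at the
#'   excitation and emission wavelengths, L mol^-1 cm^-1.
#' @param baseline_ex,baseline_em quencher-independent absorbance offsets
#'   (e.g. the protein's own absorbance at the excitation wavelength).
#' @param noise_cv multiplicative Gaussian noise scale on intensities
#'   (coefficient of variation).
#' @param seed integer seed for the panel's random stream.
#' @param blocks_site1,blocks_site2 marker occupancy flags for a single
#'   simulated series; [simulate_panel()] overrides them per condition.
#' @param allosteric_factor multiplier on `K2` when site 1 is marker-blocked
#'   (warfarin-hemin site coupling); 1 disables the coupling.
#' @param residual_K weak nonspecific association constant, L/mol, used when
#'   both sites are blocked.
#' @param residual_q_factor the residual site quenches with efficiency
#'   `residual_q_factor * q1`.
#' @param ligand_depletion `"exact"` to solve the free-ligand mass balance
#'   at each titration point (the physical regime for micromolar protein
#'   binding a micromolar ligand at K ~ 1e5-1e6 L/mol), `"off"` to treat
#'   total and free quencher as equal.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(delta_H1 = -47.4, delta_S1 = -48.9,
                         delta_H2 = -11.6, delta_S2 = 23.9,
                         q1 = 0.8, q2 = 0.1,
                         F0 = 1000,
                         epsilon_ex = 1.0e4, epsilon_em = 2.5e3,
                         baseline_ex = 0.05, baseline_em = 0,
                         noise_cv = 0.01,
                         seed = 42L,
                         blocks_site1 = FALSE, blocks_site2 = FALSE,
                         allosteric_factor = 1,
                         residual_K = 2e4, residual_q_factor = 0.2,
                         ligand_depletion = c("exact", "off")) {
  ligand_depletion <- match.arg(ligand_depletion)
  gt <- structure(list(
    delta_H1 = delta_H1, delta_S1 = delta_S1,
    delta_H2 = delta_H2, delta_S2 = delta_S2,
    q1 = q1, q2 = q2, F0 = F0,
    epsilon_ex = epsilon_ex, epsilon_em = epsilon_em,
    baseline_ex = baseline_ex, baseline_em = baseline_em,
    noise_cv = noise_cv, seed = as.integer(seed),
    blocks_site1 = isTRUE(blocks_site1), blocks_site2 = isTRUE(blocks_site2),
    allosteric_factor = allosteric_factor,
    residual_K = residual_K, residual_q_factor = residual_q_factor,
    ligand_depletion = ligand_depletion),
    class = "ground_truth")
  gt$K1 <- binding_constant_at(gt, site = 1, temperature_K = 298.15)
  gt$K2 <- binding_constant_at(gt, site = 2, temperature_K = 298.15)
  validate_ground_truth(gt)
}

#' Validate simulator ground truth
#' @param gt a `ground_truth`.
#' @return `gt` on success.
#' @export
validate_ground_truth <- function(gt) {
  if (!(gt$q1 >= 0 && gt$q1 <= 1 && gt$q2 >= 0 && gt$q2 <= 1)) {
    stop("quench efficiencies must lie in [0, 1]", call. = FALSE)
  }
  if (gt$q1 + gt$q2 > 1) stop("q1 + q2 must be <= 1", call. = FALSE)
  if (!(gt$K1 > gt$K2 && gt$K2 > 0)) {
    stop("site constants must satisfy K1 > K2 > 0 (at 298.15 K)",
         call. = FALSE)
  }
  if (gt$noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (gt$F0 <= 0) stop("F0 must be > 0", call. = FALSE)
  if (gt$epsilon_ex < 0 || gt$epsilon_em < 0 ||
      gt$baseline_ex < 0 || gt$baseline_em < 0) {
    stop("extinction coefficients and baselines must be >= 0", call. = FALSE)
  }
  if (gt$residual_K < 0 || gt$allosteric_factor <= 0) {
    stop("residual_K must be >= 0 and allosteric_factor > 0", call. = FALSE)
  }
  invisible(gt)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> K1(25C) = %.4g, K2(25C) = %.4g L/mol; q1 = %.2f, q2 = %.2f\n",
              x$K1, x$K2, x$q1, x$q2))
  cat(sprintf("  noise_cv = %.3g, seed = %d, depletion = %s\n",
              x$noise_cv, x$seed, x$ligand_depletion))
  invisible(x)
}

#' Site association constant at a temperature
#'
#' @param gt a `ground_truth`.
#' @param site 1 (primary) or 2 (secondary).
#' @param temperature_K absolute temperature, K.
#' @return `K_site(T)` in L/mol.
#' @export
binding_constant_at <- function(gt, site, temperature_K) {
  dH <- if (site == 1) gt$delta_H1 else gt$delta_H2
  dS <- if (site == 1) gt$delta_S1 else gt$delta_S2
  exp(-dH * 1000 / (.R_J * temperature_K) + dS / .R_J)
}

#' Single-site occupancy isotherm
#'
#' `theta = K Q / (1 + K Q)`: the fraction of a site occupied at free ligand
#' concentration `Q`.
#'
#' @param K association constant, L/mol, >= 0.
#' @param Q_free free ligand concentration, mol/L, >= 0.
#' @return occupancy in `[0, 1]`; vectorised over `Q_free`.
#' @export
site_occupancy <- function(K, Q_free) {
  if (any(K < 0) || any(Q_free < 0)) {
    stop("K and Q_free must be >= 0", call. = FALSE)
  }
  K * Q_free / (1 + K * Q_free)
}

#' Free ligand concentration from the two-site mass balance
#'
#' Solves `Q_total = Qf + P * (K1 Qf/(1 + K1 Qf) + K2 Qf/(1 + K2 Qf))` for
#' the free concentration `Qf` by bisection on `[0, Q_total]`. The left side
#' is strictly increasing in `Qf`, so the root is unique; bisection is
#' iterated until the residual is below `1e-12 * max(Q_total, 1e-9)`.
#'
#' @param K1,K2 site association constants, L/mol, >= 0.
#' @param protein_total total protein concentration, mol/L, >= 0.
#' @param quencher_total total ligand concentration, mol/L, >= 0.
#' @return the free ligand concentration, mol/L.
#' @export
free_ligand <- function(K1, K2, protein_total, quencher_total) {
  stopifnot(K1 >= 0, K2 >= 0, protein_total >= 0, quencher_total >= 0)
  if (quencher_total == 0) return(0)
  bound <- function(qf) {
    protein_total * (site_occupancy(K1, qf) + site_occupancy(K2, qf))
  }
  resid <- function(qf) qf + bound(qf) - quencher_total
  lo <- 0
  hi <- quencher_total
  tol <- 1e-12 * max(quencher_total, 1e-9)
  repeat {
    mid <- (lo + hi) / 2
    r <- resid(mid)
    if (abs(r) < tol || (hi - lo) / 2 < .Machine$double.xmin) return(mid)
    if (r > 0) hi <- mid else lo <- mid
  }
}

# Effective (possibly marker-blocked) site constants for one condition.
.effective_constants <- function(gt, temperature_K) {
  K1 <- binding_constant_at(gt, 1, temperature_K)
  K2 <- binding_constant_at(gt, 2, temperature_K)
  if (gt$blocks_site1 && gt$blocks_site2) {
    list(residual = TRUE, K1 = gt$residual_K, K2 = 0,
         q1 = gt$residual_q_factor * gt$q1, q2 = 0)
  } else if (gt$blocks_site1) {
    list(residual = FALSE, K1 = 0, K2 = gt$allosteric_factor * K2,
         q1 = gt$q1, q2 = gt$q2)
  } else if (gt$blocks_site2) {
    list(residual = FALSE, K1 = K1, K2 = 0, q1 = gt$q1, q2 = gt$q2)
  } else {
    list(residual = FALSE, K1 = K1, K2 = K2, q1 = gt$q1, q2 = gt$q2)
  }
}

#' Noise-free intensity of the two-site static quenching model
#'
#' The model is a static-quenching mixture: each site, when occupied,
#' removes its quench efficiency's worth of the intrinsic fluorescence,
#' `F = F0 * (1 - q1 * theta1 - q2 * theta2)`. Occupancies use the free
#' ligand concentration when `ligand_depletion = "exact"`, otherwise the
#' total. Marker-blocked sites contribute zero occupancy; with both sites
#' blocked a weak residual site (`residual_K`, efficiency
#' `residual_q_factor * q1`) stands in for nonspecific association.
#'
#' @param gt a `ground_truth` (its blocking flags apply).
#' @param quencher_M total quencher concentration(s), mol/L.
#' @param temperature_K absolute temperature, K.
#' @param protein_M total protein concentration, mol/L (used by the mass
#'   balance when depletion is exact).
#' @return noise-free intensity (vectorised over `quencher_M`).
#' @export
true_intensity <- function(gt, quencher_M, temperature_K = 298.15,
                           protein_M = 3e-6) {
  stopifnot(inherits(gt, "ground_truth"))
  if (any(quencher_M < 0)) stop("quencher_M must be >= 0", call. = FALSE)
  eff <- .effective_constants(gt, temperature_K)
  vapply(quencher_M, function(qt) {
    qf <- if (gt$ligand_depletion == "exact") {
      free_ligand(eff$K1, eff$K2, protein_M, qt)
    } else {
      qt
    }
    th1 <- if (eff$K1 > 0) site_occupancy(eff$K1, qf) else 0
    th2 <- if (eff$K2 > 0) site_occupancy(eff$K2, qf) else 0
    gt$F0 * (1 - eff$q1 * th1 - eff$q2 * th2)
  }, numeric(1L))
}

#' Observe a titration point through the instrument model
#'
#' Applies the quencher's optical attenuation (the inner filter effect,
#' `F_obs = F_true * 10^(-(A_ex + A_em)/2)` with `A = epsilon * [Q] +
#' baseline`) and multiplicative Gaussian noise drawn from the current RNG
#' stream. Absorbances themselves are noise-free and carried on the point so
#' the correction module can undo the attenuation exactly.
#'
#' @param gt a `ground_truth`.
#' @param f_true noise-free intensity.
#' @param quencher_M total quencher concentration, mol/L.
#' @return a one-row tibble: `quencher_M`, `intensity`, `absorbance_ex`,
#'   `absorbance_em`.
#' @export
observe <- function(gt, f_true, quencher_M) {
  a_ex <- gt$epsilon_ex * quencher_M + gt$baseline_ex
  a_em <- gt$epsilon_em * quencher_M + gt$baseline_em
  noise <- if (gt$noise_cv > 0) stats::rnorm(length(f_true), 0, gt$noise_cv) else 0
  tibble::tibble(
    quencher_M = quencher_M,
    intensity = f_true * 10^(-(a_ex + a_em) / 2) * (1 + noise),
    absorbance_ex = a_ex,
    absorbance_em = a_em)
}

#' Titration panel design
#'
#' The default design mirrors the reference experiment: 3 uM protein
#' titrated with 0-10 uM quencher in 1 uM steps, at 25/35/45 degC, under the
#' free condition and four marker-occupancy conditions.
#'
#' @param quencher_M total quencher grid, mol/L; must start at 0.
#' @param temperatures_C panel temperatures, degrees Celsius.
#' @param conditions condition labels; marker semantics come from
#'   [marker_conditions()].
#' @param protein_conc_M total protein concentration, mol/L.
#' @return a list of class `panel_design`.
#' @export
panel_design <- function(quencher_M = seq(0, 10e-6, by = 1e-6),
                         temperatures_C = c(25, 35, 45),
                         conditions = c("free", "warfarin", "ibuprofen",
                                        "hemin", "warfarin+hemin"),
                         protein_conc_M = 3e-6) {
  if (quencher_M[1L] != 0) stop("quencher grid must start at 0", call. = FALSE)
  structure(list(quencher_M = quencher_M,
                 temperatures_C = temperatures_C,
                 conditions = conditions,
                 protein_conc_M = protein_conc_M),
            class = "panel_design")
}

# Deterministic per-(condition, temperature) seed stream. Fixed offsets per
# registry slot mean adding a condition or temperature to a design does not
# perturb the draws of the others. Kept below 2^31 - 1.
.series_seed <- function(seed, condition, temperature_C) {
  registry <- c("free", "warfarin", "ibuprofen", "hemin", "warfarin+hemin")
  ci <- match(condition, registry, nomatch = length(registry) + 1L)
  (abs(seed) + 7919L * ci + 101L * as.integer(round(temperature_C))) %%
    2147483647L
}

#' Simulate one titration series
#'
#' @param gt a `ground_truth`; its blocking flags are replaced by the
#'   marker semantics of `condition`.
#' @param condition condition label (see [marker_conditions()]).
#' @param temperature_C temperature, degrees Celsius.
#' @param design a [panel_design()] supplying grid and protein
#'   concentration.
#' @param seed optional override of `gt$seed` for the panel stream.
#' @return a [titration_series] with absorbance columns filled and the
#'   generating `ground_truth` attached as attribute `truth`.
#' @export
simulate_series <- function(gt, condition = "free", temperature_C = 25,
                            design = panel_design(), seed = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  seed <- if (is.null(seed)) gt$seed else as.integer(seed)
  mk <- marker_conditions()
  row <- match(condition, mk$label)
  gt$blocks_site1 <- if (is.na(row)) FALSE else mk$blocks_site1[row]
  gt$blocks_site2 <- if (is.na(row)) FALSE else mk$blocks_site2[row]

  set.seed(.series_seed(seed, condition, temperature_C))
  tk <- celsius_to_kelvin(temperature_C)
  f_true <- true_intensity(gt, design$quencher_M, temperature_K = tk,
                           protein_M = design$protein_conc_M)
  pts <- observe(gt, f_true, design$quencher_M)
  out <- titration_series(condition, temperature_C, pts,
                          protein_conc_M = design$protein_conc_M)
  attr(out, "truth") <- gt
  out
}

#' Simulate a full titration panel
#'
#' One series per (condition, temperature) cell of the design, each with its
#' own deterministic sub-stream of the panel seed.
#'
#' @param gt a `ground_truth`.
#' @param design a [panel_design()].
#' @param seed optional override of `gt$seed`.
#' @return a list with elements `series` (named list of [titration_series]),
#'   `truth` and `design`.
#' @export
simulate_panel <- function(gt, design = panel_design(), seed = NULL) {
  series <- list()
  for (cond in design$conditions) {
    for (tc in design$temperatures_C) {
      s <- simulate_series(gt, condition = cond, temperature_C = tc,
                           design = design, seed = seed)
      series[[paste0(cond, "_", tc)]] <- s
    }
  }
  list(series = series, truth = gt, design = design)
}

#' Write a simulated panel to disk
#'
#' Emits the CSV dialects the reader understands plus the hidden parameters:
#' `titration.csv` (summary format), `absorbance.csv` (sidecar) and
#' `ground_truth.json`. Identical ground truth, design and seed give
#' byte-identical files.
#'
#' @param gt a `ground_truth`.
#' @param design a [panel_design()].
#' @param dir output directory (created if needed).
#' @param seed optional override of `gt$seed`.
#' @return invisibly, the named character vector of file paths.
#' @export
generate_panel <- function(gt, design = panel_design(), dir, seed = NULL) {
  panel <- simulate_panel(gt, design = design, seed = seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  rows <- lapply(panel$series, function(s) {
    tibble::tibble(condition = s$condition,
                   temperature_C = s$temperature_C,
                   quencher_total_M = s$points$quencher_M,
                   intensity = s$points$intensity,
                   protein_conc_M = s$protein_conc_M)
  })
  titr_path <- file.path(dir, "titration.csv")
  readr::write_csv(do.call(rbind, rows), titr_path, progress = FALSE)

  ab_rows <- lapply(panel$series, function(s) {
    tibble::tibble(condition = s$condition,
                   temperature_C = s$temperature_C,
                   quencher_total_M = s$points$quencher_M,
                   absorbance_ex = s$points$absorbance_ex,
                   absorbance_em = s$points$absorbance_em)
  })
  ab_path <- file.path(dir, "absorbance.csv")
  readr::write_csv(do.call(rbind, ab_rows), ab_path, progress = FALSE)

  gt_path <- file.path(dir, "ground_truth.json")
  truth <- panel$truth
  truth_list <- unclass(truth)
  jsonlite::write_json(truth_list, gt_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(titration = titr_path, absorbance = ab_path,
              ground_truth = gt_path))
}
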