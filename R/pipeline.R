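#' Analysis configuration
#'
#' Assembles and validates the tunable parameters of [run_analysis()].
#' Unknown keys are rejected so that a typo cannot silently fall back to a
#' default.
#'
#' @param ... overrides of the defaults: `tau0_s` (fluorophore lifetime,
#'   s), `min_segment`, `alpha`, `diffusion_limit` (L mol^-1 s^-1),
#'   `quench_floor`, `wavelength` (nm or `"peak"`, for spectral input),
#'   `ife_mode` (`"sidecar"`, `"linear_model"` or `"off"`), `epsilon_ex`,
#'   `epsilon_em`, `baseline_ex`, `baseline_em` (linear absorbance model),
#'   `path_weight`, `absorbance_ceiling`.
#' @return a named list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  defaults <- list(
    tau0_s = .TAU0_DEFAULT,
    min_segment = 3,
    alpha = 0.05,
    diffusion_limit = .DIFFUSION_LIMIT,
    quench_floor = 1e-3,
    wavelength = 340,
    ife_mode = "sidecar",
    epsilon_ex = NULL, epsilon_em = NULL,
    baseline_ex = 0, baseline_em = 0,
    path_weight = 0.5,
    absorbance_ceiling = 2)
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1L]]) &&
      is.null(names(overrides))) {
    overrides <- overrides[[1L]]
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(overrides)] <- overrides
  if (!defaults$ife_mode %in% c("sidecar", "linear_model", "off")) {
    stop("ife_mode must be 'sidecar', 'linear_model' or 'off'", call. = FALSE)
  }
  structure(defaults, class = "analysis_config")
}

# IFE handling for one series according to the configured mode.
.apply_ife <- function(series, config) {
  has_cols <- all(c("absorbance_ex", "absorbance_em") %in%
                    names(series$points)) &&
    !anyNA(series$points$absorbance_ex) && !anyNA(series$points$absorbance_em)
  switch(config$ife_mode,
    off = series,
    sidecar = {
      if (!has_cols) {
        stop("ife_mode = 'sidecar' but series '", series$condition,
             "' carries no absorbances; supply a sidecar or set ife_mode",
             call. = FALSE)
      }
      correct_series(series, path_weight = config$path_weight,
                     ceiling = config$absorbance_ceiling)
    },
    linear_model = correct_series(
      series,
      epsilon_ex = config$epsilon_ex, epsilon_em = config$epsilon_em,
      baseline_ex = config$baseline_ex, baseline_em = config$baseline_em,
      path_weight = config$path_weight, ceiling = config$absorbance_ceiling))
}

#' Run the full titration analysis pipeline
#'
#' Per (condition, temperature) series: inner-filter correction, segmented
#' Stern-Volmer fit, quenching constants, and the double-log binding fit.
#' Across temperatures of the free condition: mechanism classification,
#' Van't Hoff thermodynamics per site, Gibbs energy table and the force
#' signature. Across conditions at the lowest temperature: the competition
#' report and site inference. The result is a plain list ready for
#' [write_report()].
#'
#' @param titration a path/connection to a titration CSV (see
#'   [read_titration_csv()]) or a list of [titration_series].
#' @param absorbance optional path to an absorbance sidecar CSV (required
#'   when `ife_mode = "sidecar"` and the titration carries no absorbance
#'   columns).
#' @param config an [analysis_config()] (or a list of overrides).
#' @return the report list: `meta`, `conditions`, `mechanism`,
#'   `thermodynamics`, `competition`, `warnings`.
#' @export
run_analysis <- function(titration, absorbance = NULL, config = analysis_config()) {
  if (!inherits(config, "analysis_config")) config <- analysis_config(config)
  series <- if (is.list(titration) && !is.data.frame(titration) &&
                all(vapply(titration, inherits, logical(1L), "titration_series"))) {
    titration
  } else {
    .read_titration_input(titration, config)
  }
  if (!is.null(absorbance)) {
    series <- attach_absorbance(series, read_absorbance_csv(absorbance))
  }

  notes <- character(0)
  note <- function(tag, msg) notes <<- c(notes, paste0(tag, ": ", msg))
  quiet <- function(tag, expr) {
    tryCatch(
      withCallingHandlers(expr, warning = function(w) {
        note(tag, conditionMessage(w))
        invokeRestart("muffleWarning")
      }),
      error = function(e) {
        note(tag, conditionMessage(e))
        NULL
      })
  }

  corrected <- list()
  conditions_out <- list()
  qres_all <- list()
  bres_all <- list()
  for (nm in names(series)) {
    s <- quiet(nm, .apply_ife(series[[nm]], config))
    if (is.null(s)) next
    corrected[[nm]] <- s
    qres <- quiet(nm, quenching_constants(
      sv_fit(s, min_segment = config$min_segment, alpha = config$alpha),
      tau0 = config$tau0_s))
    sv_bp <- if (!is.null(qres) && qres$fit$two_segment) {
      log10(qres$fit$breakpoint_x)
    } else NULL
    bres <- quiet(nm, fit_binding(
      double_log_points(s, quench_floor = config$quench_floor),
      min_segment = config$min_segment, alpha = config$alpha,
      breakpoint_x = sv_bp))
    qres_all[[nm]] <- qres
    bres_all[[nm]] <- bres
    fit <- if (!is.null(qres)) qres$fit else NULL
    conditions_out[[nm]] <- list(
      label = s$condition,
      temperature_C = s$temperature_C,
      stern_volmer = if (is.null(qres)) NULL else list(
        two_segment = fit$two_segment,
        ksv1 = qres$ksv1, ksv2 = qres$ksv2,
        kq1 = qres$kq1, kq2 = qres$kq2,
        intercepts = c(fit$intercept1, fit$intercept2),
        r2 = c(fit$r2_segment1, fit$r2_segment2),
        breakpoint_Q = fit$breakpoint_x),
      binding = if (is.null(bres)) NULL else list(
        kb1 = bres$kb1, kb2 = bres$kb2, n1 = bres$n1, n2 = bres$n2))
  }

  if (length(corrected) == 0L) {
    stop("configuration error: no series could be analysed (",
         paste(notes, collapse = "; "), ")", call. = FALSE)
  }

  # Temperature ladder of the free condition drives mechanism + thermodynamics.
  free_names <- names(corrected)[vapply(corrected, function(s) {
    s$condition == "free"
  }, logical(1L))]
  free_temps <- vapply(corrected[free_names], function(s) s$temperature_C,
                       numeric(1L))
  mechanism <- "indeterminate"
  thermodynamics <- NULL
  if (length(free_names) >= 2L) {
    qmap <- qres_all[free_names]
    names(qmap) <- as.character(free_temps)
    keep <- !vapply(qmap, is.null, logical(1L))
    if (sum(keep) >= 2L) {
      mechanism <- quiet("mechanism", classify_mechanism(
        qmap[keep], diffusion_limit = config$diffusion_limit))
      if (is.null(mechanism)) mechanism <- "indeterminate"
    }
    thermodynamics <- quiet("thermodynamics", {
      tk <- celsius_to_kelvin(free_temps)
      kb1 <- vapply(bres_all[free_names], function(b) {
        if (is.null(b)) NA_real_ else b$kb1
      }, numeric(1L))
      kb2 <- vapply(bres_all[free_names], function(b) {
        if (is.null(b)) NA_real_ else b$kb2
      }, numeric(1L))
      site <- function(kb) {
        ok <- !is.na(kb)
        if (sum(ok) < 2L) return(NULL)
        th <- vant_hoff(kb[ok], tk[ok])
        list(dH_kJ_mol = th$delta_H_kJ_mol,
             dS_J_mol_K = th$delta_S_J_mol_K,
             dG_by_T = as.list(th$delta_G_kJ_mol),
             r_squared = th$r_squared,
             force_signature = force_signature(th$delta_H_kJ_mol,
                                               th$delta_S_J_mol_K))
      }
      s1 <- site(kb1)
      s2 <- site(kb2)
      if (is.null(s1) && is.null(s2)) NULL else list(
        site1 = s1, site2 = s2,
        force_signature = if (!is.null(s1)) s1$force_signature else NULL)
    })
  } else {
    note("thermodynamics", "single temperature: no Van't Hoff analysis")
  }

  # Competition panel at the lowest temperature with a free condition.
  competition <- NULL
  if (length(free_temps) >= 1L) {
    t0 <- min(free_temps)
    panel <- corrected[vapply(corrected, function(s) {
      s$temperature_C == t0
    }, logical(1L))]
    if (length(panel) >= 2L) {
      competition <- quiet("competition", {
        rep <- analyze_panel(panel, tau0 = config$tau0_s,
                             min_segment = config$min_segment,
                             alpha = config$alpha,
                             quench_floor = config$quench_floor)
        inf <- infer_sites(rep)
        notes <<- c(notes, rep$warnings)
        list(curvature_classes = stats::setNames(
               as.list(rep$table$curvature_class), rep$table$condition),
             inferred_sites = inf$assignment,
             evidence = inf$evidence,
             conclusive = inf$conclusive,
             allosteric_flag = rep$allosteric_flag)
      })
    }
  }

  list(meta = list(version = as.character(utils::packageVersion("sternvolmer")),
                   config_echo = unclass(config)),
       conditions = unname(conditions_out),
       mechanism = mechanism,
       thermodynamics = thermodynamics,
       competition = competition,
       warnings = notes)
}

# Read titration input that may be a path or literal CSV; isolated so
# run_analysis can also accept pre-built series lists.
.read_titration_input <- function(titration, config) {
  read_titration_csv(titration, wavelength = config$wavelength)
}

#' Simulate a panel and write it to disk
#'
#' Thin orchestration over [generate_panel()]: the simulate entry point of
#' the pipeline.
#'
#' @param gt a [ground_truth()].
#' @param design a [panel_design()].
#' @param out_dir output directory.
#' @param seed optional seed override (changes the noise draws only, never
#'   the design grid).
#' @return the written file paths, invisibly.
#' @export
run_simulate <- function(gt = ground_truth(), design = panel_design(),
                         out_dir, seed = NULL) {
  generate_panel(gt, design = design, dir = out_dir, seed = seed)
}

#' Parameter-recovery study
#'
#' Simulates `replicates` independent panels, analyses each with the
#' standard pipeline, and tabulates the recovered constants next to the
#' generating truth. This packages the recovery procedure used to validate
#' the pipeline end to end.
#'
#' @param gt a [ground_truth()].
#' @param design a [panel_design()]; the free condition plus whatever marker
#'   conditions the study needs.
#' @param replicates number of independent panels.
#' @param seed base seed; replicate `i` uses `seed + i`.
#' @param config an [analysis_config()].
#' @return a tibble, one row per replicate: recovered `ksv1`, `ksv2`,
#'   `kb1`, `n1`, `sv_two_segment`, `order_ok` (`ksv1 > ksv2`),
#'   `warfarin_single` (when the design includes warfarin), and the truth
#'   columns `K1_true`, `K2_true`.
#' @export
run_recovery <- function(gt = ground_truth(), design = panel_design(),
                         replicates = 20, seed = 1,
                         config = analysis_config()) {
  t0 <- min(design$temperatures_C)
  tk <- celsius_to_kelvin(t0)
  K1_true <- binding_constant_at(gt, 1, tk)
  K2_true <- binding_constant_at(gt, 2, tk)
  has_warfarin <- "warfarin" %in% design$conditions

  one <- function(i) {
    panel <- simulate_panel(gt, design = design, seed = seed + i)
    free <- panel$series[[paste0("free_", t0)]]
    free <- correct_series(free, path_weight = config$path_weight)
    qres <- tryCatch(suppressWarnings(
      quenching_constants(sv_fit(free, min_segment = config$min_segment,
                                 alpha = config$alpha),
                          tau0 = config$tau0_s)),
      error = function(e) NULL)
    sv_bp <- if (!is.null(qres) && qres$fit$two_segment) {
      log10(qres$fit$breakpoint_x)
    } else NULL
    bres <- tryCatch(suppressWarnings(
      fit_binding(double_log_points(free, quench_floor = config$quench_floor),
                  min_segment = config$min_segment, alpha = config$alpha,
                  breakpoint_x = sv_bp)),
      error = function(e) NULL)
    warf_single <- NA
    if (has_warfarin) {
      warf <- correct_series(panel$series[[paste0("warfarin_", t0)]],
                             path_weight = config$path_weight)
      wfit <- tryCatch(suppressWarnings(
        sv_fit(warf, min_segment = config$min_segment, alpha = config$alpha)),
        error = function(e) NULL)
      warf_single <- if (is.null(wfit)) NA else !wfit$two_segment
    }
    tibble::tibble(
      replicate = i,
      ksv1 = if (!is.null(qres)) qres$ksv1 else NA_real_,
      ksv2 = if (!is.null(qres)) qres$ksv2 else NA_real_,
      sv_two_segment = if (!is.null(qres)) qres$fit$two_segment else NA,
      order_ok = if (!is.null(qres) && !is.na(qres$ksv2)) {
        qres$ksv1 > qres$ksv2
      } else NA,
      kb1 = if (!is.null(bres)) bres$kb1 else NA_real_,
      n1 = if (!is.null(bres)) bres$n1 else NA_real_,
      warfarin_single = warf_single,
      K1_true = K1_true, K2_true = K2_true)
  }
  do.call(rbind, lapply(seq_len(replicates), one))
}
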