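#' Site-marker semantics
#'
#' Which of the two modelled ligand sites each marker condition occupies:
#' warfarin is the drug site 1 marker, hemin the fatty-acid site 1 (the
#' modelled secondary site) marker, ibuprofen marks drug site 2, which the
#' two-site model does not use, so it blocks neither modelled site and acts
#' as a negative control.
#'
#' @return a tibble with columns `label`, `blocks_site1`, `blocks_site2`.
#' @export
marker_conditions <- function() {
  tibble::tibble(
    label = c("free", "warfarin", "ibuprofen", "hemin", "warfarin+hemin"),
    blocks_site1 = c(FALSE, TRUE, FALSE, FALSE, TRUE),
    blocks_site2 = c(FALSE, FALSE, FALSE, TRUE, TRUE))
}

#' Analyze a marker-competition panel
#'
#' Runs the full quenching + binding pipeline on each condition of a panel
#' measured at one temperature, classifies each Stern-Volmer curve as
#' `"linear"` (one regime) or `"downward"` (two regimes), and raises the
#' allosteric flag when the warfarin-blocked condition binds more strongly
#' at the remaining (secondary) site than the free protein does. Conditions
#' whose data defeat part of the pipeline (e.g. quenching too weak for a
#' binding fit) yield `NA` entries and a collected warning, never an abort:
#' real competition panels are noisy.
#'
#' @param series_by_condition a list of [titration_series] at one
#'   temperature, containing a `"free"` condition.
#' @param tau0 unquenched fluorophore lifetime, s.
#' @param min_segment,alpha segmented-fit controls.
#' @param quench_floor passed to [double_log_points()].
#' @return an object of class `competition_report`: `table` (one row per
#'   condition), `temperature_C`, `allosteric_flag`, `details` (per-condition
#'   fit objects) and `warnings`.
#' @export
analyze_panel <- function(series_by_condition, tau0 = .TAU0_DEFAULT,
                          min_segment = 3, alpha = 0.05,
                          quench_floor = 1e-3) {
  stopifnot(is.list(series_by_condition), length(series_by_condition) > 0L)
  conds <- vapply(series_by_condition, function(s) s$condition, character(1L))
  if (!"free" %in% conds) {
    stop("competition panel must contain a 'free' condition", call. = FALSE)
  }
  temps <- vapply(series_by_condition, function(s) s$temperature_C, numeric(1L))
  if (length(unique(temps)) != 1L) {
    stop("competition panel must be measured at a single temperature",
         call. = FALSE)
  }

  notes <- character(0)
  details <- list()
  rows <- list()
  for (i in seq_along(series_by_condition)) {
    s <- series_by_condition[[i]]
    qres <- tryCatch(
      withCallingHandlers(
        quenching_constants(sv_fit(s, min_segment = min_segment,
                                   alpha = alpha), tau0 = tau0),
        warning = function(w) {
          notes <<- c(notes, paste0(s$condition, ": ", conditionMessage(w)))
          invokeRestart("muffleWarning")
        }),
      error = function(e) {
        notes <<- c(notes, paste0(s$condition, ": ", conditionMessage(e)))
        NULL
      })
    sv_bp <- if (!is.null(qres) && qres$fit$two_segment) {
      log10(qres$fit$breakpoint_x)
    } else NULL
    bres <- tryCatch(
      withCallingHandlers(
        fit_binding(double_log_points(s, quench_floor = quench_floor),
                    min_segment = min_segment, alpha = alpha,
                    breakpoint_x = sv_bp),
        warning = function(w) {
          notes <<- c(notes, paste0(s$condition, ": ", conditionMessage(w)))
          invokeRestart("muffleWarning")
        }),
      error = function(e) {
        notes <<- c(notes, paste0(s$condition, ": ", conditionMessage(e)))
        NULL
      })

    two <- if (!is.null(qres)) qres$fit$two_segment else NA
    rows[[s$condition]] <- tibble::tibble(
      condition = s$condition,
      curvature_class = if (is.na(two)) NA_character_ else
        if (two) "downward" else "linear",
      inferred_free_sites = if (is.na(two)) NA_integer_ else
        if (two) 2L else 1L,
      ksv1 = if (!is.null(qres)) qres$ksv1 else NA_real_,
      ksv2 = if (!is.null(qres)) qres$ksv2 else NA_real_,
      kq1 = if (!is.null(qres)) qres$kq1 else NA_real_,
      kq2 = if (!is.null(qres)) qres$kq2 else NA_real_,
      kb1 = if (!is.null(bres)) bres$kb1 else NA_real_,
      kb2 = if (!is.null(bres)) bres$kb2 else NA_real_,
      n1 = if (!is.null(bres)) bres$n1 else NA_real_,
      n2 = if (!is.null(bres)) bres$n2 else NA_real_)
    details[[s$condition]] <- list(quenching = qres, binding = bres)
  }
  table <- do.call(rbind, rows)

  free_kb2 <- table$kb2[table$condition == "free"]
  warf_kb1 <- if ("warfarin" %in% table$condition) {
    table$kb1[table$condition == "warfarin"]
  } else NA_real_
  allosteric_flag <- isTRUE(!is.na(free_kb2) && !is.na(warf_kb1) &&
                              warf_kb1 > free_kb2)

  structure(list(table = table,
                 temperature_C = temps[1L],
                 allosteric_flag = allosteric_flag,
                 details = details,
                 warnings = notes),
            class = "competition_report")
}

#' @export
print.competition_report <- function(x, ...) {
  cat(sprintf("<competition_report> %d condition(s) at %.4g degC, allosteric flag: %s\n",
              nrow(x$table), x$temperature_C, x$allosteric_flag))
  print(x$table)
  invisible(x)
}

# Relative closeness used by the inference rules: real panels are noisy, so
# "unchanged" means within a generous relative band rather than equality.
.near <- function(a, b, tol = 0.25) {
  !is.na(a) && !is.na(b) && abs(a - b) <= tol * max(abs(a), abs(b))
}

#' Infer ligand binding sites from a competition report
#'
#' Applies the marker-displacement logic: a condition that collapses the
#' free protein's two-regime curve to a straight line has one modelled site
#' occupied by its marker, so the ligand uses that marker's site; a
#' condition indistinguishable from free protein shows its marker's site is
#' not a ligand site; the ordering of the single-regime binding constants
#' ranks the sites' affinities. Contradictory patterns (e.g. a linear free
#' curve turning two-regime under a blocker) produce an inconclusive verdict
#' with diagnostics rather than an error.
#'
#' @param report a `competition_report` from [analyze_panel()].
#' @return a list with `assignment` (text verdict), `evidence` (character
#'   vector of observations) and `conclusive` (logical).
#' @export
infer_sites <- function(report) {
  stopifnot(inherits(report, "competition_report"))
  tb <- report$table
  get <- function(cond, col) {
    v <- tb[[col]][tb$condition == cond]
    if (length(v) == 0L) NA else v
  }
  markers <- setdiff(tb$condition, "free")
  if (length(markers) == 0L) {
    return(list(assignment = "inconclusive: free condition only",
                evidence = "no marker condition to compare against",
                conclusive = FALSE))
  }

  free_class <- get("free", "curvature_class")
  evidence <- character(0)

  # Contradiction guard: a blocker cannot expose more regimes than the free
  # protein shows.
  if (identical(free_class, "linear")) {
    twos <- markers[vapply(markers, function(m) {
      identical(get(m, "curvature_class"), "downward")
    }, logical(1L))]
    if (length(twos) > 0L) {
      return(list(
        assignment = "inconclusive: contradictory curvature pattern",
        evidence = paste0("free curve is linear but condition '", twos,
                          "' shows two regimes"),
        conclusive = FALSE))
    }
  }

  unchanged <- vapply(markers, function(m) {
    identical(get(m, "curvature_class"), free_class) &&
      .near(get(m, "ksv1"), get("free", "ksv1"))
  }, logical(1L))

  if (all(unchanged)) {
    return(list(
      assignment = "no modeled site is shared with any tested marker",
      evidence = paste0("condition '", markers,
                        "' indistinguishable from free protein"),
      conclusive = TRUE))
  }

  warf_linear <- identical(get("warfarin", "curvature_class"), "linear")
  hemin_linear <- identical(get("hemin", "curvature_class"), "linear")
  ibu_unchanged <- "ibuprofen" %in% markers && unchanged[["ibuprofen"]]

  if (identical(free_class, "downward") && warf_linear && hemin_linear) {
    evidence <- c(evidence,
                  "two regimes for free protein: two ligand sites",
                  "linear under warfarin: drug site 1 is a ligand site",
                  "linear under hemin: the fatty-acid/hemin site is a ligand site")
    kb_hemin <- get("hemin", "kb1")   # site 1 left free
    kb_warf <- get("warfarin", "kb1") # site 2 left free
    if (!is.na(kb_hemin) && !is.na(kb_warf)) {
      evidence <- c(evidence, sprintf(
        "single-site kb: %.3g (site 1, under hemin) vs %.3g (site 2, under warfarin): %s site binds more strongly",
        kb_hemin, kb_warf, if (kb_hemin > kb_warf) "the drug site 1" else "the hemin"))
    }
    if (ibu_unchanged) {
      evidence <- c(evidence,
                    "unchanged under ibuprofen: drug site 2 is not a ligand site")
    }
    assignment <- paste0(
      "primary site = drug site 1 (warfarin site); ",
      "secondary site = fatty-acid site 1 (hemin site)",
      if (ibu_unchanged) "; drug site 2 not used" else "")
    if (report$allosteric_flag) {
      evidence <- c(evidence,
                    "secondary-site binding enhanced under warfarin: allosteric coupling")
    }
    return(list(assignment = assignment, evidence = evidence,
                conclusive = TRUE))
  }

  # Partial patterns: report what each marker shows without forcing a verdict.
  for (m in markers) {
    cls <- get(m, "curvature_class")
    evidence <- c(evidence, sprintf(
      "condition '%s': %s curve%s", m,
      if (is.na(cls)) "unclassifiable" else cls,
      if (!is.na(unchanged[m]) && unchanged[m]) " (unchanged from free)" else ""))
  }
  list(assignment = "partial evidence only; see evidence list",
       evidence = evidence, conclusive = FALSE)
}
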