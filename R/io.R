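#' Read titration data from CSV
#'
#' Reads a tidy titration table and returns one [titration_series] per
#' (condition, temperature) group. Two dialects are accepted:
#'
#' * summary format: `condition, temperature_C, quencher_total_M, intensity`
#'   with optional `absorbance_ex`, `absorbance_em` and `protein_conc_M`;
#' * spectral long format: `condition, temperature_C, quencher_total_M,
#'   wavelength_nm, intensity`, reduced per point via [intensity_at()].
#'
#' Concentrations may instead be given in micromolar through a
#' `quencher_total_uM` column (converted to mol/L on read); everything is
#' stored in mol/L internally. Row order is irrelevant: series are sorted by
#' quencher concentration, so a shuffled file parses to the identical result.
#'
#' @param source path to a CSV file, a literal CSV string, or a connection
#'   (anything [readr::read_csv()] accepts).
#' @param wavelength analysis wavelength in nm for spectral input, or
#'   `"peak"`; ignored for summary input. Default 340 nm, the tryptophan
#'   emission maximum.
#' @return a named list of [titration_series] (names `condition_temperature`).
#' @export
read_titration_csv <- function(source, wavelength = 340) {
  tbl <- readr::read_csv(source, show_col_types = FALSE, progress = FALSE)
  names(tbl) <- trimws(names(tbl))

  if ("quencher_total_uM" %in% names(tbl) &&
      !"quencher_total_M" %in% names(tbl)) {
    tbl$quencher_total_M <- tbl$quencher_total_uM * 1e-6
    tbl$quencher_total_uM <- NULL
  }
  required <- c("condition", "temperature_C", "quencher_total_M", "intensity")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0L) {
    stop("titration CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  spectral <- "wavelength_nm" %in% names(tbl)
  if (spectral) {
    tbl <- .reduce_spectral(tbl, wavelength)
  }

  key <- interaction(tbl$condition, tbl$temperature_C, drop = TRUE)
  groups <- split(tbl, key)
  series <- lapply(groups, function(g) {
    if (anyDuplicated(g$quencher_total_M)) {
      stop("duplicate (condition, temperature, quencher) rows for condition '",
           g$condition[1L], "' at ", g$temperature_C[1L], " degC", call. = FALSE)
    }
    pts <- tibble::tibble(quencher_M = g$quencher_total_M,
                          intensity = g$intensity)
    for (col in c("absorbance_ex", "absorbance_em")) {
      if (col %in% names(g)) pts[[col]] <- g[[col]]
    }
    pconc <- if ("protein_conc_M" %in% names(g)) g$protein_conc_M[1L] else 3e-6
    titration_series(as.character(g$condition[1L]), g$temperature_C[1L],
                     pts, protein_conc_M = pconc)
  })
  names(series) <- vapply(series, function(s) {
    paste0(s$condition, "_", s$temperature_C)
  }, character(1L))
  series[order(names(series))]
}

# Collapse long-format spectra to one intensity per titration point.
.reduce_spectral <- function(tbl, wavelength) {
  key <- interaction(tbl$condition, tbl$temperature_C, tbl$quencher_total_M,
                     drop = TRUE)
  rows <- lapply(split(tbl, key), function(g) {
    g <- g[order(g$wavelength_nm), , drop = FALSE]
    spec <- emission_spectrum(g$wavelength_nm, g$intensity,
                              temperature_C = g$temperature_C[1L])
    out <- g[1L, setdiff(names(g), c("wavelength_nm", "intensity")),
             drop = FALSE]
    out$intensity <- intensity_at(spec, wavelength)
    out
  })
  do.call(rbind, rows)
}

#' Read an absorbance sidecar CSV
#'
#' Columns: `condition, temperature_C, quencher_total_M, absorbance_ex,
#' absorbance_em` (a `quencher_total_uM` column is converted as in
#' [read_titration_csv()]).
#'
#' @param source path, literal CSV string, or connection.
#' @return a tibble.
#' @export
read_absorbance_csv <- function(source) {
  tbl <- readr::read_csv(source, show_col_types = FALSE, progress = FALSE)
  names(tbl) <- trimws(names(tbl))
  if ("quencher_total_uM" %in% names(tbl) &&
      !"quencher_total_M" %in% names(tbl)) {
    tbl$quencher_total_M <- tbl$quencher_total_uM * 1e-6
    tbl$quencher_total_uM <- NULL
  }
  required <- c("condition", "temperature_C", "quencher_total_M",
                "absorbance_ex", "absorbance_em")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0L) {
    stop("absorbance CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(tbl)
}

#' Attach sidecar absorbances to titration series
#'
#' Joins per-point absorbances (at the excitation and emission wavelengths)
#' onto each series by condition, temperature and quencher concentration.
#'
#' @param series_list a list of [titration_series].
#' @param absorbance a tibble from [read_absorbance_csv()].
#' @return the list with `absorbance_ex`/`absorbance_em` columns filled.
#' @export
attach_absorbance <- function(series_list, absorbance) {
  lapply(series_list, function(s) {
    sel <- absorbance$condition == s$condition &
      absorbance$temperature_C == s$temperature_C
    ab <- absorbance[sel, , drop = FALSE]
    idx <- match(s$points$quencher_M, ab$quencher_total_M)
    if (anyNA(idx)) {
      stop("absorbance sidecar is missing points for condition '",
           s$condition, "' at ", s$temperature_C, " degC", call. = FALSE)
    }
    s$points$absorbance_ex <- ab$absorbance_ex[idx]
    s$points$absorbance_em <- ab$absorbance_em[idx]
    s
  })
}

#' Write titration series to CSV
#'
#' Inverse of [read_titration_csv()] for the summary dialect; round-trips
#' validated series exactly (numbers are written with full round-trip
#' precision).
#'
#' @param series_list a list of [titration_series].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(series_list, path) {
  rows <- lapply(series_list, function(s) {
    out <- tibble::tibble(condition = s$condition,
                          temperature_C = s$temperature_C,
                          quencher_total_M = s$points$quencher_M,
                          intensity = s$points$intensity,
                          protein_conc_M = s$protein_conc_M)
    for (col in c("absorbance_ex", "absorbance_em")) {
      if (col %in% names(s$points)) out[[col]] <- s$points[[col]]
    }
    out
  })
  readr::write_csv(do.call(rbind, rows), path, progress = FALSE)
  invisible(path)
}

#' Write an analysis report as JSON
#'
#' Serializes the report produced by [run_analysis()] with full numeric
#' precision. Reading it back with [read_report()] reproduces the values.
#'
#' @param report an analysis report (non-empty list).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (!is.list(report) || length(report) == 0L) {
    stop("report is empty; run the analysis first", call. = FALSE)
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read an analysis report written by [write_report()]
#' @param path file path.
#' @return the report as a list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                      simplifyMatrix = FALSE)
}
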