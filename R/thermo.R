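#' Van't Hoff analysis of binding constants
#'
#' Ordinary least squares of `ln kb` against `1/T`:
#' `ln kb = -dH/(R T) + dS/R`, so `dH = -R * slope` and `dS = R * intercept`.
#' The regression is unweighted. Gibbs energies are filled for every input
#' temperature through `dG = dH - T * dS`.
#'
#' @param kb binding constants, L/mol, all > 0.
#' @param temperature_K absolute temperatures, K, all distinct; same length
#'   as `kb`, at least 2.
#' @return an object of class `thermo_result`: `delta_H_kJ_mol`,
#'   `delta_S_J_mol_K`, `delta_G_kJ_mol` (named by temperature, K),
#'   `r_squared`, `gas_constant`.
#' @examples
#' # kb synthesized from dH = -50 kJ/mol, dS = -40 J/mol/K is recovered exactly
#' Tk <- c(298.15, 308.15, 318.15)
#' kb <- exp(50e3 / (8.314 * Tk) - 40 / 8.314)
#' vant_hoff(kb, Tk)
#' @export
vant_hoff <- function(kb, temperature_K) {
  kb <- as.numeric(kb)
  temperature_K <- as.numeric(temperature_K)
  if (length(kb) != length(temperature_K)) {
    stop("kb and temperature_K must have the same length", call. = FALSE)
  }
  if (length(unique(temperature_K)) < 2L) {
    stop("Van't Hoff regression needs >= 2 distinct temperatures",
         call. = FALSE)
  }
  if (any(duplicated(temperature_K))) {
    stop("duplicate temperatures", call. = FALSE)
  }
  if (any(!is.finite(kb)) || any(kb <= 0)) {
    stop("binding constants must be finite and > 0", call. = FALSE)
  }
  if (any(temperature_K <= 0)) stop("temperatures must be > 0 K", call. = FALSE)

  line <- .ols_line(1 / temperature_K, log(kb))
  delta_H <- -.R_J * line$slope / 1000     # kJ/mol
  delta_S <- .R_J * line$intercept         # J/mol/K
  delta_G <- gibbs(delta_H, delta_S, temperature_K)
  names(delta_G) <- format(temperature_K, trim = TRUE)
  structure(list(delta_H_kJ_mol = delta_H,
                 delta_S_J_mol_K = delta_S,
                 delta_G_kJ_mol = delta_G,
                 r_squared = line$r2,
                 gas_constant = .R_J),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("<thermo_result> dH = %.4g kJ/mol, dS = %.4g J/mol/K (R2 = %.4f)\n",
              x$delta_H_kJ_mol, x$delta_S_J_mol_K, x$r_squared))
  for (i in seq_along(x$delta_G_kJ_mol)) {
    cat(sprintf("  dG(%s K) = %.4g kJ/mol\n",
                names(x$delta_G_kJ_mol)[i], x$delta_G_kJ_mol[i]))
  }
  invisible(x)
}

#' Gibbs free energy from enthalpy and entropy
#'
#' `dG = dH - T * dS`, with `dH` in kJ/mol, `dS` in J/mol/K and the result in
#' kJ/mol (the 1000 handles the J/kJ mismatch). Vectorised over temperature.
#'
#' @param delta_H enthalpy change, kJ/mol.
#' @param delta_S entropy change, J mol^-1 K^-1.
#' @param temperature_K absolute temperature(s), K, > 0.
#' @return Gibbs energy change(s), kJ/mol.
#' @export
gibbs <- function(delta_H, delta_S, temperature_K) {
  if (any(temperature_K <= 0)) stop("temperature must be > 0 K", call. = FALSE)
  delta_H - temperature_K * delta_S / 1000
}

#' Entropy from enthalpy and Gibbs energy
#'
#' Algebraic inverse of [gibbs()] at fixed enthalpy and temperature:
#' `dS = (dH - dG) * 1000 / T` in J mol^-1 K^-1.
#'
#' @param delta_H enthalpy change, kJ/mol.
#' @param delta_G Gibbs energy change, kJ/mol.
#' @param temperature_K absolute temperature, K, > 0.
#' @return entropy change, J mol^-1 K^-1.
#' @export
entropy_from_enthalpy_gibbs <- function(delta_H, delta_G, temperature_K) {
  if (any(temperature_K <= 0)) stop("temperature must be > 0 K", call. = FALSE)
  (delta_H - delta_G) * 1000 / temperature_K
}

#' Inhibition constant from a docking binding free energy
#'
#' Docking programs report an estimated inhibition constant alongside the
#' binding free energy via `Ki = exp(dG / (R T))` with `R` in kcal mol^-1
#' K^-1 (1.987e-3) and `T = 298.15 K` by convention.
#'
#' @param delta_G_kcal binding free energy, kcal/mol (negative for
#'   favourable binding).
#' @param temperature_K absolute temperature, K.
#' @return inhibition constant `Ki` in mol/L.
#' @examples
#' ki_from_binding_energy(-10.1) * 1e6  # ~0.04 uM
#' @export
ki_from_binding_energy <- function(delta_G_kcal, temperature_K = 298.15) {
  if (any(temperature_K <= 0)) stop("temperature must be > 0 K", call. = FALSE)
  exp(delta_G_kcal / (.R_KCAL * temperature_K))
}

#' Binding free energy from an inhibition constant
#'
#' Inverse of [ki_from_binding_energy()]: `dG = R T ln(Ki)` in kcal/mol.
#'
#' @param ki inhibition constant, mol/L, > 0.
#' @param temperature_K absolute temperature, K.
#' @return binding free energy, kcal/mol.
#' @export
binding_energy_from_ki <- function(ki, temperature_K = 298.15) {
  if (any(ki <= 0)) stop("Ki must be > 0", call. = FALSE)
  if (any(temperature_K <= 0)) stop("temperature must be > 0 K", call. = FALSE)
  .R_KCAL * temperature_K * log(ki)
}

#' Dominant interaction forces from the thermodynamic signature
#'
#' The sign pattern of the enthalpy and entropy changes is the classical
#' fingerprint of the dominant non-covalent forces: both negative points to
#' hydrogen bonding and Van der Waals contacts, both positive to hydrophobic
#' interactions, and mixed signs to a combination.
#'
#' @param delta_H enthalpy change, kJ/mol.
#' @param delta_S entropy change, J mol^-1 K^-1.
#' @return `"hydrogen_bond_vdw"`, `"hydrophobic"` or `"mixed"`.
#' @export
force_signature <- function(delta_H, delta_S) {
  if (delta_H < 0 && delta_S < 0) return("hydrogen_bond_vdw")
  if (delta_H > 0 && delta_S > 0) return("hydrophobic")
  "mixed"
}
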