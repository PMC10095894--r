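# Independent oracles and fixture builders shared across the suite.

# Brute-force breakpoint enumeration using lm(), independent of the package's
# OLS internals. Returns the SSE-minimising split (ties to the earlier
# breakpoint) or NULL when no admissible split exists.
brute_force_breakpoint <- function(x, y, min_segment = 3) {
  n <- length(x)
  if (n < 2 * min_segment) return(NULL)
  best <- NULL
  for (k in min_segment:(n - min_segment)) {
    i1 <- seq_len(k)
    i2 <- (k + 1):n
    m1 <- stats::lm(y[i1] ~ x[i1])
    m2 <- stats::lm(y[i2] ~ x[i2])
    sse <- sum(stats::residuals(m1)^2) + sum(stats::residuals(m2)^2)
    if (is.null(best) || sse < best$sse) best <- list(k = k, sse = sse)
  }
  best
}

# Free-ligand mass balance solved with uniroot instead of the package's
# bisection.
free_ligand_oracle <- function(K1, K2, P, Qt) {
  if (Qt == 0) return(0)
  f <- function(q) {
    q + P * (K1 * q / (1 + K1 * q) + K2 * q / (1 + K2 * q)) - Qt
  }
  stats::uniroot(f, c(0, Qt), tol = 1e-18)$root
}

# Perfect single-site titration: fully quenched complex, F = F0 / (1 + K [Q]).
single_site_series <- function(K, F0 = 1000, quencher_M = seq(0, 10e-6, 1e-6),
                               condition = "free", temperature_C = 25) {
  titration_series(condition, temperature_C, tibble::tibble(
    quencher_M = quencher_M,
    intensity = F0 / (1 + K * quencher_M)))
}

# Summary-format CSV text for a titration (condition, temperature fixed).
titration_csv_text <- function(quencher_M, intensity, condition = "free",
                               temperature_C = 25) {
  paste(c("condition,temperature_C,quencher_total_M,intensity",
          sprintf("%s,%g,%.10g,%.10g", condition, temperature_C,
                  quencher_M, intensity)),
        collapse = "\n")
}
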