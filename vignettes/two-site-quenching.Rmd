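---
title: "Two-site analysis of fluorescence quenching titrations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-site analysis of fluorescence quenching titrations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sternvolmer)
```

This vignette is the package's account of the science it implements: the
models, the assumptions behind them, the parameters a user may want to
move, the numerical choices that were genuinely open, and what the
simulation-based validation does and does not demonstrate about real data.

## The measurement and its correction

A titration series is a fixed concentration of fluorescent protein
(typically 3 µM serum albumin, whose single tryptophan reports on the
drug-site region) measured at increasing total ligand concentration
`[Q]` (0–10 µM here), at one temperature. The first point must be
ligand-free; it defines `F0`.

Ligands that absorb at the excitation or emission wavelength attenuate the
measured signal (the inner filter effect) and bias every downstream
constant. For a 1 cm cuvette with centred right-angle optics the standard
path-averaged correction is

`F_corr = F_obs · 10^((A_ex + A_em)/2)`.

Assumptions: absorbances below ~2 AU (beyond that the factor is returned
but flagged unreliable, default ceiling configurable), and no geometric or
wavelength-resolved re-absorption effects. The half-path weight 0.5 is a
`path_weight` argument should a different cuvette geometry require it.
Absorbances come from a per-point sidecar table or from a linear model
`A = ε·[Q] + baseline` with user-supplied extinction coefficients.

Emission spectra, when supplied in long format, are reduced to a single
intensity at a fixed analysis wavelength (default 340 nm, the tryptophan
emission maximum) by linear interpolation; a `"peak"` mode follows the band
maximum instead. Fixed-wavelength reduction is the default because it is
reproducible under the small band shifts that ligand binding induces.

## Segmented Stern–Volmer analysis

Static quenching by a bound ligand obeys `F0/F = 1 + K_SV [Q]` per
accessibility class. With two sites of unequal quenching efficiency the
plot is concave toward the concentration axis, and the practice in the
albumin literature is to read two constants off the two approximately
linear portions. The package makes that reproducible:

* every admissible breakpoint (each segment at least `min_segment = 3`
  points) over the observed abscissae is evaluated exhaustively — with at
  most a dozen titration points this is exact and cheap;
* both blocks are fit by ordinary least squares with free intercepts (the
  first segment's intercept near 1 is a diagnostic, not a constraint);
* the split minimising the total squared error wins, ties going to the
  earlier breakpoint so results are deterministic;
* the two-regime model is kept only if an extra-parameters F-test (2 extra
  parameters) against the single line is significant at `alpha = 0.05`.

One selection subtlety matters and was measured during development: taking
the best of several breakpoints inflates the naive F-test, so on genuinely
straight noisy data the two-regime model would be accepted far more often
than `alpha` suggests (about 22 % at 0.5 % noise on an 11-point grid). The
p-value is therefore Bonferroni-corrected by the number of candidate
breakpoints searched, which restores the intended operating characteristic
(≥ 95 % correct single-line classification at that noise level) while
losing no power on data with a real breakpoint. Perfectly collinear data
are recognised by a relative tolerance (`1e-18` on the squared spread of
the ordinates) rather than an exact-zero test.

At the quenching layer, a second segment *steeper* than the first is not a
two-site signature (downward curvature is), so such fits are demoted to the
single line. Constants then follow as `K_SV1 = slope1`, `K_SV2 = slope2`,
`K_q,i = K_SV,i / τ0` with `τ0 = 5.9 ns` by default (the literature value
for albumin tryptophan; configurable). The quotient form is used even
though part of the source literature prints the relation as a product —
only `K_SV/τ0` produces the >10¹⁰ L mol⁻¹ s⁻¹ magnitudes that the static
mechanism argument relies on; the printed product is a typographical slip.

Mechanism classification across a temperature ladder is deliberately
conservative: *static* requires every `K_q1` above the diffusion limit
(10¹⁰ L mol⁻¹ s⁻¹) **and** strictly decreasing `K_SV1`; *dynamic* the
converse; anything else is *indeterminate* rather than forced.

## Double-logarithmic binding analysis

For static quenching, `log10((F0−F)/F) = log10(k_b) + n·log10([Q])`, so
each linear portion gives a binding constant (intercept) and an apparent
site number (slope). Base-10 logarithms are used throughout so that the
intercept is directly the order of magnitude of `k_b`. Points that cannot
enter the transform are dropped with warnings: the zero-ligand point,
points with `F ≥ F0`, and points with relative quenching below
`quench_floor = 1e-3`, where the logarithm of near-zero quenching is
numerically meaningless.

The segmentation itself reuses the machinery above, with one pipeline-level
refinement. The two diagnostic plots describe the same two occupancy
regimes of the same titration, but their noise behaviour is very
different: at low quenching the log-log ordinate amplifies intensity noise
roughly by `1/quenching`, whereas the Stern–Volmer ordinate does not.
Simulation during development showed that letting the two fits choose
breakpoints independently makes the recovered `k_b1` swing over a factor
of two at 1 % intensity noise purely through selection jitter (the
intercept extrapolates almost six decades, so a slope wobble of 0.05 moves
`k_b` by 2×). The pipeline therefore parts the double-log points at the
concentration where the Stern–Volmer fit placed its breakpoint — the same
convention the bench analysis uses when it reads both plots as "the first
and the second linear portion". `fit_binding()` called directly, without a
carried-over breakpoint, still selects its own split.

A two-regime double-log fit must satisfy `k_b1 > k_b2`; otherwise it does
not describe a primary/secondary pair and is demoted with a warning. `k_b`
is reported in L/mol even when `n ≠ 1` (formally the unit is `(L/mol)^n`);
`n` is always carried alongside.

## Thermodynamics

Unweighted ordinary least squares of `ln k_b` on `1/T` (the linear Van't
Hoff model, constant ΔH over the 20 K window studied):
`ΔH = −R·slope`, `ΔS = R·intercept`, `R = 8.314 J mol⁻¹ K⁻¹`. Gibbs
energies are *defined* here as `ΔG = ΔH − TΔS` — the package keeps that
identity exact in every `thermo_result` rather than recomputing
`−RT ln k_b`, because the two routes differ slightly once constants are
rounded, and the enthalpy/entropy route is the one that reproduces
published tables self-consistently. The algebraic inverse
`ΔS = (ΔH − ΔG)·1000/T` is provided for checking printed tables.

Docking free energies (kcal/mol) convert to inhibition constants with
`Ki = exp(ΔG/(R_kcal·T))`, `R_kcal = 1.987e-3 kcal mol⁻¹ K⁻¹`,
`T = 298.15 K` by convention; the inverse is exact. The force signature
follows the classical sign fingerprint: ΔH and ΔS both negative — hydrogen
bonding/Van der Waals; both positive — hydrophobic; mixed — both force
classes contribute.

## Site-marker competition

Marker semantics are fixed by albumin pharmacology: warfarin occupies drug
site 1, hemin fatty-acid site 1 (the modelled secondary site), ibuprofen
drug site 2 (not a site of the two-site model — a negative control), and
warfarin+hemin both modelled sites. `analyze_panel()` runs the full
pipeline per condition at one temperature and classifies each curve as
`downward` (two regimes) or `linear`. The inference rules are:

* a blocker that collapses the free protein's two-regime curve to a line
  occupies a ligand site;
* a condition indistinguishable from free protein (same class, `K_SV1`
  within 25 %) rules its marker's site out;
* the single-regime `k_b` values under complementary blockers rank the
  sites' affinities;
* the *allosteric flag* is raised when the warfarin-blocked condition
  yields a larger `k_b` than the free protein's secondary site — apparent
  site-coupling;
* contradictory patterns (free curve linear but a blocked curve
  two-regime) give an inconclusive verdict with diagnostics, never an
  error — real panels are noisy.

## The synthetic titration generator

The generator exists so the pipeline can be validated end to end with a
known truth. It emulates, by construction, exactly the statistical
structure the analysis assumes:

* **two-site static quenching**: `F = F0·(1 − q1·θ1 − q2·θ2)` with
  occupancies `θi = K_i Q/(1 + K_i Q)` — occupied sites remove a fixed
  fraction (`q_i`) of the intrinsic fluorescence, unoccupied protein
  fluoresces fully (no collisional term);
* **per-site thermodynamics**: `K_i(T) = exp(−ΔH_i/RT + ΔS_i/R)`, so a
  simulated temperature ladder is exactly Van't Hoff-linear;
* **ligand optics**: `A_ex = ε_ex[Q] + baseline`, `A_em = ε_em[Q]`, and
  the observation applies `10^(−(A_ex+A_em)/2)` — the same attenuation the
  correction module removes, making the round trip exact at zero noise;
* **noise**: multiplicative Gaussian on intensities only (absorbances are
  noise-free), the simplest model that stresses both the ratio and the
  double-log transforms;
* **marker occupancy**: blocked sites contribute zero occupancy; with both
  sites blocked a weak residual site (`residual_K = 2e4 L/mol`, efficiency
  `0.2·q1`) stands in for nonspecific association, so the double-marker
  condition retains weak curvature; an `allosteric_factor` multiplies `K2`
  when site 1 is blocked (default 1 — no coupling is assumed unless a
  study asks for it);
* **determinism**: one seed per panel, split into fixed per-condition,
  per-temperature sub-streams, so adding a condition to a design never
  changes the draws of the others; identical configuration and seed give
  byte-identical files.

### Calibration of the defaults

The default truth was calibrated once, before the validation suite was
frozen, so that running the *full analysis* on a simulated 25 °C panel
lands on the scale of published corrected constants for the
indomethacin–albumin system: primary-site `k_b` near 5.9×10⁵ L/mol with
`n` near 1.05, and a secondary Stern–Volmer segment near 1.5×10⁵ L/mol.
The calibrated values are `ΔH1 = −47.4 kJ/mol`, `ΔS1 = −48.9 J mol⁻¹ K⁻¹`
(`K1(25 °C) = 5.6e5 L/mol`), `ΔH2 = −11.6`, `ΔS2 = 23.9`
(`K2(25 °C) = 1.9e3`), `q1 = 0.8`, `q2 = 0.1`, `ε_ex = 1e4`,
`ε_em = 2.5e3 L mol⁻¹ cm⁻¹`, `baseline_ex = 0.05 AU`, `noise_cv = 0.01`.

Two calibration findings shaped the model and are worth recording:

* **Free-ligand depletion is on by default** (`ligand_depletion =
  "exact"`, a bisection solve of the two-site mass balance, residual below
  `1e-12·[Q]_total`). At 3 µM protein and `K1 ≈ 6e5 L/mol` most of the
  ligand is bound at the low end of the titration; this is the physical
  regime of the experiment, and it is also what produces double-log slopes
  slightly above 1 and intercepts at the published magnitude. With
  depletion off, the apparent `k_b1` of this analysis cannot exceed about
  a quarter of the true `K1` for any admissible quench efficiencies — a
  bias worth knowing about when reading published constants.
* **Apparent multi-temperature constants are biased.** Because the
  depletion-induced bias varies with `K1(T)`, a Van't Hoff regression over
  *recovered* `k_b1` values overestimates the enthalpy magnitude (by tens
  of percent at these settings) even though regression over the *true*
  constants is exact. The package therefore validates Van't Hoff recovery
  on true constants, and treats thermodynamics from fitted constants as
  what they are on real data too: estimates inheriting the method's
  biases.

### What the simulations do not show

The generator draws from the same model family the analysis assumes, so
passing recovery tests demonstrates internal consistency and correct
numerics — not robustness to the ways real spectra deviate: band-shape
changes on binding, baseline drift and photobleaching, correlated
instrument noise, marker–ligand exchange kinetics (markers are binary,
fully equilibrated occupancy here), or ternary equilibria. One model-level
consequence deserves emphasis: a noiseless single-free-site curve in this
family is strictly concave, and the F-test detects that curvature at *any*
amplitude on noiseless data (the SSE ratio is scale-invariant), so the
"straight line under a single marker" classification seen on the bench
emerges only at realistic noise, where the residual curvature is below the
noise floor. Classification tests are therefore run at the generator's
default 1 % noise, and only the two-free-site ⇒ downward half of the
pattern is asserted noiselessly.

### Problem sizes

Validation uses the study's own design throughout: 11-point titrations,
three temperatures, five conditions, and 20-replicate recovery studies at
1 % noise; oracle-equivalence suites use 500 random segmented-fit
instances (≤ 20 points) and 100 random mass-balance draws. The full suite
runs in well under a minute.

## Known limitations

* Only the static-quenching mixture model is considered: no modified
  Stern–Volmer (`1/ΔF` vs `1/[Q]`), sphere-of-action, or lifetime-resolved
  analysis.
* Two sites at most; the residual-site emulation for the double-blocked
  condition is a stand-in, not a mechanistic model.
* Unweighted regressions everywhere, matching field practice; no
  heteroscedasticity handling on the log scale.
* The linear Van't Hoff form assumes ΔCp = 0 over the temperature window.
* The allosteric flag compares apparent constants; it is a coarse
  indicator, and at the default truth (secondary signal near the noise
  floor) it stays down for any plausible coupling strength.
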