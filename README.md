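# sternvolmer

Analysis of protein–ligand fluorescence quenching titrations with a primary
and a secondary binding site.

Serum albumins carry most small-molecule drugs in plasma, and the standard
bench assay for a drug–albumin interaction is a fluorescence titration: the
protein's single tryptophan is excited, and increasing amounts of ligand
quench its emission. When the ligand occupies more than one site, the
Stern–Volmer plot bends downward and a single quenching constant no longer
describes the data. This package implements the full two-site workflow for
such titrations:

* **Inner filter effect (IFE) correction.** Observed intensities are
  attenuated by the ligand's own absorbance; for a 1 cm cuvette
  `F_corr = F_obs · 10^((A_ex + A_em)/2)`, with `A_ex`, `A_em` the
  absorbances at the excitation and emission wavelengths.
* **Segmented Stern–Volmer analysis.** `F0/F = 1 + K_SV [Q]` per regime; an
  exhaustive breakpoint search plus an F-test splits the plot into the
  primary- and secondary-site portions, giving `K_SV1 > K_SV2` and the
  bimolecular constants `K_q = K_SV / τ0` (τ0 = 5.9 ns for HSA tryptophan).
  `K_q` far above the diffusion limit (~10¹⁰ L mol⁻¹ s⁻¹) together with
  `K_SV` falling as temperature rises classifies the quenching as static.
* **Double-logarithmic binding analysis.**
  `log((F0−F)/F) = log k_b + n·log[Q]` per segment yields the binding
  constant and apparent site number for each site.
* **Van't Hoff thermodynamics.** `ln k_b` against `1/T` gives ΔH (slope)
  and ΔS (intercept); `ΔG = ΔH − TΔS`; the sign pattern of ΔH/ΔS
  fingerprints the dominant forces. Docking energies convert to inhibition
  constants via `Ki = exp(ΔG/RT)`.
* **Site-marker competition.** Titrations of protein pre-saturated with
  warfarin (drug site 1), ibuprofen (drug site 2), hemin (fatty-acid site
  1) or warfarin+hemin are classified as one- or two-regime and combined
  into a site assignment.
* **A calibrated forward simulator.** Two-site static quenching with
  per-site thermodynamics, exact free-ligand mass balance, ligand
  absorbance (so the IFE is present in the raw data), multiplicative noise
  and marker-occupancy semantics — with a ground-truth sidecar, so the
  whole pipeline is exercised and validated end to end without any
  instrument data.

## Worked example

Simulate the default study design (3 µM protein, 0–10 µM ligand, 25/35/45
°C, free + four marker conditions, 1 % noise) and analyse it:

```r
library(sternvolmer)

gt <- ground_truth()          # calibrated two-site truth, seed 42
panel <- simulate_panel(gt)
report <- run_analysis(panel$series)

free25 <- Filter(function(cc) cc$label == "free" && cc$temperature_C == 25,
                 report$conditions)[[1]]
free25$stern_volmer[c("ksv1", "ksv2", "kq1")]
#> ksv1 2.112e+05   ksv2 1.545e+05   kq1 3.579e+13
free25$binding[c("kb1", "n1")]
#> kb1 6.03e+05   n1 1.086
report$mechanism
#> "static"
unlist(report$competition$curvature_classes)
#> free "downward"  warfarin "linear"  ibuprofen "downward"
#> hemin "downward"  warfarin+hemin "linear"
```

The free-protein curve splits into two regimes with `K_SV1/K_SV2 ≈ 1.4` and
a primary-site binding constant of `6.0e5 L/mol` at `n ≈ 1.09` — the
generator's true `K1(25 °C)` is `5.6e5 L/mol`. `K_q ≈ 3.6e13 L mol⁻¹ s⁻¹`
is far above the diffusion limit, and the constants fall with temperature,
so the mechanism reads as static quenching. Pre-blocking drug site 1 with
warfarin collapses the curve to a single line: only the weak secondary site
remains.

Thermodynamics of the primary site from published-scale binding constants:

```r
th <- vant_hoff(c(5.9e5, 2.9e5, 1.8e5), celsius_to_kelvin(c(25, 35, 45)))
th
#> <thermo_result> dH = -46.9 kJ/mol, dS = -47.07 J/mol/K (R2 = 0.9911)
#>   dG(298.15 K) = -32.86 kJ/mol
#>   dG(308.15 K) = -32.39 kJ/mol
#>   dG(318.15 K) = -31.92 kJ/mol
force_signature(th$delta_H_kJ_mol, th$delta_S_J_mol_K)
#> "hydrogen_bond_vdw"

ki_from_binding_energy(-10.1) * 1e6   # docking energy (kcal/mol) -> Ki (uM)
#> 0.0394
```

Exothermic binding with negative entropy: hydrogen bonding and Van der
Waals contacts dominate the primary site.

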