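# sterolentropy

Analysis pipeline for quantifying **entropic repulsion of bioadhesion by
sterol surface layers** — for biointerface scientists who want to reproduce,
stress-test or extend the quantitative chain linking interfacial
orientational fluctuations to antiadhesive behaviour.

Spin-coated cholesterol multilayers resist protein adsorption and bacterial
adhesion because adsorption freezes the orientational fluctuations of
interfacial sterols. The package implements every quantitative step of that
argument, each driven by a synthetic-data generator with the statistical
structure the analysis assumes:

| Stage | Model | Key output |
|---|---|---|
| Adaptation kinetics | dσ/dt = −kσⁿ, F(t) = F∞(1 − σ/σ₀); AICc order selection | reaction order (3 = cooperative trios), lumped rate κ |
| Adsorption thermodynamics | Sauerbrey Δm = −C·Δf/n; Langmuir K = θ/((1−θ)x); ΔG = ΔH − TΔS | entropic barrier ΔS_chol = ΔS_SCL − mean(ΔS_controls) |
| Geometric entropy | ΔS = R·ln(A_constr/A_fluct) per cooperative unit | ≈ −160 J mol⁻¹ K⁻¹ per adsorbed protein |
| Rotor Monte Carlo | E = −J Σ u_i·u_j − h Σ u_iz + ½k_z Σ δz², flip barrier on equator crossings | back-reorientation, C_r(d) decay ≤ 1 nm, interfacial roughness |
| FRAP mobility | Soumpasis f(t) = e^(−2τ/t)[I₀+I₁](2τ/t), D = w²/(4τ_D) | lateral D ≈ 0.3–0.4 µm² s⁻¹ |
| Bioadhesion index | per-assay normalization to the reference SCL, mean aggregation | per-surface index (reference ≡ 1) |

## Worked example

Recover the entropic barrier from a synthetic temperature-series adsorption
experiment (one cholesterol SCL, two thiol-SAM controls, 288–313 K, 2%
mass noise, generated barrier −200 J mol⁻¹ K⁻¹):

```r
library(sterolentropy)
p   <- thermo_gen_params(seed = 42)
tab <- gen_temperature_adsorption(p)
res <- barrier_from_table(tab, gamma_max = p$gamma_max,
                          bulk_mole_fraction = p$bulk_mole_fraction)
res$barrier
#> [1] -204.5584
res$barrier_se
#> [1] 6.016588
geometric_entropy()$dS_per_protein   # independent geometric estimate
#> [1] -160.5793
hydrogen_bond_equivalent(res$barrier, 310)
#> [1] 3.170656
```

The chain inverts Langmuir coverage to ΔG(T) per surface, fits
ΔG = ΔH − TΔS, and subtracts the mean control entropy: the recovered barrier
(−205 ± 6 J mol⁻¹ K⁻¹) matches the generated −200, the geometric estimate
agrees at −161, and the penalty is worth about three hydrogen bonds at 37 °C.

The numbered drivers under `analysis/` run each stage end to end and write
their tables under `results/`:

```sh
Rscript analysis/01_kinetics.R   # order selection -> 3; repeat-force CVs
Rscript analysis/02_thermo.R    # barrier -204.6 +/- 6.0 J/mol/K
Rscript analysis/03_rotor.R     # 13/13 vs 0/13 recovery; C_r decay 0.94 nm
Rscript analysis/04_frap.R      # D = 0.377 +/- 0.006 um^2/s
Rscript analysis/05_assays.R    # per-surface bioadhesion index
```

See `vignettes/entropic-repulsion-methods.Rmd` for the models, parameter
choices and limitations.

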