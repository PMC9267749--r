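# tendonmech

Analysis toolkit for combined tensile-testing and potential-difference
measurements on tendon fascicle bundles — the validation workflow of a
mechanical testing stand that stretches fascicle bundles through a fixed
six-stage strain protocol while logging force (20 Hz) and the voltage
generated across the tissue (50 Hz), with specimen cross-sections taken
from 3D surface scans.

The package is for biomechanics groups who need the full measurement
chain as code: geometry, protocol, metric extraction, electrical feature
extraction and group statistics, plus a seeded simulator that generates
complete synthetic specimen records with ground truth so every estimator
can be verified end to end.

## What it computes

* **CSA profiling** — the specimen cross-sectional area is the average of
  300 plane sections through the STL mesh, spaced 0.1 mm, ±150 slices
  about the volume centroid: `A = mean_k area(S ∩ Π_k)`, each section area
  the summed shoelace area of its closed intersection contours.
* **Protocol** — strain control with gauge length L₀ = 50 mm: preload to
  1 N, five ±1 mm preconditioning cycles at 1 Hz, then stretch to
  ε = 6% at 1 mm/s (stage 1), 600 s relaxation (2), unload (3), 2 s rest
  (4), stretch (5), unload (6); ε = u/L₀, σ = F/A.
* **Mechanics metrics** — moduli E_f, E_s as slopes of lines fitted to the
  stage-1/stage-5 loading curves; ΔE = (E_f − E_s)/E_f · 100%;
  peak stresses σ_f, σ_s and Δσ = (σ_f − σ_s)/σ_f · 100%; hysteresis
  H = (A_load − A_unload)/A_load · 100% by the trapezoid rule (stage 1 vs
  stage 3); percent stress-relaxation drop over the stage-2 hold.
* **Voltage features** — stage maxima of |V − baseline|, spike detection,
  exponential decay constants, step drops during the relaxation hold.
* **Group statistics** — mean ± sd per group, one-way ANOVA and pairwise
  Student's t-tests with Bonferroni correction (α = 0.05) across the three
  specimen groups (G3 porcine CDET, G5 bovine SDFT, G7 deer SDFT).
* **Synthetic specimens** — quasi-linear viscoelastic records
  (toe-then-linear elasticity, two-term Prony relaxation
  G(t) = g_inf + Σ gᵢ e^(−t/τᵢ)), strain-rate-driven voltage with
  first-order decay, and extruded meshes with known mean CSA.

## Worked example

```r
library(tendonmech)

protocol <- build_protocol(protocol_config())   # defaults: the printed protocol
specimen <- simulate_specimen(protocol, specimen_params(seed = 3), mesh = TRUE)

profile <- csa_profile(specimen$mesh)
profile
#> <csa_profile> 300/300 valid slices; mean 14.994 mm^2, median 14.976 mm^2, sd 0.146 mm^2

compute_metrics(specimen, profile$mean)
#> <mechanics_metrics> Ef 91.0 MPa, Es 52.1 MPa (dE 42.8%); sigma_f 5.08 MPa,
#>   sigma_s 3.08 MPa (dsigma 39.5%); H 78.0%, relaxation drop 51.4%

voltage_features(specimen)
#> <voltage_features> baseline 2.00 mV; max |V| s1 80.4 mV, s5 20.5 mV;
#>   16 spikes; decay tau 27.4 s; 0 hold drops
```

Reading the output: the mesh slicing recovers this specimen's true mean
CSA (15 mm²) to 0.04%. The first-stretch modulus (91 MPa) sits below the
generator's 100 MPa linear-region slope because the fit spans the toe
region and the tissue relaxes during the ramp; the second stretch is
softer (ΔE ≈ 43%) because the 600 s hold dissipated stress. Hysteresis of
78% and a 51% relaxation drop are typical of fascicle bundles under this
protocol, and the voltage channel spikes on motion events (preload,
cycling, unloading) with tens of mV, decaying on a ~30 s time constant.

A full cohort (3 groups × 9 specimens, meshes, metrics and statistics):

```r
res <- run_pipeline(run_config(seed = 42))
head(res$metrics)        # one tidy row per specimen
res$stats$anova          # per-metric F and p across G3/G5/G7
```

A thin command-line front end over the same functions lives in
`inst/cli/tendonmech.R` (`simulate`, `csa`, `protocol`, `analyze`,
`stats`, `run` subcommands).

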