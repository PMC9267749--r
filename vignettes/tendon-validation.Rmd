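---
title: "Methods: validating tendon fascicle tensile tests with tendonmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating tendon fascicle tensile tests with tendonmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tendonmech)
```

## The measurement problem

Tendon fascicle bundles are tested in uniaxial tension while the electric
potential difference across the specimen is recorded. Three quantities make
the mechanical metrics meaningful:

* **cross-sectional area (CSA)** — the denominator turning force into
  stress. Fascicle bundles are irregular, so a single caliper measurement
  is unreliable; instead the specimen is surface-scanned and the CSA is
  averaged over many plane sections of the resulting STL mesh;
* **grip-to-grip strain** — crosshead displacement divided by the 50 mm
  gauge length set by the jaw holders;
* **a fixed six-stage strain protocol** — stretch to 6% at 1 mm/s,
  10 min relaxation, unload, 2 s rest, stretch again, unload — preceded by
  a 1 N preload and five ±1 mm preconditioning cycles at 1 Hz.

`tendonmech` reimplements this analysis as a tested pipeline and pairs it
with a synthetic specimen simulator so every estimator can be checked
against ground truth.

## CSA from mesh slicing

`csa_profile()` slices the mesh with 300 planes orthogonal to the long
axis, spaced 0.1 mm, ±150 slices on either side of the volume centroid.
Design choices that needed fixing:

* **Centroid.** "Centre of gravity" is read as the volume centroid,
  computed by signed-tetrahedron decomposition against the origin. When the
  mesh is not watertight (an edge not shared by exactly two faces) the
  solid centroid is undefined and the area-weighted surface centroid is
  used with a warning.
* **±150 slices exclude the centroid plane.** Positions are
  `centroid ± k·0.1 mm`, `k = 1..150` — exactly 300 sections; including
  the centroid plane would give 301. The two central positions therefore
  sit 0.2 mm apart.
* **Slicing axis.** Default is the coordinate axis of the largest
  bounding-box extent (scans are acquired with the specimen mounted
  vertically); a principal-axis (second-moment) mode handles tilted scans,
  with ties broken toward +z, +y, +x.
* **Empty slices.** Planes beyond the specimen ends return area 0 with no
  contours; these are *excluded* from the mean/median/sd rather than
  averaged as zeros, which would bias the stress denominator downward. If
  more than half the window is empty the specimen is too short and an
  error is raised.
* **Section areas.** Each plane-triangle intersection produces a segment
  whose endpoints are shared intersection points on mesh edges; segments
  chain into closed contours exactly (no tolerance matching is needed once
  duplicate vertices are merged at 1e-6 mm, the resolution at which STL
  float storage is reliable). Areas are absolute shoelace areas, summed
  over disjoint lobes. Vertices lying exactly in a slicing plane are
  nudged by 1e-12 mm so every crossing is a clean two-edge crossing.

These choices are verified against analytic sections (cylinder, cuboid,
tapered frustum), a rasterization oracle on random star-convex extrusions,
a voxel-average centroid oracle, and scale/rigid-motion invariances.

## Protocol generation

`build_protocol()` emits the waveform on a 100 Hz command clock. Strain is
`displacement / gauge_length` at every sample, ramps run at exactly the
configured crosshead speed, and phase labels partition the time axis as
`preload, precondition, s1..s6`. Two modelling decisions:

* the preload is **force-controlled** and cannot be a strain target; it is
  represented as a zero-displacement placeholder flagged
  `force_controlled`, and the realised preload motion comes from the
  simulator (or the hardware log). The strain datum (0%) is the
  grip-to-grip length *after* preload;
* the preconditioning amplitude is ±1 mm *about the datum* (an amplitude,
  not peak-to-peak), as a sinusoid at 1 Hz.

`emit_gcode()` encodes the waveform as `G21`/`G90` headers, `G1 X.. F..`
linear moves and `G4 S..` dwells (no dialect is mandated by the hardware;
this one is deliberately minimal), and `parse_gcode()` closes the
round-trip to within one command-clock sample.

## The synthetic specimen

The simulator is the package's test bed: it produces records with the
statistical structure the analysis assumes, with known ground truth. It is
a stand-in for archived raw records, not a tissue model.

**Mechanics.** Quasi-linear viscoelasticity with a toe-then-linear
instantaneous response: a quadratic toe below `toe_strain` joining a
linear region of slope `modulus_E` with continuous value and slope, and a
two-term Prony reduced relaxation function
`G(t) = g_inf + g1 exp(-t/tau1) + g2 exp(-t/tau2)`. Stress is the discrete
hereditary convolution of elastic-stress increments with `G`, evaluated by
exact per-term exponential recursions, so the `g_i = 0` limit equals the
elastic response to machine precision and a step strain reproduces the
closed-form decay. Force is `stress × true CSA` plus the preload offset
(so the recorded force at the strain datum equals the 1 N preload),
floored at zero — a slack specimen carries no load — and sampled at 20 Hz
with Gaussian noise. Negative strains (slack) carry zero stress.

**Voltage.** A first-order decay element driven by `k·|dε/dt|`, resampled
to 50 Hz, plus Gaussian noise and Poisson-placed persistent step drops
during hold phases. The form is the simplest one reproducing the observed
morphology — spikes tied to preload, cycling, unloading and re-stretching,
decaying over ~90 s (default `tau_v` = 30 s, so a spike decays to ~5% in
90 s), little response during the slow constant-rate stretch, and
spontaneous drops during relaxation. The underlying mechanism
(piezoelectric vs streaming potential) is not modelled and is explicitly
out of scope; the simulator makes no scientific claim about it.

**Groups.** Three default groups of nine specimens mirror the validation
design: G3 (porcine common digital extensor — positional, stiffest
parameter mean, smallest CSA ≈ 11 mm²), G5 (bovine superficial digital
flexor, CSA ≈ 17 mm²) and G7 (deer superficial digital flexor, largest and
most variable CSA ≈ 23 mm²). Parameter draws are normal, truncated at ±2
standard deviations (biological parameters are bounded; untruncated tails
would occasionally produce non-physical specimens). The moduli means
(160/110/100 MPa for G3/G5/G7, sd 25/18/22) were chosen once so that
*fitted* moduli — which sit some 10% below the generator's linear-region
slope because the fit spans the toe region and the viscoelastic response
relaxes during the ramp — fall inside the 37–139 MPa envelope reported
for bovine fascicles at 6% strain. The Prony defaults
(`g1 = 0.30, tau1 = 10 s; g2 = 0.25, tau2 = 120 s`) place hysteresis in
the observed 65–85% band and give relaxation drops near 50% over the
600 s hold. Voltage gains are drawn identically across groups, matching
the finding that electrical observables did not differ between species;
the defaults keep all excursions well inside the observed 0–200 mV range.
All randomness flows from one master seed through a single splitting rule
(`sample.int` under the master seed), so records are reproducible to the
byte.

**What the simulator does not emulate.** Scan noise and mesh defects
beyond smooth radial irregularity; micro-damage, temperature, hydration
and freeze–thaw effects; inter-channel clock drift; mains interference.
Passing tests therefore demonstrate that the *estimators* are correct and
well-calibrated on data obeying the stated model, not that the model
captures every feature of real tissue records.

## Mechanics metrics

From the stress–strain series (force clock, displacement linearly
resampled onto it):

* `Ef`, `Es` — slopes of least-squares lines fitted to the stage-1 and
  stage-5 loading curves. The default fit window is the full 0–6% ramp,
  matching the procedure's literal description; a window option restricts
  the fit to an upper linear region (e.g. 3–6%) for the common
  alternative. On an exact line the fit is exact; the reported `r_squared`
  flags curvature.
* `ΔE = (Ef − Es)/Ef · 100` and `Δσ = (σf − σs)/σf · 100` with `σf`, `σs`
  the stage-1/stage-5 peak stresses. Both identities are recomputed in
  tests on every pipeline output. Negative `ΔE` (stiffening) is allowed.
* **Hysteresis** `H = (A_load − A_unload)/A_load · 100`, trapezoid-rule
  areas over strain, with the loading area as the 100% reference and the
  unloading curve reversed to ascending strain first. `H` pairs the
  stage-1 loading with the stage-3 unloading, *with the 600 s relaxation
  in between* — this is the published definition, and it inflates `H`
  relative to an uninterrupted cycle; values near 75% here correspond to
  ~55% protocols that cycle without a hold.
* **Relaxation drop** `(σ_start − σ_end)/σ_start · 100` over the stage-2
  hold, with endpoints taken as medians over the first and last 1 s of
  the hold — raw endpoints are too noise-sensitive, and no endpoint rule
  is mandated by the source procedure. The hold-start reference (rather
  than the stage-1 peak) was chosen because the drop describes the hold
  itself.

Stage boundaries come from the protocol when available; otherwise
`segment_stages()` infers them from the strain derivative (ramp/hold runs
against a threshold of 10% of the ramp rate, runs under 0.5 s merged) and
locates the trailing up–hold–down–hold–up–down pattern.

## Voltage features

All amplitudes are magnitudes relative to the baseline (median of the
first 2 s); the signed value is kept alongside. Stage maxima use
`max |V − baseline|`, covering spikes of both polarities. Spikes are local
maxima above a threshold (default 5× the baseline-window noise sd),
greedily thinned to a 5 s minimum separation and annotated with their
protocol phase. Decay constants come from log-linear least squares over
90 s after a peak, floored at the noise level; fewer than 20 usable
samples yields "no decay". Hold drops are step changes in the difference
of 1 s leading/trailing medians. One caveat baked into the defaults: the
record begins *at* preload, so the "baseline" window already contains
motion; detector tests that need an exact baseline pass it explicitly.

## Group statistics

Summaries are mean ± sample sd (n−1). Between-group differences use
one-way ANOVA (`F = MSB/MSW`, verified against brute-force sums of squares
to 1e-9) and Student's pooled-variance pairwise t-tests — pooled rather
than Welch because that is the named procedure — with Bonferroni
correction by p-value multiplication capped at 1, α = 0.05. Under a true
null the empirical rejection rate over 1000 seeded replicates is required
to sit in 0.05 ± 0.02.

## Numerical choices and degenerate inputs

* vertex merge and contour tolerances 1e-6 mm; in-plane vertex nudge
  1e-12 mm; degenerate-volume threshold 1e-9 mm³;
* protocol durations are rounded up to the 100 Hz command clock so phase
  boundaries land on samples; ramp targets are exact at stage ends;
* `qlv_stress` and the channel readers require uniform time grids
  (hereditary recursion and rate validation both assume them);
* identical groups give `F = 0, p = 1`; identical pairs give `t = 0,
  p = 1`; singleton groups flag `sd = NA` rather than failing;
* empty cross-sections are data (area 0, no contours), not errors; chains
  that fail to close are discarded from the area with a warning.

## Problem sizes used in the tests

The unit tests run shortened holds (10–30 s) where the full 600 s hold
adds nothing to the property under test; the acceptance-style checks that
validate the published envelopes use the full default protocol
(621 s span at 100 Hz), cohorts of 9 specimens per group with meshes of
~9000 faces, 300-slice profiles, 20 recovery specimens, and 1000 ANOVA
null replicates. These sizes were chosen as the smallest that exercise
the complete study design.

## Known limitations

* The hysteresis definition ties `H` to this specific protocol; comparing
  against cycle-only protocols requires the caveat above.
* The modulus is a secant-style straight-line fit over a curved toe
  region; it systematically under-reads the linear-region slope unless the
  fit window is restricted.
* Group-level published statistics (species means, p-values) depend on the
  original raw recordings and are context, not reproduction targets; the
  simulator reproduces their *envelopes* by construction, which validates
  the pipeline, not the biology.
* The voltage model is phenomenological; its features (gains, decay
  constants, drop rates) should not be interpreted as tissue constants.
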