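Package: tendonmech
Title: Mechanical and Electrical Analysis of Tendon Fascicle Tensile Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for validating combined tensile-testing and
    potential-difference measurements on tendon fascicle bundles.
    Computes specimen cross-sectional area profiles by plane-slicing
    STL surface scans about the volume centroid, generates the
    six-stage strain-controlled testing protocol (preload,
    preconditioning, stretch-relax-unload-rest-stretch-unload) as a
    time-stamped waveform with a g-code emitter, extracts elastic and
    viscoelastic metrics (elastic moduli of both stretches, modulus and
    peak-stress drops, trapezoid-rule hysteresis, stress-relaxation
    drop) and piezoelectric voltage-waveform features (stage maxima,
    spikes, exponential decay constants, hold-phase drops), and
    compares groups with one-way ANOVA and Bonferroni-corrected
    pairwise t-tests. A seeded quasi-linear viscoelastic specimen
    simulator produces complete synthetic records (mesh, 20 Hz force
    and displacement, 50 Hz voltage) with ground truth for end-to-end
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
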