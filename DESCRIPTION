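Package: OCTrepeat
Title: Repeatability of Retinal Layer Thickness Estimates from Macular OCT
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the test-retest repeatability of
    intra-retinal layer thickness estimates derived from macular optical
    coherence tomography (OCT) volume scans. Converts segmentation surface
    exports into per-layer thickness maps on physical coordinate grids,
    evaluates a registry of twelve published thickness estimates (regional
    averages over discs, elliptical annuli, B-scan subsets and sparse point
    sets), and computes reliability statistics: one-way ANOVA variance
    components, the single-measures intraclass correlation ICC(1,1) with
    exact F-based confidence intervals, the coefficient of repeatability,
    and Bland-Altman limits of agreement. A synthetic cohort simulator with
    known variance components (between-eye variation, session offsets,
    spatially correlated segmentation noise, scan-window jitter and a
    beam-angle-dependent Henle fiber layer boundary artifact) makes every
    pipeline stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'scan-protocol.R'
    'geometry.R'
    'masks.R'
    'estimates.R'
    'stats-anova.R'
    'stats-icc.R'
    'stats-blandaltman.R'
    'stats-tables.R'
    'templates.R'
    'simulate.R'
    'io.R'
    'pipeline.R'
    'OCTrepeat-package.R'
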