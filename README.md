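# OCTrepeat

Test–retest repeatability of intra-retinal layer thickness estimates
from macular OCT volume scans.

Longitudinal studies of neurodegeneration read changes of a few
micrometres out of mean retinal layer thicknesses (RNFL, GCL, IPL,
GCIP, INL, OPL, ONL). Whether such changes are signal or noise depends
on the *thickness estimate* — the recipe that turns a segmented volume
into one number: which scan protocol, which B-scans, which spatial
region, averaged how. OCTrepeat is for researchers who need to compare
those recipes, analyse their own repeated measurements, or simulate
repeatability studies with known ground truth.

The package provides:

* **Geometry** — segmentation-surface exports → per-layer thickness maps
  in µm on fovea-centred physical grids; circular, elliptical-annulus,
  B-scan-line and point-set region masks; B-scan extraction.
* **Twelve published estimates (A–L)** as declarative definitions: 6-mm
  disc means on dense volume scans (A–C), full-area means (D–E), a
  reduced B-scan subset (F), single/paired fovea-centred B-scans (G–I),
  a sparse 3-point sample (J) and the Cirrus elliptical annulus
  (outer radii 2.4/2.0 mm, inner 0.6/0.5 mm) for RNFL and GCIP (K–L).
* **Reliability statistics** — one-way ANOVA variance components with
  the eye as unit (unbalanced designs via the effective group size
  k₀), the single-measures intraclass correlation

      ICC(1,1) = (MSB − MSW) / (MSB + (k₀ − 1)·MSW)

  with exact F-based 95% confidence intervals and the
  excellent/moderate/insufficient classification (0.9/0.8 thresholds);
  the coefficient of repeatability CR = 2.77·s_w; and Bland–Altman
  bias and limits of agreement over all session pairs.
* **A synthetic cohort simulator** with known variance components:
  between-eye variation, per-scan offsets, spatially correlated
  segmentation noise, scan-window jitter, and a beam-angle-dependent
  Henle-fiber-layer artifact that shifts the apparent OPL/ONL boundary
  antisymmetrically across the fovea.
* **A pipeline** (`runStudy()`, plus `inst/scripts/octrepeat.R` for the
  shell) producing deterministic ICC/CR report tables, Bland–Altman
  point sets and a reproducibility manifest.

## Worked example

Nine measurements — three eyes, three sessions each:

```r
library(OCTrepeat)
vc <- onewayAnova(c(141.2, 140.1, 141.9, 128.3, 129.0, 128.1,
                    135.7, 137.2, 136.4), rep(1:3, each = 3))
vc
#> One-way ANOVA: 3 units, MSB = 121.8, MSW = 0.5367, k_eff = 3
iccOneway(vc)
#> ICC(1,1) = 0.9869 [0.9098, 0.9997] (excellent)
coefficientOfRepeatability(vc)
#> CR = 2.0292 um (within-subject SD 0.7326 um)
```

Between-eye variation dwarfs session noise, so the ICC is excellent;
the CR says two repeated scans of the same eye agree within ±2.0 µm
with 95% probability.

End to end on a small synthetic cohort (4 controls × 3 sessions,
2 patients × 2 sessions, both eyes, both devices):

```r
cfg <- CohortConfig(nHcSubjects = 4, nMsSubjects = 2,
                    protocols = builtinProtocols(maxAScans = 48), seed = 11)
sim <- simulateCohort(cfg)
tab <- applyAll(builtinEstimates(protocols = cfg@protocols), sim$cohort)
nrow(tab)
#> [1] 2368
rt  <- repeatabilityTable(tab, cohort = "mixed")
head(formatICCTable(rt), 3)
#>   Estimate            mRNFL              GCL              IPL             GCIP
#> 1        A 0.98 [0.94-0.99] 0.97 [0.92-0.99] 0.98 [0.95-0.99] 0.98 [0.93-0.99]
#> 2        B 0.98 [0.94-0.99] 0.98 [0.96-1.00] 0.98 [0.96-1.00] 0.98 [0.95-0.99]
#> 3        C 0.99 [0.96-1.00] 0.96 [0.89-0.99] 0.98 [0.95-0.99] 0.97 [0.92-0.99]
#>                INL              OPL              ONL
#> 1 0.98 [0.96-1.00] 0.95 [0.86-0.98] 0.99 [0.98-1.00]
#> 2 0.98 [0.94-0.99] 0.95 [0.87-0.98] 0.99 [0.97-1.00]
#> 3 0.99 [0.97-1.00] 0.97 [0.91-0.99] 0.99 [0.98-1.00]
head(formatCRTable(rt), 3)
#>   Estimate mRNFL  GCL  IPL GCIP  INL  OPL  ONL
#> 1        A  1.65 1.39 1.40 1.99 1.57 1.67 1.28
#> 2        B  1.64 0.92 1.31 1.75 1.96 1.65 1.37
#> 3        C  1.38 1.55 1.44 2.32 1.29 1.23 1.27
```

Rows are the estimates, columns the seven layers; cells show
"ICC [95% CI]" and CR in µm. At full cohort size the area estimates
(A–E, K, L) stay excellent with CRs of 1–3 µm, the sparse-point
estimate J exceeds 8 µm CR in every layer, and the OPL is the least
repeatable layer — see the methods vignette for the noise model behind
this.

The same run from a shell:

```sh
Rscript inst/scripts/octrepeat.R run --seed 1 --out report/
```

writes `icc_<cohort>.csv`, `cr_<cohort>.csv`,
`bland_altman_<cohort>.csv`, full-precision sidecars and a manifest for
the mixed, control-only and patient-only cohorts.

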