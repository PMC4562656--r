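---
title: "Methods: repeatability of OCT layer thickness estimates"
author: "OCTrepeat authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeatability of OCT layer thickness estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OCTrepeat)
```

## The problem

Quantitative macular OCT reduces a segmented volume scan to a handful of
mean layer thicknesses — one number per retinal layer per eye — and
longitudinal studies then interpret changes of a few micrometres in those
numbers. Whether such changes are meaningful depends entirely on how well
the numbers reproduce when the same eye is scanned again minutes later.
That reproducibility is not a property of the device alone: it depends on
*how* the mean is formed. The literature contains at least twelve distinct
recipes ("thickness estimates"), from averaging a 6-mm-diameter disc of a
dense volume scan down to averaging three discrete points on a single
B-scan.

OCTrepeat implements these estimates declaratively, computes the standard
reliability statistics on repeated measurements, and ships a synthetic
cohort generator with known variance components so that the whole
pipeline can be validated end to end without patient data.

## Statistical model

Repeated measurements $x_{ij}$ (eye $i = 1..a$, session $j = 1..n_i$) are
decomposed by a one-way ANOVA with the eye as the unit:

$$MSB = \frac{\sum_i n_i(\bar x_i - \bar x)^2}{a - 1}, \qquad
  MSW = \frac{\sum_i \sum_j (x_{ij} - \bar x_i)^2}{N - a}.$$

The single-measures intraclass correlation is

$$\widehat{ICC}(1,1) = \frac{MSB - MSW}{MSB + (k_0 - 1)\,MSW},$$

with $k_0 = (N - \sum_i n_i^2/N)/(a-1)$ the effective number of sessions
per eye ($k_0 = k$ for balanced designs). The 95% confidence interval is
the exact F-based one: with $F = MSB/MSW$ and $f^*$ the $F$ quantile at
$\alpha/2$ on $(a-1, N-a)$ degrees of freedom, each bound has the form
$(F/f^* - 1)/(F/f^* + k_0 - 1)$. ICC above 0.9 is classified *excellent*,
between 0.8 and 0.9 *moderate*, below 0.8 *insufficient*.

The coefficient of repeatability is the absolute counterpart:

$$CR = 2.77 \times s_w, \qquad s_w = \sqrt{MSW},$$

the 95% bound on the absolute difference between two repeated
measurements. Bland–Altman analysis plots, for every unordered session
pair of every eye, the pair difference against the pair mean, with bias
and $\pm 1.96\,SD$ limits of agreement; under pure session noise the LoA
half-width $1.96\sqrt{2}\,\sigma_w$ coincides with the CR.

Three deliberate choices:

* **The eye is the unit**, and both eyes of a subject enter as
  independent units; inter-eye correlation is ignored. This matches the
  design the statistics are meant for; a subject-level analysis can be
  had by passing subject ids as units.
* **Negative ICC estimates are reported unclamped.** The estimator's
  range is $[-1/(k_0-1), 1]$; truncating at zero would bias every
  simulation study built on it. Descriptions of the ICC as ranging "0 to
  1" refer to the population parameter.
* **The constant is the printed 2.77**, not $1.96\sqrt 2 = 2.7719$, so
  that published tables can be reproduced digit for digit. The
  difference is 0.07%.

## Geometry and the estimate registry

A scan protocol is named `direction-nB-nA` (e.g. `V-25-1024`: vertical
B-scans, 25 of them, 1024 A-scans each) plus physical extents and the
axial scale. Grids place A-scans uniformly with spacing $\mathrm{extent}/(n-1)$,
so corner A-scans sit on the scan-area corners; coordinates are reported
in mm with the origin at the fovea. The fovea position is an *input*
(defaulting to the scan-area centre) — automatic fovea detection is out
of scope.

Thickness is the axial boundary distance times the axial scale
(micrometres); positions are 0-based pixels from the image top,
increasing with depth — a documented convention, since exports differ.
The composite GCIP is always computed as the exact elementwise sum of
GCL and IPL when the intermediate boundary exists. Missing segmentation
values are excluded from averages, and a record whose mask has more than
20% missing cells is flagged (threshold configurable).

Region masks are evaluated at A-scan cell centres: a cell belongs to a
disc iff $x^2+y^2 \le r^2$ (closed boundary), and to the elliptical
annulus iff it is inside-or-on the outer ellipse and strictly outside
the inner one. Cell-centre membership is the simplest deterministic
rule; its error vanishes as grids refine. Averages weight all included
A-scans equally, even though the grids are anisotropic (B-scan spacing
differs from within-B-scan spacing) — this is what "mean of all values"
means operationally.

Of the twelve registry entries, only part of the geometry is fixed by
the sources: A–C use the 6-mm disc on different Spectralis volume
settings, G–J are single-B-scan based, and K/L use the Cirrus elliptical
annulus (outer radii 2.4/2.0 mm, inner 0.6/0.5 mm) restricted to RNFL
and GCIP. Everything else — the exact per-estimate scan settings, the
B-scan subset of F, the pairing of H, J's point count — ships as
documented defaults behind a generic engine (protocol × B-scan selector
× mask), so reproducing any published variant is a configuration change,
not code. J is modelled as a three-point mean at 0, 1 and 2 mm from the
fovea along its B-scan: a deliberately one-sided, sparse sample, which
is what makes it both noisy and sensitive to the fovea-antisymmetric
artifact below. The Cirrus cube presets (512×128 and 200×200 A×B scans
over 6×6 mm) are implementation defaults, not device facts.

## The synthetic cohort

The generator reproduces the study design it is meant to exercise: two
healthy-control cohorts of 15 subjects (one per device) with three
sessions each, 13 patients with two sessions on both devices, both eyes
included — 56 eyes per device, unbalanced sessions, exactly the
situation $k_0$ exists for.

Each eye's truth is an analytic layer template (foveal depression with a
perifoveal ridge for GCL/IPL/INL, peripheral ramp for RNFL, foveal peak
for ONL) plus a per-eye, per-layer offset with SD $\sigma_b$. Patient
eyes get GCL/IPL templates thinned by 0.85 (RNFL by half that), standing
in for disease-related atrophy. Each session then observes this truth
through four noise components:

| component | default | what it emulates |
|---|---|---|
| global offset, $\sigma_{off}$ | 0.3 µm | per-scan segmentation bias |
| correlated field, $\sigma_f$, $\ell$ | 7 µm, 0.10 mm | local segmentation error |
| window jitter | 0.1 mm SD | imperfect re-placement without follow-up |
| HFL artifact, $A$, $\theta$ | 60 µm, $U(-0.5, 0.5)$ | beam-angle OPL/ONL shift |

The correlated field is Gaussian-kernel-smoothed white noise rescaled to
an exact marginal SD at every cell — the variance, not the spectrum, is
the contract, since no noise spectrum is documented for segmentation
error. Jitter translates the sampling window over the analytic truth.
The HFL artifact adds $\delta = A\theta\,s(x,y)$ to the OPL and
subtracts it from the ONL, with $s$ smooth, $|s|\le 1$ and antisymmetric
across the fovea along a per-session random beam-offset direction; both
layers are floored at 0.5 µm, and wherever the floor is not hit the
OPL+ONL sum is conserved exactly. Because $\theta$ is drawn fresh per
session, OPL noise stems from beam placement, not from spatial
averaging — which is why averaging over a larger area does *not* rescue
the OPL the way it rescues field noise, and why the artifact cancels in
fovea-centred area means but not in one-sided sparse samples.

**How the defaults were chosen.** No quantitative within-session variance
decomposition is documented, so the noise magnitudes are calibrated
once, against the qualitative ordering the statistics are known to show:
area estimates excellent (ICC > 0.9) with CR of a few micrometres,
the sparse-point estimate J above 8 µm CR in every layer, OPL the least
repeatable layer. Working backwards: J's CR is dominated by the field
($CR \approx 2.77\,\sigma_f/\sqrt 3$), which sets $\sigma_f = 7$ µm; the
area estimates then require the field to average away, which the
correlation length $\ell = 0.10$ mm provides (about
$4\pi\ell^2 = 0.13$ mm² of correlation area, i.e. ~220 effective
independent patches in the 6-mm disc); $\sigma_{off} = 0.3$ µm keeps
area CRs above 1 µm; and the per-layer $\sigma_b$ values (2.2 µm for the
thin OPL up to 6 µm for the ONL) encode that a layer's ICC is its
between-eye variance over total — the thin OPL has little population
variance to "protect" its ICC, the thick ONL a lot, which is exactly
why the same artifact noise makes OPL insufficient but leaves ONL
excellent. The artifact amplitude $A = 60$ µm makes opposite beam
offsets ($\theta = \pm 0.4$) differ by up to ~35 µm on single B-scans.
These values were fixed before any acceptance threshold was attached to
them and are not revisited per run.

**Problem sizes.** Simulation studies run on the native protocol designs
thinned to at most 96 A-scans per B-scan (extent unchanged) — the
package's chosen resolution for validation work, since every quantity
involved is a regional mean whose value is resolution-independent and
whose sampling noise the field model controls explicitly. Tests use a
further-thinned 24-A-scan set. The acceptance script uses 200 cohort
replicates for parameter recovery and 2 000 for CI coverage.

**What the generator does not emulate** — and what passing tests
therefore do not show about real data: OCT speckle and image formation,
real segmentation-algorithm failure modes (vessel shadows, detachments),
fixation-dependent fovea mis-centring beyond translation, pathology
beyond global inner-layer scaling, and inter-eye correlation (the two
eyes of a subject are generated independently, matching the analysis
assumption rather than biology).

## Numerical choices and degenerate inputs

* Units with a single session are dropped with a warning; fewer than two
  usable units, or zero total variance, is an error. $MSB = MSW = 0$
  makes the ICC undefined (error); $MSW = 0$ alone gives ICC exactly 1
  with a degenerate interval.
* Nearest-B-scan selection breaks midway ties toward the lower index;
  out-of-range indices and offsets are errors, never wraparounds.
* Masks are bit-for-bit deterministic for a fixed grid and parameters;
  two protocols are interchangeable only if their full geometry agrees
  (the name alone is ambiguous after thinning).
* Report cells round ICC and CR to two decimals, the conventional print
  precision; full-precision grids are written alongside as TSV.
* The run manifest fingerprints the config (FNV-1a) and records the
  seed; identical config and seed reproduce every output byte.

## Known limitations

Reproducing any *specific* published table cell-for-cell requires the
corresponding measurement data in the long-table schema; the synthetic
cohort validates the machinery and the qualitative structure, not
subject-level values. The elliptical-annulus estimates apply only to
RNFL and GCIP, as their source software provides; and the package
deliberately stops short of vendor-format parsing, fovea detection and
image-level segmentation — it starts where a segmentation export ends.
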