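---
title: "Gray-level quantification of pancreatic cystic lesions on EUS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gray-level quantification of pancreatic cystic lesions on EUS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eusquant)
```

## The measurement model

B-mode endoscopic ultrasound renders tissue echogenicity as 8-bit gray
values. In pancreatic cystic lesions the fluid compartments are anechoic
(near 0), solid components — septa, mural nodules, the cyst wall — are
markedly brighter, and healthy parenchyma brighter still. `eusquant`
operationalizes this as first-order gray-level statistics over three region
families per frame:

* the **whole lesion**, outlined free-hand as a polygon;
* its **cystic part(s)**, segmented by tolerance-based seeded region growing
  (the "magic wand" of mainstream image software): starting from a
  user-chosen pixel, the maximal connected set of pixels whose gray value
  differs from the *seed's* gray value by at most the tolerance;
* the **solid part**, defined as whole minus cystic.

Per region the package reports echogenicity (mean gray), inhomogeneity
(gray SD), calibrated area (mm²), and *density* — the sum of gray values
divided by the region's area in mm². Density is not an independent quantity:
with pixel area $1/c^2$ at calibration $c$ pixels/mm,

$$\mathrm{density} = \frac{\sum g}{n / c^2} = \bar g \, c^2 ,$$

an identity the test suite enforces to relative $10^{-9}$ and which also
reproduces the published density column from the published echogenicity
column at $c = 12.2674$ ($c^2 \approx 150.489$). All moment bookkeeping is
exact: a region is represented by $(n, \sum g, \sum g^2)$ accumulated in
doubles (exact integers far below $2^{53}$), and the solid part is obtained
by *subtracting* the cystic moments from the whole-lesion moments, which is
pixel-for-pixel identical to measuring the set-difference mask.

### Assumptions worth stating

* **Seed-anchored tolerance.** The admissible band is fixed at
  $[g(\mathrm{seed}) - T,\ g(\mathrm{seed}) + T]$, not updated by a running
  region mean. This matches the described tool behavior and makes the result
  independent of visit order; the cost is sensitivity to the seed pixel's
  own noise, which is why tolerance is a required per-seed annotation input
  rather than a global constant (the study does not report the values used).
* **4-connectivity** for growing and lobule counting (8 available as a
  config toggle). Conservative: diagonal one-pixel gaps do not leak.
* **Sample SD** ($n-1$) by default, the convention of mainstream
  image-measurement software; a population-SD switch exists and provably
  affects only the SD columns.
* **Pixel-center rasterization.** A pixel belongs to the polygon iff its
  center is inside under the even-odd rule; centers exactly on an edge
  resolve by the half-open boundary of the crossing test. Coordinates are
  (row, col), 0-based, center at integer coordinates, everywhere.
* **Per-image units.** Group tests treat each frame as one observation, as
  the source analysis did (it reports image counts per group); a per-patient
  aggregation flag is available since several frames may share a patient.

### Degenerate inputs

Empty regions are errors, not zeros. A lesion whose cystic part fills the
polygon has no solid part: solid metrics are *missing*. An annotation with
no cystic seeds yields missing cystic metrics, solid = whole, area ratio 0.
Mask subtraction tolerates stray subtrahend pixels outside the minuend
(annotation noise) with a warning that counts them.

## The statistics stage

For each metric and group pair the routed two-sample procedure applies the
Welch $t$-test when both samples pass the normality gate and the two-sided
Mann–Whitney U test otherwise (exact for small untied samples, normal
approximation with tie correction otherwise). The normality battery computes
all four tests the protocol names — Anderson–Darling, D'Agostino–Pearson,
Shapiro–Wilk, Kolmogorov–Smirnov (Lilliefors) — but the *gate* is
Shapiro–Wilk at $\alpha = 0.05$ alone, because the protocol lists four tests
without a combination rule; the other three are reported for inspection.
Anderson–Darling, D'Agostino–Pearson and the Lilliefors p-value are
implemented from the standard published approximations (no installed package
provides them); the Lilliefors p uses the Dallal–Wilkinson formula, which is
designed for $p \le 0.10$ and is only indicative above that. Group
composition uses Pearson's χ² without continuity correction, with a warning
when any expected count drops below 5. Raw p-values only — the source
applied no multiplicity adjustment, and neither does the package.

Samples smaller than 8 cannot support the battery and route non-parametric
with a warning. The routed procedure's type-I error is checked by simulation
(1000 null replicates at $n = 30$ per arm) to lie in $[0.03, 0.07]$.

The published table's "±" entries deserve a note: for the lesion metrics
they are only plausible as standard errors (a between-image SD of ±0.9 gray
levels across 81 frames of 8-bit data would be implausibly tight), while the
parenchyma rows are explicitly labelled SD. Group summaries therefore report
*both* `sd` and `sem`, and the phantom generator reads lesion-metric ± as
SEM (between-image SD = SEM·√n) but area ± as SD — the SEM reading of the
area rows would imply between-image SDs of ~600 mm² on means of 400–600 mm²,
i.e. mostly negative areas.

## What the phantom generator emulates — and what it does not

The study's 170 patient frames are unavailable, so validation runs on
synthetic phantoms with known truth. A phantom is an ellipse world: a
parenchyma noise background, a solid-tissue lesion ellipse, anechoic cystic
content inside it, optionally an echogenic wall ring, and three auto-placed
5-mm parenchyma reference circles. Pixel noise is an independent per-pixel
truncated normal on [0, 255], rounded to integers.

Three generator choices matter:

* **Realized-moment parameterization.** Published region statistics are
  measurements of 8-bit pixels — of the *truncated* distribution. A cystic
  mean of 7.5 with SD 7.1 cannot be the moments of an untruncated normal on
  [0, 255]. The generator therefore moment-matches the parent normal so the
  truncated draw realizes the requested mean/SD (sampled by inverse CDF,
  which is exactly the conditional distribution on [0, 255]; naive
  redraw-rejection has vanishing acceptance for such targets). Truth records
  the realized statistics, which are authoritative for tests.
* **Septated cystic partitions.** Multi-lobule cysts at the published area
  ratios cannot be built from disjoint lobule ellipses: two equal
  non-overlapping ellipses inside a similar outer ellipse cap the cystic
  fraction at 0.50, below the published 0.57 (SCN, ~2 lobules) and 0.61
  (pseudocyst). The cohort generator instead uses a concentric similar
  ellipse split by thin (1.2 mm) solid septa into the requested number of
  lobules, sized so the *net* cystic fraction equals the target — which is
  also the morphology of real multilocular lesions. Explicit ellipse lobules
  remain available for hand-built specs.
* **A perfect annotator, not a blind one.** The truth annotation discretizes
  the lesion boundary at 72 vertices, places one seed per lobule with
  tolerance = half the solid−cystic mean gap, and seeds *on a pixel
  representative of the lobule* (gray closest to the lobule mean, ties
  broken by distance to the lobule center). Because the tolerance band is
  anchored to the seed's own gray value, seeding on an arbitrary noise draw
  would degrade segmentation for reasons no human annotator — who sees the
  image — would reproduce.

Cohorts draw per-image parameters from the group tables: region means
jittered between images (SEM·√n), areas (printed ± as SD), cystic fraction
around the published ratios with SD 0.15 (the table prints only group means;
0.15 is a fixed, a-priori choice reflecting the wide clinical spread of
cystic fractions), lobule counts as 1 + Poisson(group mean − 1). Everything
is reproducible from one master seed, and scaled-down frames (smaller
calibration) keep gray statistics and mm² areas intact for fast tests.

What the phantom does **not** model: speckle correlation (the published
analysis uses only first-order statistics; an optional smoothing hook is
deliberately absent rather than half-realistic), attenuation, shadowing,
reverberation, free-hand lesion shapes, wall thickening gradients. A green
phantom test therefore establishes that the *measurement pipeline* is
correct and that the *statistical structure* of the published table is
recoverable — not that the pipeline segments real EUS speckle texture well.

## Numerical choices

* Calibration: `pixel_area_mm2 = 1 / pixels_per_mm²`, asserted to relative
  $10^{-12}$.
* Luminance for color inputs: ITU-R BT.601 (0.299, 0.587, 0.114), rounded
  half-up; JPEG artifacts are accepted as-is (the source frames were saved
  JPEGs).
* Region growing is a vectorized frontier flood fill; its exact equality
  with a scalar breadth-first-search oracle is property-tested on 1000
  random frames.
* Moment subtraction guards the Cauchy–Schwarz invariant
  $n \sum g^2 \ge (\sum g)^2$ and refuses inconsistent (non-nested) region
  pairs; a fully cystic lesion raises a distinct error that the pipeline
  records as missing solid metrics.
* Ties in the Mann–Whitney U with fully tied samples (e.g. two constant
  regions) produce an undefined normal-approximation p; the package reports
  p = 1 (no evidence of difference) rather than NA.

## Known limitations

* The published solid-part *areas* are inconsistent with whole − cystic
  (e.g. pseudocyst 196.1 mm² printed vs 590.4 − 324.1 = 266.3 mm²); the
  package implements the subtraction definition strictly and documents the
  discrepancy rather than emulating it.
* Lilliefors p-values above 0.1 are approximate (Dallal–Wilkinson's formula
  is designed for the rejection region); the verdict never depends on them.
* The SCN-vs-pseudocyst whole-lesion comparison sits near the decision
  boundary in the published world itself (means 18.8 vs 19.8 with SEs ~1.5
  apart): simulated cohorts reproduce its non-significance in most but not
  all replicates, which is a property of the stated parameters, not of the
  implementation.
* Tolerance values for the study's actual tracing-tool selections are
  unreported; they are a required annotation input here, and sensitivity to
  them is exercised in tests rather than fixed by a constant.
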