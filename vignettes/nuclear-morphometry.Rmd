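---
title: "Nuclear morphometry of lobular carcinoma variants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear morphometry of lobular carcinoma variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lobmorph)
```

## The measurement problem

Breast lobular carcinoma is classified into classic, solid and
pleomorphic variants partly on nuclear grounds: the pleomorphic variant
carries larger and more variable nuclei, and a markedly worse prognosis.
The conventional criteria ("nuclei three to four times a lymphocyte") are
subjective, and inter-observer agreement on nuclear pleomorphism is known
to be poor. `lobmorph` operationalises the nuclear part of the diagnosis
as four reproducible measurements per nucleus and two statistics per case,
and evaluates cut-off rules on those statistics.

The pipeline deliberately starts *after* nucleus detection: it consumes
boundary polygons (QuPath-style GeoJSON, or integer label masks from any
segmentation tool) rather than bundling a detector, so any segmentation
front end can feed it. The only calibration needed is the scanner's
isotropic pixel size in µm/pixel (common scanner values are 0.19, 0.25
and 0.5 µm/pixel); anisotropic pixels are not supported.

## The four size parameters

For a simple closed boundary ring $P$ with vertices $(x_i, y_i)$:

* **Area** $A = \tfrac12\left|\sum_i (x_i y_{i+1} - x_{i+1} y_i)\right|$.
  Using the absolute value makes the result independent of ring
  orientation and of the image frame's handedness (image y grows
  downward; all four parameters are reflection-invariant, so geometry is
  computed on raw coordinates).
* **Perimeter** $L$: the closed sum of Euclidean edge lengths.
* **Maximum Feret diameter** $F_{\max}$: the largest caliper distance.
  The diameter of a point set is attained between convex-hull vertices,
  so an exhaustive scan over hull-vertex pairs is exact — no angular
  discretisation is involved.
* **Minimum Feret diameter** $F_{\min}$: the smallest caliper width. The
  minimum width of a convex polygon is attained perpendicular to one of
  its edges, so the minimum over hull edges of the farthest-vertex
  distance to the edge's supporting line is likewise exact.

Every measurement record satisfies $F_{\min} \le F_{\max}$, the
isoperimetric inequality $L^2 \ge 4\pi A$, and $A \le F_{\min} F_{\max}$
(the polygon fits inside its hull, whose area is at most width ×
diameter); the tests enforce these invariants on random polygons, and
check the diameter operations against brute-force oracles (all-pairs
distances; a 3600-angle projected-width sweep).

### Ring hygiene

Input rings are normalised on construction: a duplicated closing vertex
and consecutive duplicates are dropped, orientation is normalised to
counter-clockwise, and simplicity is verified by an all-pairs
edge-crossing test. Self-intersecting "bow-tie" rings — which real
segmentation exports occasionally contain — are repaired by splitting at
the first edge crossing and keeping the larger simple sub-ring
(recursively, up to four splits); unrepairable rings are rejected with an
error rather than silently measured.

### Mask-derived boundaries

Label masks are converted to polygons with a marching-squares contour at
iso-level 0.5 on each label's binary image, which places vertices at
sub-pixel interpolated positions; the contour is then decimated with a
perpendicular-deviation tolerance of 0.05 pixel. Sub-pixel contouring
substantially reduces the staircase bias in the perimeter — the one
parameter sensitive to pixelation — but a residual upward bias of order
1–3 % on rasterised input remains and is accepted as a documented
limitation (no Crofton-style correction is applied, since the polygon
ingest path is the primary one). Labels touching the image border are
incomplete nuclei and are excluded by default (`include_border = TRUE`
overrides). Area recovery on rasterised synthetic nuclei at 0.25 µm/pixel
is tested to within 5 %.

## Case statistics

Each case is summarised per parameter by the median (size) and the
interquartile range IQR = Q3 − Q1 (pleomorphism, i.e. variability). The
IQR is always recomputed from our own quartiles, never trusted from an
input file. Two quantile conventions are exposed because the source
statistics of this field are frequently computed in SPSS:

* `interp_linear` (default): position $h = (n-1)p + 1$ on the sorted
  sample — the common linear-interpolation rule;
* `spss_haverage`: $h = (n+1)p$ — SPSS's default weighted-average rule.

The two disagree on small samples, which is the most plausible source of
the small internal inconsistencies in published quartile tables where
printed IQRs differ from their own printed Q3 − Q1 by a rounding step.
`check_printed_iqr()` makes that arithmetic explicit: it recomputes
Q3 − Q1 for every printed row and flags rows whose printed IQR disagrees
at one-decimal rounding (2 of the 24 pooled-variant rows and 5 of the 14
per-case rows), rather than correcting or hiding them.

Both pooling modes are provided — `per_case` (one summary per case, the
unit of diagnosis) and `pooled_by_variant` (all nuclei of a variant's
cases pooled) — because published pooled tables do not state which was
used; pooled-by-variant output is the one comparable to such tables.
Lesion-to-reference ratios are elementwise median ratios, carried both
raw and rounded to one decimal (the display convention of the field's
tables).

## Cut-off rules and models

`published_rules()` returns the eight published thresholds (medians:
area > 48.2 µm², perimeter > 25.2 µm, min Feret > 6.8 µm, max Feret >
9.1 µm; IQRs: > 19.4, > 5.3, > 1.5, > 2.2). Flags use strict inequality,
matching the "> threshold" phrasing of the source rules; a summary
sitting exactly at a threshold does not fire.

How the eight flags combine into one diagnosis was never specified by the
source, so the combination policy is explicit and configurable:

* `single_parameter` (default): the maximum-diameter median *and* IQR
  rules must both fire. The maximum diameter is chosen because it is the
  most influential parameter in the multivariable model;
* `all_of`, `any_of`, and `vote_k` (at least *k* of 8) are provided for
  sensitivity analyses.

ROC cut-offs are derived with the distinct observed score values as
candidate thresholds, AUC by the trapezoid rule (identical to the
Mann–Whitney concordance probability, ties counted ½ — asserted against a
brute-force pairwise count in the tests), and "highest sensitivity and
specificity" operationalised as the Youden index, ties broken toward the
smaller threshold (the higher-sensitivity side). This is the standard
reading of SPSS ROC practice; the source never defines its tie rule.

The logistic model is the maximum-likelihood fit by IRLS (`stats::glm`),
with Wald — not profile-likelihood — 95 % intervals, again matching SPSS
output conventions. Features enter on their raw scale, so odds ratios are
per µm or per µm² (a `standardize` flag rescales to per-SD). Complete
separation is detected and flagged in the result rather than silently
returned. The published odds ratios themselves are *not* reproduction
targets: they were fitted to raw per-case data that were never deposited.
The same applies to the published AUCs and sensitivities (one printed
sensitivity, 77.6 %, is not even an attainable fraction of 14 positive
cases, so the positive-set definition is unknowable); the test suite
replaces them with property checks (oracle equivalence, closed-form 2×2
recovery, coefficient recovery within 2 SE, and a case-level
discrimination bound on calibrated synthetic cohorts).

## The synthetic generator

No image data were deposited by the underlying study, so the generator is
the package's data source for testing and calibration experiments. It
emulates:

* **the nuclear area law**: lognormal, calibrated from a printed
  median/quartile row by $\mu = \ln(\text{median})$,
  $\sigma = \ln(Q3/Q1)/(2 z_{0.75})$ with $z_{0.75} = 0.6745$. Lognormal
  was chosen because every published variant row is right-skewed
  (Q3 − median > median − Q1); the residual misfit is quantified by the
  reported symmetry diagnostic $|\ln(Q3/\text{median}) -
  \ln(\text{median}/Q1)|$ rather than hidden;
* **nucleus shape**: an ellipse with per-nucleus eccentricity drawn from
  [0.3, 0.7] by default, perturbed by low-order radial Fourier noise
  (modes 2–6, total relative amplitude 0.05 by default, hard-capped below
  0.5 so rings stay simple and star-convex), randomly rotated, and
  rescaled so the polygon area equals the sampled area to machine
  precision;
* **case heterogeneity**: a multiplicative per-case median shift
  (additive on log area) with log-SD 0.17 by default, a constant fitted
  to the spread of the 14 published per-case pleomorphic medians
  (47–82.5 µm²);
* **cohort bookkeeping**: per-case nucleus counts uniform on 100–600 by
  default (study-level counts were only published in a supplement not
  reproduced here, so this default is an explicit guess), a manifest, and
  a ground-truth table of generating parameters. Everything is
  reproducible from a single seed, to the point of byte-identical GeoJSON.

Two deliberate scope notes. First, perimeter and Feret laws are *not*
independently calibrated — they emerge from the area law and the shape
model — so only area-based statistics are quantitative calibration
targets; the other parameters are structurally realistic but not matched
to printed rows. Second, the generator does not emulate H&E texture,
segmentation errors beyond boundary noise, overlapping nuclei, or the
apocrine/non-apocrine cytology axis; passing tests therefore demonstrate
correctness of the measurement and statistics machinery on
realistically distributed boundaries, not robustness to real-world
segmentation failure modes.

### Calibration versus heterogeneity

Calibration-fidelity checks (pooled median within 5 %, IQR within 10 %
of the generating row at 2000 nuclei) run with `case_heterogeneity = 0`:
with the shift active the pooled distribution is intentionally *wider*
than the base law, so the generating target would no longer be the
printed row. The discrimination experiment (20 cases per arm, 200 nuclei
per case, pleomorphic vs classic score-1, case-level area-IQR ROC
required to exceed AUC 0.85) keeps the default heterogeneity, since
per-case spread is precisely what a case-level classifier must survive.
These problem sizes (2000-nucleus calibration cohorts, 40-case
discrimination cohorts, 32–96 polygon vertices) were chosen as the
smallest at which the statistical tolerances above are comfortably
non-trivial.

## Numerical choices and degenerate inputs

* Quantile of an empty vector, non-finite coordinates, rings with fewer
  than three distinct vertices, collinear ("zero-area") rings, ROC with
  one class, logistic fits with a constant feature or one class: all hard
  errors with named causes.
* Coordinate round trips (GeoJSON write/read) are exact to well below the
  documented 1e-9 µm tolerance; measurement CSVs print
  full-precision (`%.17g`) values so a write–read–write cycle is
  byte-identical.
* The GeoJSON reader accepts both QuPath's nested
  `{"classification": {"name": ...}}` and a plain string; unit handling
  is explicit (`pixel_size` multiplies file coordinates; omit it for
  µm-native files) because exports in the wild are inconsistent about
  units.
* Label masks written to disk use 16-bit grayscale TIFF, which round
  trips integer labels exactly.

## Known limitations

Beyond the generator scope notes above: no texture/chromatin or shape
features (circularity, solidity) — the quantitative results this package
reproduces use size parameters only; no pyramidal whole-slide formats; no
stain handling; single isotropic pixel size per image. The published
rule-set thresholds are carried as constants with provenance notes; they
should be revalidated before any clinical use.
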