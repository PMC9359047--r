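---
title: "Direct 3D anatomy match for knowledge-based planning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct 3D anatomy match for knowledge-based planning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anatmatch)
```

## The problem

In pelvic IMRT planning the protocol template (e.g. rectum and bladder
V50Gy < 50 %) is a ceiling, not a target: how much further each organ can be
spared depends on the individual geometry — chiefly how much of the rectum
and bladder lies inside or near the planning target volume (PTV). Planners
probe this by trial and error. Knowledge-based planning replaces the probing
with evidence: find previously treated patients whose anatomy resembles the
new patient's, and adopt the dose–volume values *actually achieved* for them
as constraints that are demonstrably attainable.

`anatmatch` quantifies "resembles" directly on the 3D binary structure
masks instead of 1D/2D summaries (overlap-volume histograms, distance
histograms, beam's-eye-view projections), which discard volume, direction,
or depth information.

## The matching model

**Stage 0 — common grid.** All patients are resampled (nearest-neighbor for
masks, trilinear for dose) onto one shared isotropic grid, 2.5 mm by
default. The correlation objective indexes both masks with a single lattice,
which requires commensurate grids; clinical CT grids are heterogeneous, so a
common resampling target is a necessary (and configurable) choice.

**Stage 1 — translation-only PTV registration.** For binary masks, the
squared error between the test mask and a translated candidate mask
decomposes into two constants plus a cross-term, so minimizing it is
equivalent to maximizing the overlap count

$$S(u,v,w) \;=\; \sum_{x,y,z} I_\mathrm{test}(x,y,z)\,
  I_\mathrm{match}(x-u,\,y-v,\,z-w).$$

`correlationMap()` evaluates $S$ for every integer translation at once:
both masks are cropped to their occupancy bounding boxes, zero-padded to the
full linear-correlation size (sum of box shapes − 1, rounded up to an
FFT-friendly composite), transformed, multiplied with one factor
conjugated, inverse-transformed, and rounded to the nearest integer.
Rotation and sub-voxel refinement are deliberately excluded: rotational
differences between patients are part of the anatomical dissimilarity the
method is meant to measure, and binary masks at 2.5 mm gain little from
sub-voxel shifts.

Numerical choices:

* **Linear, not circular, correlation.** Padding only "up to the same size"
  would wrap large-offset scores around the volume; padding to the full
  linear size eliminates wrap-around, so the score at even the most extreme
  offset is the true (possibly zero) overlap.
* **Integer rounding before argmax.** The true score is an integer overlap
  count; rounding the inverse-FFT output removes floating-point noise and
  makes tie handling deterministic. An exact spatial-domain implementation
  (`bruteForceCorrelation`, pair-difference counting in integer arithmetic)
  is shipped as a verification oracle and asserted equal, elementwise, in
  the test suite.
* **Deterministic tie-breaks.** Among tied maxima: smallest Euclidean
  displacement in millimetres first, then lexicographic order on
  $(u,v,w)$. The convention for the sign of the translation is "the shift
  applied to the moving mask": registering a copy displaced by $+d$ returns
  $-d$, and `applyTranslation()` with that result restores alignment.
* **Search range.** The full linear-correlation range is searched; no ±k
  window is imposed.

**Stage 2 — Dice ranking.** The candidate's PTV, rectum and bladder are all
moved by the single PTV translation — preserving the candidate's PTV–organ
geometric relationship, which is precisely the similarity of interest — and
compared with the test patient's structures by the Dice coefficient.
`matchPatient()` keeps the top `kPtv = 20` patients by PTV DSC, then ranks
rectum and bladder **independently** (the best rectum surrogate and the best
bladder surrogate need not be the same patient), keeping `kOar = 3` each.
All ranking ties break by ascending patient ID; a database entry whose ID
equals the test patient's is excluded (leave-one-out). With a database of
this size (~80), a fixed top-k is used rather than a DSC threshold.

**Stage 3 — constraint transfer.** The personalized constraint per organ is
the *minimum* achieved V50Gy among its matched patients — the most ambitious
value known to be achievable in comparable anatomy. The values are used
as-is, not floored at the protocol template; all other template rows (PTV
uniform dose 50 Gy, Dmin 49.5 Gy, Dmax 52 Gy, minimum V50Gy 96 %; femoral
heads V45Gy 5 %; small intestine V45Gy 10 %, Dmax 50 Gy; spinal cord Dmax
42 Gy) are emitted verbatim. Plan creation and inverse optimization belong
to a treatment planning system and are out of scope; the hand-off artifact
is a TPS-agnostic JSON objective file.

## DVH metrics

`cumulativeDVH()` counts, per dose edge (0.05 Gy bins by default), the
fraction of structure voxels receiving at least that dose (inclusive
threshold). `vAtDose()` is computed from the raw voxel doses, so VxGy values
are exact rather than interpolated; `dAtVolume()` interpolates linearly
between bracketing histogram edges (fine bins keep pass/fail decisions
stable); `doseMax()` is the single-voxel maximum — a deliberate, simplest
reading of "Dmax", configurable in principle but not a near-max dose like
D0.03cc. The homogeneity index is $100\,(D2 - D98)/D_{Rx}$ with
$D_{Rx} = 50$ Gy. `evaluatePlan()` flags each metric against the clinical
goals with strict inequalities and reports absent structures as `missing`
rather than failed. `comparePlanCohorts()` implements the paired t-test from
its definition (mean and s.d. of paired differences, two-sided p from the t
distribution with $n-1$ d.f.); identical cohorts give $p = 1$, and
zero-variance nonzero differences are flagged degenerate with $p = 0$
rather than hidden.

## The synthetic cohort: what it emulates, what it does not

No clinical database can ship with the package, so `makeDatabase()`
generates one: each patient is a jittered pelvic phantom — ellipsoidal PTV
(default semi-axes 45 × 32 × 45 mm), a spherical bladder anterior-superior
to it, a tubular rectum posterior to it, lateral femoral-head spheres and a
posterior midline cord — rasterized on the common grid (96 × 96 × 64 at
2.5 mm by default). Two parameters, `bladderPenetration` and
`rectumPenetration` (mm past the PTV surface), control the organ–PTV
overlap, the geometric quantity that drives achievable sparing. Per-patient
variation is multiplicative size jitter (s.d. 10 %) and Gaussian center
jitter (s.d. 5 mm), truncated at 2.5 s.d. so no jittered organ can leave the
grid; every output is a pure function of the seed.

Achieved doses come from a logistic falloff surrogate in place of an
optimizer:

$$D(\mathbf{x}) = \frac{h\,D_{Rx}}{1 + \exp\!\big((s(\mathbf{x}) -
  \mu)/\sigma\big)}, \qquad \mu = m - \sigma\,\log(h - 1),$$

where $s(\mathbf{x})$ is the signed Euclidean distance from the PTV surface
(negative inside; computed with an exact anisotropic distance transform in
compiled code), $\sigma = 3$ mm sets the penumbra (80–20 width
$\approx 2.8\sigma \approx 8$ mm, typical of IMRT), $h = 1.04$ caps the
hotspot at 52 Gy (the PTV Dmax objective), and the offset $\mu$ is chosen so
the prescription isodose sits exactly $m = 1$ mm outside the PTV surface.
A plain logistic of $s$ with amplitude $D_{Rx}$ cannot work here: its
supremum is the prescription itself, so no voxel would ever reach 50 Gy and
every V50Gy would be identically zero. The hot, shifted form keeps the
sigmoid-in-distance character while making V50Gy a nonzero, smooth,
monotone function of anatomy — `V50Gy` equals the fraction of organ voxels
with $s \le m$, exactly, which the tests verify against the DVH route.
Noise is off by default (the surrogate is deterministic); Gaussian dose
noise can be enabled for robustness experiments.

What a green test on this cohort establishes: that registration, ranking,
and constraint transfer recover anatomical similarity and track each
patient's own achievable dose better than chance. What it does **not**
establish: clinical dose realism (no beam model, no scatter, no
optimizer trade-offs between organs), inter-observer contouring variation,
or realistic organ shape variability (the phantoms are smooth quadrics).
Clinical-cohort effect sizes cannot be reproduced or checked at desk scale.

## File formats

No DICOM or NIfTI library is available in this environment, so the package
defines plain-text equivalents with the same semantics: a contour JSON
(named ROIs with planar polygons in mm; alias-table name matching;
rasterization by the even–odd rule on voxel centers with XOR across
same-slice polygons so holes work; PTV mandatory), a dose JSON (stored
values with a mandatory scaling attribute — missing scaling is an error, as
for a malformed dose object — and trilinear resampling), and a per-patient
mask bundle (run-length-encoded occupancy plus grid metadata and achieved
DVH parameters). Contours whose plane lies farther than half a slice
spacing from any grid slice are skipped with a warning.

## Degenerate inputs and edge conventions

* Registration of an empty mask is an error (no meaningful optimum); the
  Dice coefficient of two empty masks is an error (0/0).
* A voxel belongs to a polygon iff its *center* is inside (even–odd rule,
  half-open edge handling so abutting contours do not double-count).
* Mask resampling is idempotent on identical grids; dose resampling clamps
  at the source boundary rather than extrapolating.
* `dAtVolume(curve, 100)` is 0 Gy by definition (the smallest dose at which
  the volume fraction has dropped to 100 % is the first edge); use
  `doseMax()` for the hottest voxel.
* Translations that push voxels off the grid drop them — no wrap-around.

## Known limitations

Translation-only registration cannot credit a candidate whose anatomy
matches after rotation; this is by design but inflates dissimilarity for
strongly tilted targets. The constraint is the raw minimum of three achieved
values, so a single outlier plan in the database propagates directly into
the derived constraint (the clinical workflow would catch this at
optimization time, which is out of scope here). The synthetic cohort's
achieved values are optimistic near zero overlap (a real optimizer cannot
always push an organ fully out of the 50 Gy region), so transfer-accuracy
statistics on the synthetic cohort should be read comparatively (matched vs
random), not as absolute clinical errors.
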