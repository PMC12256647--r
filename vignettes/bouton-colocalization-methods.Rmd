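---
title: "Object-based 3D colocalization and soma-size mixtures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Object-based 3D colocalization and soma-size mixtures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boutonCI)
```

## The problem

Two fluorescence channels label partially overlapping sets of axonal
boutons — for example an anterograde tracer filling one afferent system
(the *reference* channel) and an immunolabel for a synaptic protein (the
*candidate* channel).  Pixel-correlation colocalization measures (Pearson,
Manders) are poorly suited here because the two labels fill boutons
differently: a tracer fills the whole terminal, while an immunolabel marks
vesicle clusters inside it, so even a perfectly double-labeled bouton has
imperfect pixel overlap.  The object-based statistic implemented in this
package instead reduces each segmented bouton to a centroid and an
equivalent-sphere radius and asks whether the *objects* overlap.

## The colocalization statistic

For each object, its nearest neighbor in the *opposite* channel is found
by exact Euclidean search on centroids.  The **interbouton distance** is

d_inter = d_center − r_self − r_neighbor,

the center distance minus both equivalent radii, where each radius comes
from the object's volume, r = (3V / 4π)^(1/3).  Two objects are
**colocalized** iff d_inter < 0 — strictly: a pair of spheres that exactly
touch is *not* colocalized.  Subtracting radii makes the criterion
size-aware: two large boutons whose centers sit 1 µm apart can overlap,
while two small ones at the same center distance do not.

Per image, both directional percentages are computed, and the
**Colocalization Index** is their ratio:

CI = (% candidate objects colocalized) / (% reference objects colocalized).

The normalization cancels false-positive object detection that affects
both directions: under the design assumption that every reference bouton
contains the candidate marker, CI = 1 means complete colocalization, and
CI < 1 measures the prevalence of singly labeled candidate objects.  CI
can exceed 1 when reference-channel colocalization is itself incomplete.
CI is computed **per image**, and group statistics (mean ± SEM, Welch's t)
operate on per-image CI values — the sampling unit is the image, not the
object.

Two properties of the statistic are worth knowing.  First, the neighbor is
chosen by *center* distance before radii are subtracted; a non-nearest
object with a large radius could overlap more than the nearest one.  This
is a documented property of the method, kept as defined rather than
"corrected".  Second, no deduplication is applied when several candidate
objects share one reference neighbor; each object contributes once to its
own channel's percentage.

## Segmentation

The segmentation stage reproduces, with open components, what commercial
surface-rendering tools do:

1. **Smoothing** — Gaussian blur with physical sigma `sigma_um`
   (default 0.10 µm, the "surface detail" scale), converted per axis to
   voxel units by the anisotropic spacing.
2. **Threshold** — fixed value, or automatic by between-class-variance
   maximization (Otsu).  The automatic criterion is flat across an empty
   intensity gap between modes; the implementation takes the midpoint of
   the maximal plateau, which is both deterministic and centered.  A
   fixed-value override is always available because real acquisitions were
   thresholded by eye.
3. **Connected components** — 26-connectivity by default (the most
   inclusive neighborhood, closest to what a marching surface would
   merge); 6 and 18 are selectable.  Labels are assigned in deterministic
   first-voxel order.
4. **Measurement** — voxel count, physical volume, unweighted centroid of
   voxel centers (voxel center at `(index + 0.5) × spacing`, 0-based), and
   the equivalent-sphere radius.  Centroids are geometry-derived (binary),
   not intensity-weighted, matching surface-based object extraction.
5. **Minimum-size filter** — objects smaller than 15 voxels are excluded
   as likely background speckle; objects with exactly 15 voxels are kept.
   A physical threshold (µm³) mode exists as well, because a voxel-count
   rule changes meaning whenever the voxel spacing changes; the two modes
   are intentionally not reconciled against each other.

## The synthetic scene generator

Because no imaging data ships with the package, every downstream stage is
validated against simulated ground truth.  `generate_coloc_scene()` places
spherical boutons in a box: each reference object gets exactly one
overlapping candidate partner (center offset at most half the smaller
radius, guaranteeing a negative interbouton distance), plus a controllable
number of unpaired candidate objects.  All non-paired objects keep a
surface gap of at least `min_separation` (default 1.0 µm), so unpaired
objects never overlap across channels and same-channel objects never merge
when rendered.  The ground-truth candidate colocalization fraction is
exactly `n_reference / (n_reference + n_extra_candidate)`.

Defaults, chosen once: radii are lognormal with median 0.5 µm and
`sdlog = 0.3` — a right-skewed law spanning roughly 0.6–2 µm bouton
diameters, the size range of driver-type terminals — truncated to
[0.3, 2.0] µm because sub-0.6-µm-diameter objects are not resolvable as
boutons at the axial spacing the renderer emulates.  The source study does
not report bouton density or size distributions for its images, so these
are realistic stand-ins, not estimates of that data.  Rendering paints
solid spheres on an anisotropic grid (default spacing 0.3 × 0.1 × 0.1 µm
in z, y, x), optionally blurs with an anisotropy-aware Gaussian PSF, and
adds Gaussian noise clipped at zero.  Poisson photon noise, Airy optics,
spectral bleed-through and axon fibers are deliberately omitted: the goal
is to exercise the statistic, not to simulate a microscope.  Consequently,
passing recovery tests demonstrate correctness of the *pipeline
arithmetic* on well-separated convex objects; they do not certify
segmentation behavior on dense neuropil, touching boutons, or structured
background.

All randomness in a call flows from one explicit `seed`; a fixed seed
gives bit-identical scenes, datasets and noise.

## Soma-size mixtures

The soma workflow mirrors model-based clustering of cell sizes:

1. **Glia exclusion.**  GABA+ interneurons are the smallest neurons
   present, so the 1st percentile of GABA+ soma areas (linear
   interpolation) bounds the neuronal size range from below; cells smaller
   than the cutoff (default 40 µm²) are excluded as glia.  Exclusion runs
   *before* fitting (the alternative order is not supported; filtering
   first keeps the mixture from spending a component on glia).
2. **EM fitting.**  Univariate normal mixtures, unequal variances by
   default (the flexible family); an equal-variance mode is provided since
   either family can win on real data.  Initialization is quantile-spread
   means with pooled SD and uniform weights, plus 5 seeded random
   restarts, keeping the best converged log-likelihood.  Convergence is a
   relative log-likelihood change below 1e-8 (cap 1000 iterations);
   component collapse (SD below 1e-6 of the data SD) discards that
   restart.  The log-likelihood trace is stored so monotonicity is
   testable.
3. **BIC selection.**  BIC = 2·logL − p·ln n with p = 3K − 1 (unequal) or
   2K (equal), *maximized* over K (default 1..9).  Only converged fits are
   candidates.  The convention is stated explicitly so signs are never
   flipped: a "higher BIC" here means a better model.
4. **Classification.**  Maximum posterior; exact ties go to the
   lower-mean component.  Components are always reported in ascending-mean
   order, making outputs deterministic.

The number of components is a data outcome, not a package constant: the
tool reports whatever BIC selects.

## Group statistics

The comparison layer wraps the standard tests with the conventions fixed:
two-sided p-values throughout; Welch's t with Welch–Satterthwaite df (two
equal constant samples give t = 0, p = 1 by contract); Mann–Whitney U
with exact p for n₁ + n₂ ≤ 12 (null U distribution when untied, full
enumeration when tied) and tie-corrected normal approximation (no
continuity correction) otherwise; two-sample KS with asymptotic p;
Kruskal–Wallis with Dunn's z post hoc under Bonferroni (the named choice
for an unspecified "multiple comparisons" procedure — stated in the output
metadata); one-way ANOVA with Tukey's HSD.  Descriptives are mean ± SEM
with t-based 95% CIs.

## Numerical and design choices

- **Ties in nearest-neighbor search** resolve to the lowest neighbor id,
  making assignments reproducible.
- **Exactly zero interbouton distance** is not colocalized (strict `< 0`).
- **CI denominator zero** (no reference object colocalized) is an error,
  not an Inf/NaN: such an image violates the normalization assumption and
  must be inspected, not averaged.
- **Per-image warning, not error**, when a channel has fewer than 200
  objects (the design minimum per image); the threshold is configurable.
- **Determinism**: pipelines re-run with the same config and seed produce
  byte-identical CSV outputs, and every tunable parameter actually used is
  echoed into the run manifest.

## Problem sizes used in the shipped validation suite

The test suite regenerates all inputs at run time.  End-to-end CI
recovery uses scenes of 48 reference objects with ground-truth candidate
fractions {1.0, 0.8, 0.5, 0.2} across 20 seeds, rendered noiselessly at
0.3 × 0.1 × 0.1 µm; recovered CI stays within ±0.05 of truth.  Mixture
recovery uses n = 1000 draws from the 125.2/251.7 µm² two-component
default (SDs 30/60), with BIC selecting K = 2 in at least 18 of 20 seeded
runs and median absolute mean error under 5 µm².  Welch calibration uses
2000 null simulations at n = 20 per arm.  These sizes were chosen as the
smallest that make the checks statistically meaningful.

## Known limitations

- Equivalent-sphere geometry assumes roughly convex boutons; elongated or
  merged objects inflate radii and can over-call colocalization.
- The nearest-neighbor-then-radii ordering can miss an overlapping
  non-nearest object (see above).
- Automatic thresholding assumes a bimodal intensity histogram; dim,
  dense labeling may need the fixed-threshold mode.
- The renderer's noise model is additive Gaussian only.
- No 2D mode, no pixel-overlap coefficients, no mesh export.
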