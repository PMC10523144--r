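---
title: "Quantifying islet architecture with relative radii"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying islet architecture with relative radii}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(IsletRadius)
```

## The problem and the model

Islets of Langerhans in rodents typically show a mantle–core architecture:
beta cells in the core, alpha and delta cells in a peripheral mantle.
Impaired glucose tolerance and diabetes are associated with remodelling of
this arrangement. IsletRadius quantifies it from stained pancreatic
sections in two steps:

1. **Detection.** Hormone-positive pixels are isolated by thresholding:
   an HSV colour box for DAB-brown immunohistochemistry, or an intensity
   level (fixed or per-image Otsu) for immunofluorescence grayscale
   channels. No smoothing, deconvolution or learned segmentation is
   applied; detection is deterministic and idempotent.
2. **Geometry.** The user supplies, per islet, a boundary polygon (in this
   package: a `.polygons.json` sidecar per image rather than an
   interactive drawing, so analyses are scriptable and reproducible).
   All detected pixel centres inside the polygon are transformed to polar
   coordinates about the polygon centre; each receives a *relative
   radius*, $100\,r/R(\theta)$ percent, where $R(\theta)$ is the boundary
   radius along the same direction.

$R(\theta)$ is defined by **linear interpolation of the vertex radii over
the vertex angles**, with circular wraparound between the last and first
vertex. This is deliberate and is *not* the exact ray–edge intersection:
for a square queried between two corners the interpolated radius stays at
the corner radius $\sqrt 2$ where the true edge lies at distance 1. The
two definitions converge as the vertex count grows — for a regular 256-gon
they agree to better than 0.1 % — and a hand-drawn islet border is dense
enough that the distinction is immaterial in practice. The test suite
carries both: a scalar-loop interpolation oracle that must agree with the
package bit-for-bit, and an exact-intersection oracle used only in the
many-vertex limit. The shipped package contains exactly one definition of
the statistic.

### Validity of the boundary polygon

The projection $R(\theta)$ is single-valued only if the vertex angles
about the centre are weakly monotonic — increasing or decreasing — up to
one cyclic wraparound. The "one wraparound" allowance matters: a convex
polygon traversed from an arbitrary start vertex always has exactly one
angle wrap, and raw monotonicity would wrongly reject it. Convex polygons
are therefore always valid; concave ones may or may not be. An invalid
polygon is repaired by sorting its vertices by ascending angle (ties
broken by ascending radius, deterministically) and the repair is both
flagged on the result row (`polygon_was_invalid`) and reported as a
warning, because it changes the drawn shape. One consequence of repair is
that relative radii above 100 % can occur; since the statistic is defined
only for cells inside the islet, those are excluded from the per-islet
mean and the exclusion percentage (`pct_excluded`) is reported so the user
can judge how much the repair distorted the islet. Radii of exactly 100 %
are genuine boundary hits and are kept.

### Summaries and exclusion rules

Per islet the package reports the arithmetic mean of the included relative
radii, the inclusion/exclusion counts, and the *relative area*: the
percentage of islet pixels that are hormone-positive. Islet membership of
a pixel uses the even-odd rule on the pixel centre (at $(x+0.5, y+0.5)$ in
0-based indexing), with boundary-grazing centres counted as inside — a
deterministic rule that an independent point-in-polygon implementation can
check, and does, in the tests. An islet with no staining (or, after
repair, no included radii) is flagged `excluded_no_staining` and its mean
is reported as missing — never as 0, which would masquerade as extreme
central localization and bias cohort averages.

## Parameters that matter

* **HSV box** (`ihc`): hue 0–50°, saturation ≥ 0.2, value 0.1–0.95 by
  default. These are documented heuristics for an earthy red-brown DAB
  chromogen on a hematoxylin counterstain, not measurements; real batches
  vary and the box is meant to be tuned via the INI config file
  (`inst/extdata/detection_default.ini`) or `DetectionConfig()`. The hue
  interval may wrap through 0° (configured as lower > upper), which a
  red-brown box near hue 0 can need.
* **IF threshold** (`if`): Otsu per image by default, because a fixed
  sensible level depends on acquisition settings; a fixed level in [0, 1]
  is available when channels are comparably exposed. The threshold is
  inclusive (intensity ≥ level is positive).
* **`minBlobSize`** (pixels, default 0 = off): optional
  connected-component size filter for speckle; off by default because the
  method is defined as pure thresholding.
* **Centroid**: vertex arithmetic mean by default — the simplest reading,
  and the one the angle-sorting validity rule presupposes; the
  area-weighted (shoelace) centroid is available via
  `polygonCentroid(poly, "area")` for users who prefer it. For the
  near-convex, densely sampled polygons of real islet borders the two are
  close.
* **Angle conventions**: angles are measured from the positive horizontal
  axis in image coordinates (y down) and normalised to $[0, 2\pi)$; a
  point exactly at the centre gets angle 0 by convention (its radius is 0,
  so the choice cannot affect any result). The monotonicity test uses a
  tolerance of $10^{-9}$ radians.

## The synthetic-data generator

`simulateIslet()`/`simulateCohort()` render round cell "blobs" at
prescribed relative radial positions inside an n-gon boundary, in either
staining mode, with exact per-pixel ground truth. Three phenotypes mirror
the biological regimes of interest: *mantle* (fractions uniform on
0.85–0.95, the peripheral alpha/delta arrangement), *core* (0.2–0.4), and
*diffuse* (area-uniform over the islet disc, for which the expected
relative radius is analytically $\mathbb{E}[r/R] = 2/3$). Blob centres are
placed using the same angular interpolation of the boundary that the
analysis uses, so on circle-like polygons the pipeline should — and in the
tests does — recover intended means to well under 2 percentage points;
blob pixels inherit their centre's intended fraction as approximate truth,
with the disc extent absorbed by that tolerance. Cohort defaults (256×256
images, 128-gon boundaries with circumradius drawn on 55–90 px, 40 blobs
of radius 1.5 px per islet, foreground sampled inside the default
detection box, background a counterstain-like lavender outside it, no
noise) were chosen once as a plausible desk-scale emulation of sectioned
islets.

What the generator does *not* emulate: uneven illumination, stain
gradients, chromogen mixtures, point-spread blur, touching islets,
exocrine false positives, or hand-drawn (noisy, concave) borders. Passing
recovery tests therefore validates the geometry and bookkeeping of the
pipeline, not the adequacy of any particular threshold box for a real
staining batch — thresholds must still be validated against the user's own
material.

## Numerical and design choices

* Boundary interpolation is implemented with `findInterval` plus the
  explicit two-point linear formula (not `stats::approx`), so a scalar
  reference loop reproduces it exactly; the vectorised path and the loop
  agree bit-for-bit on thousands of random convex polygons in the suite.
* Detection runs on the whole image; detected pixels outside the polygon
  are discarded before any radius is computed and counted separately
  (`nOutside`), not in `pct_excluded` — the exclusion percentage speaks
  only about the >100 % consequence of polygon repair.
* Degenerate inputs fail loudly: polygons with fewer than three distinct
  vertices, or capturing no pixel centre, are errors rather than empty
  results; a constant image under Otsu yields a warning and an
  all-negative mask.
* Multi-frame TIFFs contribute only their first frame, with a warning.
* Support images (DAPI) are matched by the first three filename
  characters, first match in lexicographic order when ambiguous, and are
  contrast-stretched for display only; the suite asserts byte-identical
  CSVs with and without them.
* CSV numerics are written at 6 decimal places so repeated runs are
  byte-identical; the XLSX mirror stores full doubles; run metadata
  (config fingerprint, timestamp, version) lives in a JSON sidecar so the
  timestamp cannot break CSV determinism.
* Per-pixel (rather than per-connected-component) radii are computed: each
  positive pixel is a point. This weights larger cells more, matches the
  detection granularity, and avoids a segmentation step the method does
  not define.

## Problem sizes in the shipped tests

The suite validates geometry exactly on hand-derivable configurations,
bit-for-bit against the scalar oracle on 1,000 random convex polygons, and
end-to-end on seeded cohorts of 20 (mantle), 20 (core) and 50 (diffuse)
islets at 256×256 px — sizes chosen to exercise every rule while keeping
the default test run fast on a laptop. The acceptance script regenerates
comparable cohorts from a user seed and reports cohort means, the
recovery error, and the exact geometry values.

## Known limitations

* The statistic depends on the drawn boundary; two annotators drawing
  different polygons get different radii. The validity flagging bounds,
  but does not remove, that subjectivity.
* The angular-interpolation boundary overshoots straight edges between
  sparse vertices; borders should be drawn with enough vertices (dozens)
  for the overshoot to be negligible.
* Thresholding cannot separate overlapping chromogens or rescue
  over/under-stained sections; islets indistinguishable from exocrine
  tissue still require manual curation upstream.
* Statistical comparison between cohorts (rank tests, correlations) is out
  of scope: the exported CSV/XLSX tables are designed to feed standard
  tools.
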