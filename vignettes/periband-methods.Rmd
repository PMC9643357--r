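---
title: "Methods: band quantification, proximity statistics and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band quantification, proximity statistics and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(periband)
```

## The measurement model

A field of view is a set of named nonnegative 2-D intensity rasters (`dapi`,
`green`, `red`, `farred`) with a physical pixel pitch in µm (0.1625 µm for a
40× spinning-disk acquisition, 0.32 µm for a 20× widefield one). Cells enter
as an integer nucleus label mask; segmentation itself is out of scope (the
included Otsu + connected-components segmenter is a reference implementation
for synthetic disk nuclei only and is unsuitable for real tissue, where a
trained star-convex model or similar should supply the mask).

Membrane and cytoplasmic markers are measured on the **peri-nuclear band**:
the set of background pixels whose center lies within `band_width_um`
(default 1 µm) of the nucleus, with distances taken between pixel centers in
physical µm (anisotropic pixels are handled by scaling each axis). Two
per-cell, per-channel features are reported: mean intensity and raw
integrated density (RID, the plain pixel sum), linked by
RID = mean × n\_pixels. The SDF-1/αSMA workflow measures the **cell
expansion** instead: nucleus plus band.

Three numerical choices here were genuinely open:

- **Contested pixels.** Where bands of adjacent nuclei overlap, each pixel
  is assigned to the *nearest* nucleus, ties to the smaller label, so no
  pixel's intensity is counted twice. Upstream imaging protocols leave
  this unspecified; double counting was judged the worse artifact.
- **Distance convention.** Distances are measured to the nearest nucleus
  *pixel center* (as a Euclidean distance transform would), not to the
  ideal disk boundary. The discrete band area of a disk nucleus of radius
  3.25 µm at 0.1625 µm pixels is within 5 % of the analytic annulus area
  π((r+w)² − r²).
- **Border cells.** Cells whose band may be cut by the image border are
  kept but flagged `clipped`, and `drop_clipped` in the pipeline config
  removes them; dropping silently would bias density estimates.

The preprocessing hook (Gaussian blur, grey-opening background subtraction)
defaults to *off*: upstream acquisition pipelines typically apply denoising
and background subtraction with unreported parameters, and reconstructing
an unparameterized step would be guesswork.

## Positivity calls

A cell is CD8+ iff `rid_green` strictly exceeds a threshold **and**
`rid_green / rid_red > 4`; CD66b+ iff `rid_red` exceeds its threshold and
`rid_red / rid_green > 2`. The ratio gates remove erythrocytes, which
fluoresce in several channels. All comparisons are strict (`>`), matching
the stated rule constants, so boundary cases are negative; a zero denominator
with a positive numerator counts as an infinite ratio and passes. The two
gates cannot both hold, so CD8/CD66b calls are mutually exclusive and cells
are typed cd8 / neutrophil / other.

In practice this threshold is usually set by eye (comparing RID
of marker-positive cells against cells "expressing only autofluorescence").
Here that step is replaced by a reproducible rule: the empirical quantile
(linear interpolation, R type 7; default p = 0.99) of the
autofluorescence-only RID distribution, pooled per patient. Both the
quantile and pooling level are exposed in `classifier_config()`; per-patient
pooling was chosen because staining intensity varies more between patients
than between a patient's fields.

The αSMA rule is area-based: pixels of the expansion region above a
per-channel cutoff (a deliberately simple global threshold standing in for
an interactive pixel classifier) are counted, and the cell is positive iff
that area strictly exceeds 3 µm². The conventional cutoff's own derivation is
inconsistent with it (10 % of a 46 µm² band is 4.6 µm², not 3);
the stated 3 µm² is the default and the value is configurable. Cells with
classifier-positive area > 0 in green **and** red **and** far-red
simultaneously are discarded as erythrocyte overlaps.

## Proximity statistics

Within one field of view (never across fields, and never across patients),
each CD8+ cell receives the minimum centroid-to-centroid distance to any
CD66b+ cell. Centroid distances were chosen because the per-cell results
table stores centroids; edge-to-edge distance is a documented alternative,
off by default. Categories are half-open: Touching = [0, 10) µm,
Near = [10, 20) µm, excluded otherwise (the rule is stated as "<10" and
"between 10 and 20" without closing the endpoints; 10 goes to Near, 20 to
excluded).

GZMK expression varies strongly between patients, so each cell's GZMK band
mean is divided by the mean over that patient's Near cells; by construction
the Near-category mean of the normalized value is 1 per patient (to machine
precision — "exactly" in the documentation means up to floating-point
rounding). Patients with no Near cells cannot be normalized and are dropped
from the normalized analysis with a warning. The final Touching-vs-Near
comparison pools normalized cells across patients at the cell level and
uses the classical pooled-variance unpaired two-tailed t test (Welch by
flag), as does the CD8-vs-non-CD8 comparison of cells within 10 µm of a
neutrophil. The non-CD8 comparison group is the `other` class
(CD8−CD66b−): comparing lymphocyte-like bystanders was judged the intended
contrast, rather than including neutrophils themselves.

Nearest-neighbor search is an exact vectorized all-pairs computation; at
the field sizes this package targets (≤ a few thousand cells) a spatial
index buys nothing, and tests check exact agreement with an independent
scalar brute-force oracle up to 1000 cells.

## Tabular scores

- `filter_rare_clusters()`: clusters with frequency < 0.5 % are discarded;
  exactly 0.5 % is retained (strict `<` on the discard side).
- `imfi()`: MFI × frequency, min–max rescaled to [0, 100]. Rescaling is per
  marker across clusters (the iMFI definition does not fix the rescaling axis;
  per-marker scaling keeps markers comparable within a panel), and a marker
  whose raw products are all equal maps to 0 — a documented convention for
  a degenerate min–max.
- `signature_score()`: sum of signature-gene counts over total counts per
  cell; the emphasis flag marks scores strictly above the 80th percentile
  (type-7 quantile) of all cells' scores.
- `cytolytic_index()`: √(GZMA × PRF1).

## The synthetic world

`tissue_spec()` states the simulated conditions; `render_field()` produces
the rasters, nucleus label mask and exact ground truth. Nuclei are
non-overlapping disks (radius ~ N(3, 0.3) µm, rejection-sampled fully
inside the field); classes are assigned by largest-remainder rounding of
the stated fractions and shuffled. DAPI is painted on nucleus disks.
Membrane emissions — green for CD8, red for neutrophils, far-red GZMK for
CD8 — are painted on **exactly the measurement band** (the nearest-nucleus
pixel-center ring), so rendered truth and measured geometry coincide and a
noiseless field reconstructs its emissions bit-exactly. A CD8 cell whose
true nearest-neutrophil centroid distance is ≤ 10 µm is "in contact" and
its GZMK emission is `gzmk_base × gzmk_contact_fold`. Autofluorescence adds
a constant to every cell's pixels in the three marker channels; erythrocyte
artifacts are 3 µm disks emitting in green/red/far-red and absent from the
label mask; pixel noise is i.i.d. Gaussian, clipped at zero (no Poisson
model in this version).

Defaults were fixed once, before any acceptance measurement: GZMK baseline
100 intensity units, marker emissions 100 ± 5, autofluorescence 5 (5 % of
signal), noise sd 5 (validation worlds use 20 = 20 % of the GZMK baseline),
0.32 µm pixels for large simulated cohorts.

What a green test does **not** establish: the simulator has no optics (no
PSF, no chromatic shift), no tissue architecture, no segmentation errors
(the mask is the truth), no per-cell GZMK heterogeneity beyond the contact
effect, and — because emissions are painted on uniquely owned band pixels —
no signal mixing between adjacent cells. Recovery of the contact fold here
validates the measurement and statistics chain, not robustness to
segmentation or optical artifacts.

The validation worlds (`validation_spec()`, 300 × 300 µm fields with 150
CD8 / 150 neutrophils / 100 autofluorescence-only cells, cohorts of 5
patients × 4 fields) drive three studies: parameter recovery of fold 2.0
through the fully rendered image pipeline; null calibration (fold 1.0, 200
cohorts) of the Touching-vs-Near test, run at the placement level via
`simulate_truth_field()` — rendering 4 000 fields would serve no purpose,
since under the null the statistical path is what is being calibrated, and
the fast path models the band-mean measurement as truth +
autofluorescence + noise/√(band pixels); and classification recovery
(noiseless → 100 %, noise at one fifth of the class separation → ≥ 95 %).
Erythrocyte artifacts are disabled in the classification-recovery world
because cells overlapping them are *supposed* to be removed, which is a
different property, tested by the rule-constant checks.

## Known limitations

- The TIFF codec covers only uncompressed little-endian single-sample
  grayscale baseline TIFF (uint16/float32/float64, single or multi-strip).
  It round-trips its own files bit-exactly and interoperates with
  `tifffile`; compressed, tiled, big-endian or RGB TIFFs are rejected.
- The reference segmenter assumes bright, well-separated nuclei.
- Threshold calibration needs annotated autofluorescence-only cells (≥ 20
  by default); on real data without such annotations, thresholds must be
  supplied in the config.
- The pixel "classifier" is a global threshold, not a trained model.
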