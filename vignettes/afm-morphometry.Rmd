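---
title: "AFM morphometry of centromeric chromatin: models, estimators and design choices"
author: "afmchrom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AFM morphometry of centromeric chromatin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmchrom)
```

## The measurement problem

In-air tapping-mode AFM of chromatin deposited on atomically flat mica
yields a height raster `z(x, y)` in nanometres. Three single-molecule
classes matter here: nucleosomes (smooth domes, apparent peak heights
roughly 1.8–2.9 nm depending on composition and cell-cycle stage,
half-max footprints 12–14 nm across), large polygonal CENP-C-scaffolded
complexes (flat-topped, 5.8 nm and taller, lateral size 27 nm and above),
and nucleosome-free DNA (ridges of only ~0.5 nm). Because tip–sample
mechanics attenuate soft biological material, apparent AFM heights are
roughly half the cryo-EM heights of the same assemblies;
`cryoemToAfmHeight()` encodes that attenuation as a plain multiplicative
factor (default 0.5).

Every quantity the pipeline reports is defined relative to the local
*background* (the mica surface), so background estimation, not absolute
calibration, is the accuracy-limiting step.

## Background model

`flattenPlane()` fits `a + b·x + c·y` by least squares, iteratively
excluding pixels more than `k = 2` residual-sd *above* the fit (three
passes). The exclusion is one-sided because particles only stick up.
`estimateBackground()` then takes the histogram mode (0.05 nm bins,
refined by the median of pixels within ±1.5 bins) as the background
level, and a mode-centred robust sd (1.4826 × MAD within ±3 robust sd) as
the noise scale. The mode, unlike the mean, is insensitive to particles
covering up to ~20 % of the field. Heights are referenced to this global
level by default; a per-particle annulus median is available
(`localBackground = TRUE`) for substrates that are not atomically flat.
Mica is, which is why global is the default.

## Peak heights on noisy rasters

The raw estimator `height = max(z in region) − level` is unbiased on
noise-free data but inflates under scan noise by the expected maximum of
the noise over the near-peak pixels. The effect is small for curved dome
crests (few pixels lie within one noise-sd of the peak; ≈ +0.03 nm at
0.05 nm noise) but large for flat-topped complexes, whose plateaus expose
hundreds of pixels (≈ +0.14 nm). Median despeckling is not a good
default either: a 3×3 median clips an elliptical dome crest by its
*minor*-axis curvature, `π²p²/(4B²)` per pixel step (≈ 0.05 nm for a
CENP-A-sized dome), which overcorrects.

The default estimator therefore reads peaks from a lightly
Gaussian-smoothed image (σ = 0.6 px, radius-2 separable kernel), engaged
only when the measured background sd exceeds 0.01 nm so that noise-free
data are read exactly. Smoothing cuts the noise maximum by ~4× at the
cost of a small curvature-proportional crest rounding, leaving residual
height bias at the few-hundredths-of-a-nm level for both shape classes.
Footprint membership (below) is judged on the *raw* heights: smoothed
footprints systematically shrink steep-rimmed complex outlines.

## Footprints, Feret diameters and roundness

Footprints are defined at half of (peak − background) by default
(`halfMax = TRUE`), which decouples the measured diameter from the
detection threshold. Thresholded-region footprints remain available.

Pixel geometry follows a half-open convention: pixel (i, j) covers
`[(j−1)p, jp) × [(i−1)p, ip)`. For caliper quantities the footprint is
represented by its pixel centers expanded by a *half*-pixel square
(centers ± p/4). A full pixel-corner hull is exactly one Minkowski
pixel-square too wide in every direction (+p(|cos φ|+|sin φ|) per
direction φ), a center-only hull is symmetrically too narrow; rim pixels
are on average half-covered by the continuous footprint, so the
half-square expansion estimates continuous extents with negligible
quantization bias (a rasterized 12 px disk reads 12.5 px across rather
than 13+ px from corners). Using one point set for every Feret quantity
also makes the ordering `feret_min ≤ feret_max ≤ feret_boxdiag`
structural rather than approximate.

From the hull the pipeline reports:

* `feret_max_nm` — rotating-calipers maximum (antipodal-pair sweep,
  exact for convex polygons; cross-checked in the tests against the
  brute-force maximum pairwise distance);
* `feret_min_nm` — rotating-calipers minimum width (smallest
  edge-supported slab);
* `feret_boxdiag_nm` — the diagonal `sqrt(a² + b²)` of the
  principal-axis bounding box, with axes from the pixel-center
  covariance. This is the convention under which an oval of extents
  15 × 17 nm has "maximum Feret's diameter" ≈ 22.6 nm, and it is the
  convention used for complex diameters throughout; the column is
  labelled explicitly so the two conventions cannot be confused;
* `eqdiam_nm` — equivalent-circle diameter from the footprint area;
* `roundness` — `feret_min / feret_max` (1 for a perfect circle), with a
  best-fit-ellipse alternative (`roundnessMode = "ellipse"`, the ratio of
  principal-axis extents).

## Detection and classification

Detection thresholds at `max(3 × background sd, 0.5 nm)` above the
background level, groups pixels by 8-connectivity, drops regions below
`minArea_nm2 = 40`, flags border-touching regions (excluded from
measurement by default), and can optionally split merged regions by
marker-based watershed (off by default: population statistics should come
from clearly separated particles). Footprints below 4 px are debris.

Default class gates: nucleosome if height ∈ [0.8, 4) nm and gate-Feret
≤ 21 nm; complex if height ≥ 4 nm *or* gate-Feret > 21 nm, with footprint
area ≥ 150 nm²; otherwise debris. The gate-Feret is the box-diagonal.
The 21 nm boundary is the sd-weighted midpoint between the nucleosome
(≈ 15.7 ± 2 nm) and asynchronous-complex (≈ 27.4 ± 2.7 nm) box-diagonal
populations, so complexes from the short tail of the height distribution
are still caught by their lateral size; the area floor sits above
nucleosome footprints (≈ 90–180 nm²) and ~3 sd below the complex area
population. Every gate is a `classificationGates()` parameter.

## DNA tracing

Nucleosome-free DNA appears as ridges of ~0.5 nm. `segmentFilaments()`
keeps pixels 0.2–0.8 nm above background, after removing particle
footprints dilated by 4 px (covering the sub-threshold dome skirt between
the 0.5 nm detection floor and the 0.2 nm band floor, plus the smoothing
halo — and any tip broadening when tips are modelled). Segmentation runs
on a 3×3 box-mean image: the ridge crest sits only a few noise-sd above
the band floor, and an unsmoothed mask grows ragged nubs that the
skeleton would mistake for junctions (a median would clip the thin crest
toward the floor; the mean keeps it ~7 sd clear).

`traceContour()` skeletonizes by Zhang–Suen thinning followed by a
redundant-pixel cleanup: thinning can leave 2-px diagonal staircases
whose pixels all have degree ≥ 3, so pixels whose neighbour arcs form a
single connected component are removed until the skeleton has unit
width. Spurs shorter than 5 px that terminate at a junction are pruned
(free-standing short paths are kept — they may be real short filaments).
*Branch points* are pixels with ≥ 3 connected neighbour arcs — not simply
degree ≥ 3, which staircase corners reach with only two arcs. Branched
skeletons are flagged and split at those pixels; cyclic skeletons are
flagged and opened. Contour length sums chain-code steps (1 px
orthogonal, √2 px diagonal); `contourToBp()` divides by the helical rise
(0.34 nm/bp, B-form; a config field printed into every trace output).
The ~+6 % chain-code overestimate of smooth curves and the ~2 px
endpoint erosion of the skeleton largely cancel, leaving ensemble mean
contour lengths unbiased at the percent level (verified against planted
ground truth in the tests).

## The synthetic-field generator

The generator exists so that every stage above can be validated against
known ground truth; its defaults encode the measured population
statistics of the study system.

* **Nucleosomes** are elliptical cosine-tapered domes,
  `h(ρ) = peak · (1 + cos πρ)/2`, parameterized so the *half-max* major
  extent equals the preset "diameter" and the minor/major ratio equals
  the preset roundness. Peaks land exactly on pixel centers so planted
  heights are sampled exactly.
* **Complexes** are flat-topped convex-polygon prisms (4–8 vertices,
  default 6 — the shapes are polygonal, the exact vertex count is not
  diagnostic) with a cosine rim of half-width 0.25 in gauge units; the
  half-max outline is the polygon itself, affinely scaled so its
  principal-axis extents (a, b) satisfy `sqrt(a² + b²) = drawn Feret`
  and `b/a = drawn roundness` — i.e. the preset lateral value is the
  box-diagonal Feret, the same convention the measurement reports.
* **Filaments** are 2-D worm-like chains with one segment per pixel and
  Gaussian tangent-angle increments of variance `s/P`. This is the
  surface-equilibrated chain whose tangent correlation decays as
  `exp(−s/2P)` and whose mean-squared end-to-end distance follows the
  2-D Kratky–Porod relation `⟨R²⟩ = 4PL − 8P²(1 − e^{−L/2P})`; the
  persistence default is 50 nm (double-stranded DNA). The free-DNA
  length preset draws from N(156 bp, 90 bp) truncated at 30 bp — note
  the truncation raises the planted ensemble mean to ≈ 171 bp, which the
  tracing round trips inherit.
* **Composition** is pointwise maximum: the AFM sees the topmost
  surface, so overlapping objects occlude rather than add.
* **Tip convolution** is grayscale dilation with a spherical-cap
  structuring element (`applyTipDilation()`); it never lowers a pixel and
  preserves the maxima of features wider than the tip. Validation round
  trips run at tip radius 0 so lateral ground truth is recoverable; tip
  effects are exercised separately through monotonicity properties, and
  no deconvolution is attempted.
* **Fields** place objects on a jittered grid whose cells are sized from
  worst-case object support (filament cells hold a 4.5-sd contour
  un-curled; rarer draws are resampled until their bounding box fits),
  then apply tip dilation, the background plane `a + bx + cy`, and
  i.i.d. Gaussian scan noise, in that order. Heights are truncated at
  0.2 nm (sub-noise particles are unmeasurable), lateral draws at 1 nm,
  roundness to (0.05, 1]. A mandatory seed makes every field
  bit-reproducible, and the ground-truth table lists each planted object
  exactly once.

What the generator does *not* emulate: aggregation and particle contact,
tip asymmetry and double-tip artifacts, scanner drift/bow beyond a plane,
salt and buffer debris, and DNA entering/exiting nucleosomes as connected
ridges. Passing round trips therefore demonstrate correctness of the
estimators under the stated field model, not robustness to every
real-world artifact; the statistics defaults (0.05 nm noise, 150
particles or 100 filaments per field) mirror desk-scale versions of the
study conditions.

## Statistics

Group comparisons follow the study's conventions: one-way ANOVA followed
by Tukey HSD (Tukey–Kramer under unequal n) with significance at
P < 0.05, and paired two-sided t tests — all via the standard R
implementations, with brute-force sums of squares and the two-group
`F = t²` / `q = t√2` identities kept as independent oracles in the test
suite. Degenerate zero-variance inputs return p = 1 with a warning
rather than NaN; a constant non-zero paired shift is reported as the
p → 0 limit and flagged.

`assessShift()` operationalizes immuno-AFM identification: ANOVA across
labelling conditions (`no_ab`, `primary`, `secondary`, `fab`), then a
positive call iff the secondary-or-Fab condition differs from `no_ab`
with Tukey-adjusted p < α *and* a mean height increase ≥ 0.5 nm. The
0.5 nm floor is a package decision: the smallest real positive shift in
this assay class is ~1 nm (Fab) while negative-control drift is ~0.1 nm,
so 0.5 splits them with margin; it is configurable and echoed in the
output.

`simulateLadder()` digests nucleosome arrays: each internal linker is cut
independently with probability `p·r`, where the refractoriness `r < 1`
models protein-shielded linkers; a maximal uncut run of m nucleosomes
yields `m·footprint + (m−1)·linker` bp. Terminal DNA is trimmed
completely at any cut probability, so complete digestion yields exact
147 bp (H3) or 120 bp (CENP-A) protections. Linker length is a free
parameter (30 bp default) — it is not measurable from the protection
sizes themselves. Fragment mass is conserved:
`Σ fragments + cuts × linker = Σ arrays`.

`relativeExpression()` is the comparative-Ct method: per-sample
`ΔCt = Ct_target − Ct_reference`, `ΔΔCt` as the treatment−control
difference of means, fold change `2^−ΔΔCt`. It is invariant to
per-sample Ct rescaling by construction.

## Numerical and interface conventions

Pixel indices are 0-based (row, col) in file formats, rows from the top;
physical coordinates are nm from the top-left corner; every public table
is in nm / nm² / bp. Topographs serialize to a 3-line-header TSV matrix
or XYZ triples (scrambled row order tolerated, incomplete grids rejected
naming the gap), both at full double precision so round trips are
bit-identical. Configurations serialize to YAML at 15 significant
digits; unknown keys are rejected rather than silently defaulted. CSV
outputs carry units, seed and a config hash in `#` comment headers and
are byte-identical across reruns of the same inputs.

## Known limitations

* Merged particles are measured as one unless watershed splitting is
  enabled; population means from dense fields are correspondingly
  condition-dependent.
* Self-crossing DNA is split at crossings, not resolved — per-filament
  lengths fragment when chains overlap (rare at the default field
  densities).
* The class-conditional complex height mean is slightly above the
  generative mean by construction: the height gate at 4 nm truncates the
  short tail of a broad (σ ≈ 2.1 nm) population, and the Feret gate
  recovers most but not all of it.
* No tip deconvolution, no sub-pixel peak interpolation, no
  polynomial (order ≥ 2) background models, and no vendor binary
  formats.
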