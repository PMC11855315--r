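---
title: "Pore morphometry from SEM images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pore morphometry from SEM images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poremorph)
```

## The problem

Porous gels — cryogels in particular — are used as cell scaffolds in tissue
engineering, and the size, shape, and orientation of their pores influence
cell migration and differentiation. The standard readout is a scanning
electron micrograph of a cross section, in which pores appear as dark
regions on a lighter polymer matrix (darkness correlates with depth).
Measuring pores by hand in an image editor is slow, biased, and poorly
reproducible between researchers. `poremorph` implements a headless,
fully scriptable version of the standard interactive workflow: segment the
image, trace and filter pore contours, measure each pore, let the analyst
curate the results over multiple passes, and export unit-scaled statistics.

## The pipeline

A single analysis *pass* applies, in fixed order:

1. **CLAHE** (contrast-limited adaptive histogram equalization). The image
   is split into tiles, each tile's histogram is equalized with counts above
   a clip limit redistributed, and the per-tile mappings are blended
   bilinearly. An SEM cross section that is not level shows a smooth
   illumination gradient; without correction a single global threshold
   detects pores on one side of the frame and misses them on the other.
2. **Non-local-means denoising** (fast variant). Every pixel becomes a
   weighted mean of the pixels in a 21 x 21 search window whose
   `denoise_size` x `denoise_size` patch neighborhoods look similar; weights
   are `exp(-d2 / h^2)` in the mean squared patch difference `d2`, with the
   user's `denoise_strength` as `h`. This removes speckle and stray pixels
   that would otherwise be traced as spurious contours while preserving pore
   edges. Note that smoothing a boundary changes its perimeter — and hence
   the isoperimetric ratio — much more than its area.
3. **Cutoff thresholding.** Pixels strictly below `grayscale_threshold`
   become black (pore candidates); ties and everything above become white.
   Raising the cutoff admits lighter pixels into the black set, which reads
   as an outward "erosion" of pore edges: measured areas grow monotonically
   with the cutoff.

Contours of the black regions are then traced with the Suzuki–Abe
border-following algorithm, which yields every boundary loop (outer borders
and hole borders) together with the containment hierarchy. Black regions are
8-connected, the white background 4-connected — the standard duality that
keeps boundary loops well defined. Three rejection rules partition the traced
set:

* **hierarchy**: any contour that is not a top-level outer border (holes and
  all nested descendants), and any contour touching the image frame, is
  rejected; both paint magenta in overlays. All non-root contours are
  rejected, not just first-level children, since a pore-within-a-pore is an
  imaging artifact at every depth.
* **size**: remaining contours with enclosed area below `min_pore_size_px`
  or above `max_pore_size_px` are rejected (blue).
* everything else is **accepted** (green).

The size gates are interpreted as *areas in pixels squared*: they gate the
same quantity the filter exists to control (tiny speckle regions, giant
background inversions), and the "too small to be a real pore" semantics
refers naturally to area.

## Per-pore measurements

For each accepted contour the package reports:

* **area** — the enclosed-pixel count of the 8-connected region. The
  alternative, the shoelace area of the boundary-pixel polygon (exposed as
  `polygon_area()`), is biased low by roughly half the perimeter because
  boundary vertices are pixel *centers*; for a pore with a 10 px semi-minor
  axis that bias approaches 10 %, while the pixel count is accurate to
  well under 1 %.
* **perimeter** — the chain length of the boundary with the Kulpa
  digitization correction (0.948 per axial step, 1.340 per diagonal step).
  The naive (1, sqrt 2) chain length overestimates smooth digitized
  boundaries by about 5 % on average over orientations; the corrected
  estimator is accurate to ~0.5 % on digitized circles. The plain Euclidean
  polygon perimeter remains available as `polygon_perimeter()`.
* **isoperimetric ratio** `4 * pi * A / P^2` — 1 for a disc, `pi/4` for a
  square, smaller the more elongated the pore. With the corrected perimeter
  a digitized circle measures IPR ≈ 1.01; values slightly above 1 are
  possible on digitized convex shapes and are not clipped.
* **ellipse fit** — Fitzgibbon's direct least-squares conic fit constrained
  to ellipses, in the numerically stable Halir–Flusser formulation; recovery
  is exact to floating precision when the vertices lie on an ellipse.
  Contours with fewer than 5 distinct vertices get `NA` orientation fields.
* **orientation** — pores have no inherent direction, so angles live in
  [0°, 180°), measured from +x with y pointing down; the orientation vector
  points along the fitted major axis with magnitude `major - minor`, so a
  circular pore has zero orientation.
* **centroid** — the mean coordinate of the region's pixels (interior plus
  boundary), not the polygon first moment; the two agree on the test
  fixtures but the pixel mean is the defined quantity.
* **Feret diameters** — read from the fitted ellipse axes. A
  rotating-calipers Feret on the polygon would differ on irregular shapes;
  the ellipse-axis reading is the documented behavior of the workflow this
  package reproduces.

All lengths and areas convert through the scale factor
`um_per_px = scalebar_reading_um / scalebar_length_px`; pixel mode skips
conversion entirely. Pore density divides the pore count by the full image
area in mm² — the user is expected to crop away the instrument's information
band, so the full frame is the analyzed region.

## Sessions, passes, and save profiles

One settings bundle rarely outlines every pore well. The session object
supports the resulting workflow: run a pass, save the well-outlined pores
(singly or by id range), re-run with different settings, and repeat. Saved
records persist across passes and carry an immutable snapshot of their
pass's settings (the *save profile*), which is written out with every CSV
row. Pore numbering restarts at 1 each pass; exports are keyed by
`(pass_id, pore_id)`.

A new pass may re-detect a pore that is already saved; by default no
deduplication is applied (the analyst curates, as in the interactive tool),
but `run_pass(..., suppress_saved_overlap = TRUE)` drops new contours whose
filled region overlaps a saved contour with IoU > 0.5.

Because there is no GUI, curation is recorded as a plain-text replay script
(`analyze`, `save`, `remove`, `saverange`, `removerange`, `export`); running
the same script on the same image byte-reproduces the CSV.

## The synthetic phantom

Testing needs images with known ground truth. The phantom generator emulates
the relevant features of a cryogel SEM image: dark filled ellipses
(grey 40) on a lighter matrix (grey 200), an optional linear illumination
ramp, optional Gaussian noise or salt-and-pepper speckle (applied after the
ramp, then clipped to [0, 255]), and an optional information band with a
drawn scalebar. Defaults — chosen once as the package's study conditions —
are a 1024 x 1024 frame with 20 non-overlapping interior pores, semi-minor
axes uniform in 10–16 px and aspect ratios uniform in 1.3–2.5 (capped at a
40 px semi-major axis), uniform angles, and 12 px clearance between pores
and from the frame. The aspect floor of 1.3 reflects that cryogel pores are
moderately elongated (typical mean IPR around 0.55) and keeps every planted
angle well defined: a near-circular pore has no recoverable orientation, and
`score_recovery()` likewise excludes planted aspect ratios under 1.15 from
its angular-error average.

What the phantom does *not* emulate: charging artifacts, depth-of-field
blur, pore walls shared between neighboring pores, partially collapsed or
merged pores, and irregular (non-elliptical) pore outlines. Passing the
phantom suite therefore demonstrates the correctness of the segmentation,
rejection, and measurement machinery — not that any particular settings
bundle segments a given real micrograph well, which remains the analyst's
judgment across passes.

On the default phantom the pipeline at default settings attains recall 1.0
with zero spurious detections, per-pore area errors well under 5 %, and
orientation errors well under 2°; a planted border-straddling pore lands in
the hierarchy-rejected class. These are the quantities
`scripts/acceptance.R` recomputes.

## Numerical and design choices

* **Thresholding ties go white**: "strictly under the cutoff turns black" is
  the literal rule; equality is not "under".
* **CLAHE kernel size** is interpreted as the tile-grid dimension (size N
  gives N x N tiles) by default, with `clahe_units = "pixels"` available for
  the tile-side-in-pixels reading; the clip limit defaults to 2 and is
  exposed because no single value suits both gentle contrast correction and
  strong gradient flattening (the gradient demonstrations in the test suite
  use clip 8). Images whose sides are not tile multiples are edge-padded and
  cropped back. A 1 x 1 grid degenerates to global clipped histogram
  equalization, computed directly (with an unbounded clip limit this is
  classic histogram equalization).
* **Denoising** exposes one kernel knob (the patch side); the search window
  is fixed at 21 px. `denoise_strength = 0` and `clahe_size = 0` disable the
  respective stages, which the validation experiments need for on/off
  comparisons.
* **16-bit inputs** are min–max rescaled to 8 bits with a warning, so the
  cutoff always acts on [0, 255]. Color inputs reduce by BT.601 luminance.
* **Statistics** use the sample (n−1) standard deviation throughout, both in
  the results box and in the group comparisons (matching spreadsheet
  defaults). Displayed percentages round half-even to one decimal; full
  precision is kept internally.
* **Percent difference sign**: group comparisons report
  `(test − reference) / reference × 100`; the unsigned per-pore variant is
  its absolute value.
* **Problem sizes in the test suite** (400–1024 px phantoms, 6–20 pores,
  100 random polygons) were chosen as the smallest sizes at which
  digitization error is comfortably inside the documented bounds.

## Known limitations

Everything is 2-D: no interconnectivity, tortuosity, or depth information.
Merged pores are not split (no watershed), and boundaries are not refined to
sub-pixel accuracy. Reading the scalebar automatically from the instrument's
information band is not supported — crop the band and supply the scalebar
length and reading, or work in pixel units. The group-comparison module
computes descriptive statistics and percent differences only; significance
testing is left to dedicated statistics software.
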