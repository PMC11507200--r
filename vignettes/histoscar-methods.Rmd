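---
title: "Color-based infarct quantification: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Color-based infarct quantification: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoscar)
```

## The measurement model

`histoscar` treats a scanned stained section as an 8-bit RGB raster and
the infarct question as a per-pixel, three-class problem: slide
background, normal (viable or non-fibrotic) tissue, and infarct (or
fibrotic) tissue. The assumption underlying every rule is that the stain
maps class to color reliably enough that raw channel values — with no
color deconvolution, illumination correction or learned model — separate
the classes:

* **Masson's trichrome (MTS)** stains scar collagen blue and muscle red.
  An infarct pixel therefore has a low R (characteristic values near 41
  against ~251 in normal tissue) and a dominant B. The rule is
  `R ≤ r_limit` AND `B/R ≥ br_ratio_min`; the ratio clause removes pixels
  that are merely dark rather than blue. `R = 0` is treated as an
  infinite ratio (maximally blue), which keeps the rule monotone in its
  thresholds.
* **TTC** stains viable myocardium deep red while the infarct stays
  off-white with nearly equal channels (e.g. 133, 136, 134 → sample
  standard deviation ≈ 1.5; viable 187, 69, 61 → ≈ 71). The rule is
  `sd(R, G, B) ≤ std_max` with the sample (n−1) standard deviation; the
  flavor is configurable only through the threshold since the two differ
  by a constant factor (√(3/2)) on three values.
* **Picrosirius red (PSR)** stains collagen saturated red against pale
  normal tissue. With `mean_GB = (G + B)/2`, the rule is the margin
  condition `R − mean_GB ≥ thd`. A disjunction with a bare
  `R > mean_GB` would make `thd` inert (any warm pixel passes), so the
  margin form is used and `thd` remains the user's sensitivity control.
  `mean_GB` is a half-integer compared exactly, so no floating-point
  rounding can flip a pixel at the boundary.
* **H&E** gives infarct and normal myocardium similar pink hues; the
  usable signal is an elevated G in the infarct (about 174 vs 99). Two
  passes reveal it: step 1 zeroes R wherever `R > r_limit`, leaving G and
  B unchanged (normal tissue turns light blue, pure green is a fixed
  point); step 2 keeps only green where `R < G` or `B < G` and
  suppresses everything else. The *binary* decision uses strict green
  dominance after step 1 (`G > R` and `G > B`): the step-2 disjunction
  alone would also pass light-blue normal pixels whose R was stripped,
  which is desirable in the visualization but not in a mask.

All infarct rules are evaluated only inside the **tissue mask**: a pixel
is tissue when it is not near-white (`min(R,G,B) < background_white_min`,
or bright but strongly colored) and not near-black. The restriction is
what keeps the white slide background — which trivially satisfies the TTC
spread rule — out of every mask, and the near-black clause keeps scanner
void and dead pixels out of the MTS rule (black has `R = 0`, hence an
infinite B/R ratio). Infarct masks are subsets of the tissue mask by
construction.

## Tunable parameters

All thresholds live in `stain_params()` and are user-adjustable; the
defaults are engineering choices validated on the synthetic fixtures, not
measured constants:

| parameter | stain | unit | default | role |
|---|---|---|---|---|
| `r_limit` | MTS | 0–255 | 150 | upper R bound for blue scar |
| `br_ratio_min` | MTS | ratio | 1.2 | B must dominate R |
| `std_max` | TTC | 0–255 | 20 | channel-spread ceiling for off-white infarct |
| `thd` | PSR | 0–255 | 40 | red margin over `mean_GB` |
| `r_limit` | H&E | 0–255 | 200 | step-1 red removal |
| `he_close_radius` | H&E | px | 3 | closing radius of the density filter |
| `he_min_area_frac` | H&E | fraction | 0.001 | minimum component area (of tissue) |
| `background_white_min` | all | 0–255 | 230 | background luminance cutoff |
| `background_black_max` | all | 0–255 | 10 | near-black exclusion |
| `tissue_min_area` | all | px | 64 | tissue-mask component cleanup |

Raising `r_limit` (MTS), raising `std_max` (TTC) or lowering `thd` (PSR)
can only grow the infarct mask — a property the test suite checks — so
threshold tuning on real material is predictable.

## From masks to numbers

Relative infarct size is `100 · ΣP_s / ΣP_t`, with the tissue-mask pixel
count as denominator (the slide background is never part of "the entire
section"). Physical areas are `Px² · ΣP` with `Px` in µm/pixel, reported
in mm²; serial-section volumes multiply per-section areas by `h1` (stained
thickness) and `h2` (removed thickness), both in µm, reported in mm³. The
removed tissue is assumed to carry the same areas as the adjacent stained
section. Because that assumption leaves the final gap ambiguous, two gap
policies are provided: the default `per-section` policy gives every
section its own gap (`V_Ts = ΣA_si · (h1 + h2)`); the `n-1` policy
attributes removed tissue only between consecutive sections. They differ
by exactly one gap's volume, which is negligible for realistic stacks
(≈ 1/80 here) but is recorded in every output.

Hole filling in the tissue mask is **off** by default: a ventricular
cavity is enclosed background, and filling it would silently inflate the
denominator. `tissue_fill_holes = TRUE` is available for sections where
enclosed holes are genuine staining dropouts.

Dilation of the isolated infarct is supported (disc structuring element;
the radius-1 "disc" is the full 3×3 square) but inflates the counted
area, so quantification counts the undilated mask unless the caller asks
otherwise, and every run record states which mask was counted.

Diffuse fibrosis on MTS sections uses the identical color rule with *no*
minimum-component filtering, since scattered single-pixel collagen
deposits are exactly the signal; the infarct pipeline, by contrast,
removes components below 16 px by default to suppress isolated
noise-flipped pixels.

## What the synthetic generator emulates — and what it does not

`make_section()` paints a near-white slide background, an elliptical (or
annular) tissue region in the stain's normal palette, an embedded infarct
— compact blobs, or an exact fraction of scattered pixels in diffuse
mode — in the stain's infarct palette, optional gray bubble artifacts,
sparse green speckle for H&E (1% of normal tissue by default, mimicking
the strong-but-sparse green that normal myocardium shows after the
transform), and independent per-channel Gaussian noise (sd 8 by default,
clipped to [0, 255]). The palette anchors the channel each rule keys on to
the characteristic values listed above; companion channels are plausible
completions. Truth masks are the painted regions before noise and are
exact by construction; in diffuse mode the painted fraction is drawn as an
exact pixel count, so the ground-truth fraction carries no sampling error.
All randomness flows through one seed and fixtures are bit-reproducible.

What this deliberately does **not** model: stain-intensity gradients and
batch-to-batch staining variation, out-of-focus regions, tissue folds and
tears, JPEG artifacts, the Phthalo-blue perfused area of the TTC protocol
(its strong blue gives it a large channel spread, so the TTC rule excludes
it anyway), and real histological texture. Passing the recovery tests
therefore shows that the rules are implemented correctly and are robust to
pixel noise around well-separated palettes — not that the default
thresholds are optimal for any particular scanner or staining batch, which
is precisely why every threshold is exposed.

`make_stack()` builds serial sections whose infarct follows a continuous
3-D geometry (a sphere mid-stack, or a cylinder) sampled at each slab's
mid-plane, and returns the analytic volumes of that geometry. For the
cylinder (and for the tissue cylinder in both cases) the analytic volume
is defined from the rasterized disc area, making recovery exact; the
spherical cap's volume is the continuous integral, so recovery carries
rasterization and mid-plane sampling error — about 0.05% at the default 80
sections × 15 µm with a 500 µm sphere at 10 µm/pixel, comfortably inside
the 5% the validation demands.

## Numerical and implementation choices

* Images are integer arrays `height × width × 3` in 0–255; 16-bit TIFF is
  rescaled by `round(v·255/65535)`; grayscale is replicated, alpha
  dropped. JPEG is read-only: masks and intermediates must not pass
  through a lossy codec.
* Split boundaries and ROIs are 0-based half-open intervals, so
  boundaries that tile an image reproduce it bit-exactly and a partition's
  pixel counts sum to the input's.
* Connected components use 8-connectivity (diagonal neighbours join).
  The labeling is built from a 4-connectivity pass merged across diagonal
  adjacencies with a union–find, and is checked against hand-built cases.
* The H&E density filter closes the candidate mask (disc radius 3),
  measures each closed component by the *candidate* pixels it contains
  (not the closed hull), discards components below 0.1% of the tissue
  area, and finally drops candidate components below the same floor —
  closing can weld an isolated speckle onto a dense component's label,
  and the final pass removes those stragglers.
* Degenerate inputs error loudly and early: empty ROIs, out-of-range or
  overlapping boundaries, zero tissue in a percentage denominator,
  mismatched stain/parameter combinations, out-of-range thresholds
  (never clamped).
* The analysis path contains no randomness: re-running a recorded command
  on the same inputs reproduces identical pixel counts.

## Validation problem sizes

The shipped validation uses 220×220-pixel sections (≈ 22,000 tissue
pixels), 20 noisy fixtures per stain for recovery error, an 80-section
spherical-cap stack at h1 = 5 µm / h2 = 10 µm and 10 µm/pixel for volume
recovery, and per-pixel oracle comparisons on 100 random 32×32 images per
rule. These sizes give stable estimates (recovery errors reproduce to two
decimals across seeds) while keeping the whole suite fast.

## Known limitations

The method is exactly as good as the color separation of the staining:
weakly stained or over-counterstained material narrows the margins every
rule relies on, and thresholds must then be adjusted per batch. H&E
fibrosis (as opposed to compact infarct) is out of reach by design — the
density filter that rejects normal-tissue speckle also rejects sparse
fibrotic signal. The serial-section volume model assumes the removed
tissue mirrors the adjacent section and does not interpolate shape between
planes. No attempt is made to register sections to one another or to
non-invasive imaging.
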