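---
title: "Methods: whole-plate C. elegans detection and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-plate C. elegans detection and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormscope)
```

## The problem

Phenotypic screening with *Caenorhabditis elegans* — toxicity assays in
particular — needs worm counts and positions from whole agar-filled Petri
dishes, imaged at consumer-camera resolution (nominally 3280 × 2464 px for a
whole dish). At that scale an adult worm is a thin, dark, curved object a
few hundred pixels in area, sharing the plate with round dark artifacts
(air or gas bubbles trapped in the agar) and a contrast-rich dish rim that
attracts false detections. `wormscope` implements the full surrounding
pipeline for such a detector: dish localization and background masking,
sliding-window tiling, a classical segmentation chain usable both as an
annotation generator and as a baseline detector, post-processing for
externally produced network detections, and the standard object-detection
evaluation protocol. The deep detector itself (a Mask R-CNN) is *not*
built here: training it is GPU-scale work. Its hyperparameter recipe is
carried as an exportable configuration (`mrcnn_config()`), and its outputs
are consumed as detection files.

## Dish masking

The dish edge is found by scanning the horizontal line through the image's
vertical center for luminance transitions. The line is smoothed with a
width-5 moving average; a transition is any position where the luminance
difference across a 3-px window exceeds a threshold (default 25% of the
image dynamic range — the step from agar to rim is by far the strongest
edge on that line, so the precise fraction is uncritical). Each edge is
localized at the maximum-gradient position of its transition run, which
cancels the bias the smoothing would otherwise introduce; on noise-free
synthetic plates the recovered center and radius are accurate to well
under a pixel. The circle is then shrunk by `margin_fraction` (default
0.05) before everything outside is blackened: the rim zone holds no worms
but plenty of contrast, and a 5% shrink removes it while the synthetic
ground truth (placed within 80% of the dish radius) is never touched.
Masking is idempotent and leaves interior pixels bit-identical.

## Tiling

Large plates are processed in 820 × 821-px chunks with 25% overlap. The
stride is `floor(tile * (1 - overlap))` — 615 px in both axes; flooring is
a deliberate choice, since 821 × 0.75 is not an integer. The last tile in
each axis is clamped to the image boundary rather than padded, preserving
the exact tile size at the cost of extra overlap in the final row/column.
A 3280 × 2464 plate therefore yields a 5 × 4 = 20-tile grid covering every
pixel. Detections made in tile coordinates are translated back with
`to_global()` and de-duplicated with `merge_tile_detections()`, a greedy
highest-score-wins suppression at mask IoU ≥ 0.3 (box IoU when masks are
absent). The 0.3 default mirrors the per-class NMS level of the detector
configuration; no separate cross-tile merge rule is defined anywhere else,
so reusing the redundancy-suppression threshold is the package's choice.

## The classical segmentation chain

`segment_plate()` runs, in order: dish masking, bilateral denoising
(diameter 9 px, range sigma 10 gray levels, spatial sigma 5 px), grayscale
conversion (Rec.601 luma), Gaussian adaptive thresholding (71-px window,
offset constant 4), morphological closing then opening (3 × 3 structuring
element), 8-connected component labeling, and three shape filters.
Numerical choices worth recording:

* **Threshold polarity.** Worms are darker than the agar under
  transmitted light, so foreground is `pixel < local_mean - C`. The
  complementary convention is available via `polarity = "bright"`, and an
  exact symmetry holds: binarizing the inverted image with inverted
  polarity reproduces the dark-foreground result (the local mean is
  linear).
* **Gaussian window sigma.** The local mean uses a Gaussian kernel with
  the OpenCV convention `sigma = 0.3 * ((w - 1) * 0.5 - 1) + 0.8`, since
  no sigma accompanies the 71-px window size anywhere and this is the
  convention classical pipelines of this kind are built on.
* **Connectivity.** Components are labeled 8-connected, the default of
  common blob detectors; the labeling is implemented as a 4-connected
  pass plus a diagonal-merge, because the underlying library labeler is
  4-connected.
* **Blob filter semantics.** The filter ranges — area 0–700 px²,
  convexity 0.3–1, circularity > 0.2, inertia ratio 0.2–1 — describe
  objects to *remove*: a component is discarded only when it falls inside
  **all** four ranges. Small round convex blobs (bubbles) do; worms fail
  at least two (area above 700 px², inertia ratio near 0 for an elongated
  body). Descriptor definitions follow the standard blob-detector
  conventions: circularity `4πA/P²` with the perimeter from the traced
  outer contour, convexity as pixel area over convex-hull area (hull taken
  over pixel corners so 1-px-thin shapes keep a positive hull area), and
  inertia ratio as the ratio of principal second central moments, with the
  1/12 per-pixel term so single-row components are handled gracefully.
* **Size filter.** "Bounding box below 700 px² *and* shorter edge below
  24 px" is read literally as a conjunction; an `"or"` policy is a
  configuration switch for users who prefer the stricter reading.
* **Worm area band.** The semi-automatic visual-inspection step that
  normally rejects worm-shaped contours of implausible area is replaced by
  an explicit accepted band, default 700–6000 px²: below the small-segment
  floor nothing is a credible adult worm, and 6000 px² admits a few
  crossing worms merged into one component while rejecting the huge
  ring-shaped component that adaptive thresholding produces along the
  masked dish boundary.

The chain is fully deterministic, and each filter can only shrink the
component list (monotone attrition).

## Detection post-processing

`filter_chain()` applies the inference-side filters in prose order:
background-label removal, the 0.92 confidence floor, per-class greedy NMS
at IoU 0.3, the top-100 cap, and the small-box size filter. Greedy NMS
breaks score ties by lower id, making the whole chain deterministic; it is
idempotent, and the per-stage survivor counts are attached to the result
(`attr(x, "attrition")`) so the attrition of every stage is auditable.

## Evaluation protocol

Matching is greedy in descending confidence: each prediction claims the
unmatched ground truth of highest IoU provided it reaches the minimum
(default 0.5); unmatched ground truths are false negatives, unmatched
predictions false positives. The assignment *order* is not dictated by the
FN/FP rule itself, so the package follows the Pascal-VOC/COCO convention
(greedy by score). Average precision uses all-points interpolation — the
precision envelope `max precision at recall ≥ r`, summed over recall
increments, i.e. the curve is sampled exactly where the maximum precision
drops. The "average mask IoU" reported alongside precision/recall averages
over matched pairs only; averaging each prediction against its best ground
truth regardless of matching is available as an alternative through the
match result's pair list. `iou_sweep()` recomputes everything across a
threshold grid; F1 is non-increasing in the threshold because the match
set can only shrink.

## The synthetic plate generator

`generate_dish_image()` replaces the microscope: a bright agar disc
(gray level 200) with a dark rim annulus on black, dark worms (level 60),
dark circular blobs, and additive Gaussian sensor noise, with exact
per-worm masks as ground truth. Worm bodies are unions of discs along a
skeleton generated as a smoothed random-heading walk (heading increments
N(0, 0.12 rad) per 1-px step), which produces the sinusoidal postures
adult worms show on agar; the half-width profile tapers toward head and
tail. Defaults — length 120–180 px, peak half-width 5 px — give mask areas
of roughly 850–1600 px², deliberately above the 700 px²/24 px small-segment
filters, as adult worms are on real plates; postures that coil so tightly
that self-overlap drops the rendered area below 80% of the straightened
footprint are resampled (`min_area_ratio`, set 0 to disable). Blob radii
4–14 px keep bubble areas inside the blob-removal region. An
`allow_overlap = FALSE` switch rejection-samples worms and blobs so that
nothing touches, for fixtures where every ground truth is recoverable.

The generator is deliberately simple: it does not model optics
(vignetting, point-spread blur), illumination gradients, condensation,
agar texture, eggs or larval stages, or motion across frames. Passing
tests on synthetic plates therefore demonstrate the correctness of the
pipeline's logic — geometry, filtering, bookkeeping, metric arithmetic —
not the difficulty of real plate imagery, where contrast is lower and
worm/background separation far noisier. The one real-data failure mode the
generator does reproduce on request is worm crossing (`allow_overlap =
TRUE`): crossing worms merge into a single component, matching the known
behavior of contour-based extraction.

## Problem sizes and determinism

Tests and the acceptance script run on 560 × 560-px plates with 8 worms
and 6 blobs each (20 plates for the recovery experiment), a size at which
a full classical segmentation takes a second or two and the whole suite
stays comfortably interactive; nothing in the pipeline depends on the
frame size, and the tiling layout is exercised at the full 3280 × 2464
geometry arithmetically. All randomness flows through explicit seeds: a
`synth_config` embeds its seed, so identical configurations produce
bit-identical plates, and pipeline reports hash the decoded pixel buffer
(not the compressed file) so recompression cannot break reproducibility.

## Known limitations

Crossing or touching worms are returned as one instance; splitting them
(or tracking worms across frames) is out of scope. The dish detector
assumes the dish edge crosses the central scan line and falls back to a
full-image circle when no transition is found. The classical chain's
recall on real low-contrast plates is bounded by adaptive thresholding —
it is the annotation-bootstrap and baseline tool, not a replacement for a
trained instance-segmentation network.
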