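# wormscope

Whole-plate *Caenorhabditis elegans* detection, segmentation and
evaluation in R.

Phenotypic and toxicity screens with *C. elegans* need worm counts and
positions from entire agar-filled Petri dishes imaged at consumer-camera
resolution (nominally 3280 × 2464 px per dish). `wormscope` provides the
complete pipeline around such a detector:

* **Dish masking** — locate the dish circle from luminance transitions on
  the central scan line and blacken everything outside (the contrast-rich
  rim attracts false detections).
* **Tiling** — split plates into 820 × 821-px chunks with 25% overlap,
  map tile-local detections back to plate coordinates, and de-duplicate
  across overlaps.
* **Classical segmentation** — bilateral denoising, Gaussian adaptive
  thresholding (71-px window, offset 4), morphological closing/opening,
  and shape-descriptor filtering (area, convexity, circularity, inertia
  ratio) that removes round bubble artifacts while keeping elongated
  worms. Usable both as an annotation generator and as a baseline
  detector.
* **Detection post-processing** — the inference filter chain for
  externally produced instance-segmentation outputs: background-label
  removal, a 0.92 confidence floor, per-class greedy NMS (IoU 0.3), a
  top-100 cap and a small-box filter (< 700 px² and shorter edge
  < 24 px). The companion Mask R-CNN training recipe (anchor scales
  32/64/86/128/172, ratios 0.5/1/2, LR 0.001, momentum 0.9, weight decay
  1e-4, …) is carried as an exportable JSON configuration; the network
  itself is not built or trained here.
* **Evaluation** — greedy confidence-ordered matching at a minimum IoU
  (unmatched ground truths = FN, unmatched predictions = FP),
  precision / recall / F1 = 2PR/(P+R), all-points interpolated average
  precision (AP = Σ Δr · max_{r'≥r} p(r')), and IoU-threshold sweeps.
* **Synthetic plates** — a dish-image generator with exact per-worm
  ground-truth masks, so every stage is testable without microscope data.

## Worked example

```r
library(wormscope)

## a synthetic 560x560 plate: 8 worms, 6 bubble artifacts, exact ground truth
plate <- generate_dish_image(synth_config(
  image_width = 560, image_height = 560, n_worms = 8, n_blobs = 6,
  noise_sigma = 0, allow_overlap = FALSE, seed = 11))

detect_dish(plate$image)
#> dish: center (280.0, 280.0), radius 246.0 px, margin 0.05

report <- run_classical(plate$image)
report
#> plate report: 8 worms detected

report <- run_evaluation(report, plate)
report$metrics
#> precision 1.000, recall 1.000, F1 1.000 (TP 8, FP 0, FN 0), avg matched IoU 0.987
report$pr_curve
#> PR curve (8 points), AP@0.50 IoU = 1.000
```

All 8 worms are recovered (the 6 bubbles are rejected by the shape
filters), each with a mask overlapping its ground truth at IoU ≈ 0.99;
with perfect precision and recall the interpolated PR curve is flat at 1,
so AP = 1.

A thin command-line front end over the same functions is included at
`inst/cli/wormscope` (subcommands `simulate`, `mask-dish`, `tile`,
`annotate`, `detect`, `evaluate`, `sweep`, `overlay`, `emit-config`).

## Scope

The deep detector (Mask R-CNN) is deliberately out of scope: the package
emits its configuration and consumes its detection files. Crossing worms
are returned as a single instance, and tracking across image sequences is
not attempted.
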