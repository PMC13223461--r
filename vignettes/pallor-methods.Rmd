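---
title: "Methods: color-based conjunctiva segmentation and anemia screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: color-based conjunctiva segmentation and anemia screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The screening problem

Anemia — low blood hemoglobin (Hb) — shows clinically as pallor of the
palpebral conjunctiva, the vascular membrane lining the inner eyelid.
Because the conjunctiva is thin and capillary-rich, its color tracks Hb
concentration fairly directly and, usefully, independently of skin tone.
`pallor` implements a screening pipeline that takes an everted-lower-lid
photograph and produces a three-class grading:

* **anemic** — Hb < 10.5 g/dL (both sexes),
* **moderate** — Hb 10.5–13.5 g/dL (males) or 10.5–12 g/dL (females),
  boundary values included,
* **normal** — Hb above the moderate band.

The Hb gradation (`label_from_hb()`) is the gold standard against which
images are labeled; the imaging pipeline tries to recover that label from
color alone.

## Pipeline

1. **ROI detection** (`detect_roi_baseline()`). A stand-in for a learned
   detector: the tight bounding box of pixels whose CIELAB `a*` lies
   strictly above the image's 80th percentile, padded and clipped. Any
   external detector can be substituted via the documented 0-based,
   half-open box format; the package deliberately ships only this color
   prior, not a trained network.
2. **Segmentation** (`kmeans_ab()`, `select_conjunctiva_cluster()`).
   K-means with `k = 3` on the per-pixel `(a*, b*)` pairs of the ROI.
   Lightness `L*` is excluded on purpose: illumination varies wildly
   between captures, while the chromatic plane carries the
   skin/sclera/conjunctiva distinction. The conjunctiva is taken to be
   the cluster with the maximum centroid `a*` — the reddest cluster —
   with exact ties broken by larger pixel count, then lower index.
   Externally produced masks (e.g. from a promptable segmentation model)
   can be ingested instead via `load_external_mask()`.
3. **Features** (`extract_feature_vector()`). Seven scalars on the masked
   region: mean intensity, red/green mean ratio, red−green mean
   difference, population standard deviation of intensity, Shannon
   entropy of the 256-bin intensity histogram, high-hue ratio (HHR) and
   red pixel percentage (RPP).
4. **Classification** (`pallor_mlp()`). A single-hidden-layer perceptron
   (25 ReLU units, softmax output) on z-scored features.
5. **Mapping** (`aggregate_prevalence()`). Screening records carrying a
   geotag are binned into an equal-degree grid and cells with high anemic
   fraction are flagged for targeted follow-up.

## Numerical choices

**Color conversion.** sRGB is assumed (the de facto camera default) and
converted through linear RGB and XYZ with the D65 white point using the
canonical IEC 61966-2-1 constants. The conversion is implemented directly
rather than through `grDevices::convertColor`, whose sRGB gamut tables
give values that drift by ~0.25 `L*` units from the canonical pipeline;
the package's conversion reproduces the textbook value for pure red,
(53.24, 80.09, 67.20), to two decimals, and the tests hold it to ±0.1.

**HSI.** The arccos (Gonzalez–Woods) hue formulation, with
`I = (R+G+B)/(3·255)`, `S = 1 − 3·min/sum` and the convention `H = 0`
for achromatic pixels. Intensity and the grayscale used by the
statistical features are the same `(R+G+B)/3`, so the feature set is
internally consistent.

**K-means.** Lloyd iterations to an assignment fixed point (cap 300
sweeps), k-means++ initialization, emptied clusters re-seeded to the
farthest pixel. A single k-means++ draw occasionally converges to a
local optimum that splits the dominant background cluster instead of
isolating the (much smaller) conjunctiva cluster, so `kmeans_ab()` runs
`nstart = 5` seeded restarts and keeps the best objective — the standard
`stats::kmeans` remedy, kept fully deterministic by deriving restart
seeds from the user seed.

**Thresholds.** "High" hue means `H ≥ 300°` (the red–magenta band
adjoining the 0°/360° red axis); "red" pixels must dominate both other
channels by at least `δ = 20` 8-bit levels. Both are configurable; the
defaults were fixed once, from the colorimetric design of the generator
below, and are not tuned per dataset. Regions smaller than 50 pixels are
rejected rather than imputed.

**MLP.** Full-batch Adam (rate 0.01), cross-entropy loss, He
initialization from the user seed, iteration cap 1000 with a gradient
tolerance stop. Inputs are standardized by the training-set mean and
standard deviation stored in the fit. Prediction ties go to the
lexicographically first class. Evaluation reports *both* resubstitution
metrics (on training data — the optimistic convention) and held-out
metrics on a stratified 10% split; per-class training counts are
`round(0.9·n_c)`, which for the default 132/169/310 dataset gives exactly
550 training and 61 test images.

**Metrics.** Each class is reduced one-vs-rest to (TP, FP, TN, FN);
precision (= PPV), sensitivity, specificity, F1 and FDR follow the
standard formulas, macro values are unweighted class means, and ratios
with zero denominators are reported as `NaN` with a warning — never
silently as zero. One-vs-rest AUC uses the rank (Mann–Whitney)
formulation with half-credit for ties, which the tests verify against
trapezoidal integration of the empirical ROC.

## What the synthetic generator emulates

Real conjunctiva datasets are privacy-bound, so the package ships a
generator (`render_eye_image()`, `generate_dataset()`) whose defaults
define the reference evaluation conditions:

* 132 anemic / 169 moderate / 310 normal images (611 total), 256×256
  pixels, male fraction 24/54;
* Hb sampled uniformly within the class-and-sex gradation interval
  (anemic floor 6.0 g/dL; normal ceilings 17.5/15.5 g/dL for
  males/females), so `label_from_hb()` re-derives every label exactly;
* macro-style framing — a large pale sclera ellipse and a lower
  conjunctival crescent filling most of the frame, skin as a border —
  with per-image geometry jitter, per-pixel Gaussian channel noise
  (σ = 8), and a mild (±6%) vertical illumination gradient;
* six lighting conditions (tungsten, cloudy, daylight, flash,
  fluorescent, shade) as diagonal channel-gain presets, daylight being
  the identity; augmenting across all six takes 611 records to 3,666.

The class color means were calibrated once, in CIELAB, before any tests
existed, to satisfy two constraints simultaneously: (a) the conjunctiva
centroid keeps the maximum `a*` of the three regions under **all six**
lighting presets, so the reddest-cluster rule remains valid even for
pale anemic conjunctivae; and (b) the red-pixel percentage and high-hue
ratio decrease strictly from normal through moderate to anemic — the
qualitative pallor ordering the pipeline exists to detect. The defaults
are normal (190, 60, 70), moderate (195, 152, 155), anemic
(205, 172, 164), with skin (198, 192, 146) and sclera (222, 238, 252).
Note that a naive "very pale pink" anemic choice fails constraint (a):
its `a*` falls below the skin's, and the selection rule would return
skin. Conversely, making all three classes strongly red saturates RPP at
1.0 for every class and destroys ordering (b). The calibrated values sit
in the window where both hold with margin.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: specular highlights and eyelashes, motion blur,
vessel texture within the conjunctiva, anti-aliased region boundaries,
subject-level correlation (by default each image is an independent
"subject"; an `images_per_subject` option exists), non-diagonal
illuminant changes, and the continuous overlap of real class color
distributions. The synthetic classes are separable by design, so the
held-out macro F1 ≥ 0.9 achieved on the default dataset is a check that
the pipeline preserves and recovers class structure end to end — it is
not a claim about clinical accuracy, and no comparison with clinical
numbers is intended.

## Problem sizes used in the shipped checks

The test suite and the acceptance script regenerate everything from
seeds: the full 611-image dataset for the end-to-end recovery check,
60-image subsamples for segmentation recall, 1,000 random 16×16 fixtures
for the feature oracles, and ≤ 200-pixel images for the exhaustive
K-means oracle. These sizes were chosen to exercise every code path at
full default scale exactly once while keeping the whole suite
single-CPU-friendly.

## Known limitations

* The baseline ROI detector is a color prior, not a detector; on images
  whose background contains red objects it degenerates to (almost) the
  whole frame, and segmentation then relies entirely on the clustering.
* The reddest-cluster rule assumes the conjunctiva is the reddest large
  region in the ROI — true for everted-lid framing, not for arbitrary
  face photos.
* Equal-degree prevalence cells are not equal-area; at screening scale
  (city/district grids) the distortion is immaterial, but the cells
  should not be used for areal statistics at high latitudes.
* Resubstitution metrics are reported for comparability with common
  practice but are optimistically biased; decisions should rest on the
  co-reported held-out metrics.
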