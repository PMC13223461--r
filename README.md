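# pallor

Non-invasive anemia screening from eye-conjunctiva photographs.

Anemia — low blood hemoglobin (Hb) — presents clinically as pallor of the
palpebral conjunctiva, the vascular membrane lining the inner eyelid.
Because conjunctival color tracks Hb largely independently of skin tone,
a photograph of the everted lower lid carries usable screening signal.
`pallor` implements the full image-to-grading pipeline for people
building or evaluating such screeners: medical-imaging researchers,
mHealth engineers, and public-health teams who need prevalence maps from
field screenings.

## What the package computes

Given an 8-bit RGB eye image:

1. **ROI detection** — a redness-prior bounding box (CIELAB `a*` above
   the image's 80th percentile), standing in for any learned detector.
2. **Segmentation** — K-means (`k = 3`) on the per-pixel `(a*, b*)`
   chromaticity pairs; the cluster with maximum centroid `a*` (the
   reddest) is the conjunctiva. Externally produced masks (single-channel
   PNG) can be ingested instead.
3. **Features** — seven scalars on the segmented region:

   | feature | definition |
   |---|---|
   | mean intensity | mean of `(R+G+B)/3` |
   | R/G ratio | `mean(R) / mean(G)` |
   | R−G difference | `mean(R) − mean(G)` |
   | intensity SD | population standard deviation of `(R+G+B)/3` |
   | entropy | `−Σ pᵢ log₂ pᵢ` over the 256-bin intensity histogram |
   | high-hue ratio | fraction of pixels with HSI hue ≥ 300° |
   | red pixel % | fraction with `R − max(G, B) ≥ 20` and R dominant |

4. **Grading** — an MLP (one hidden layer of 25 ReLU units, softmax
   output) classifies the feature vector as **anemic** (Hb < 10.5 g/dL),
   **moderate** (10.5–13.5 g/dL male, 10.5–12 g/dL female) or **normal**,
   the Hb gradation being the gold standard (`label_from_hb()`).
5. **Mapping** — geotagged screening records aggregate into an
   equal-degree grid; cells with ≥ `min_n` records and anemic fraction ≥
   a threshold are flagged (`aggregate_prevalence()`, GeoJSON output).

A synthetic eye-image generator (`generate_dataset()`) with ground-truth
masks, the study class counts (132 anemic / 169 moderate / 310 normal =
611 images) and six lighting-condition presets (611 × 6 = 3,666 records)
makes every stage testable without any image downloads. See the methods
vignette (`vignettes/pallor-methods.Rmd`) for the model, its assumptions
and the design decisions.

## Worked example

```r
library(pallor)

spec <- synthetic_spec(n_per_class = c(anemic = 15L, moderate = 15L,
                                       normal = 15L))
man   <- generate_dataset(spec, dir = file.path(tempdir(), "demo"), seed = 42)
feats <- extract_dataset_features(man, k = 3, seed = 43)
mu <- aggregate(feats[, c("red_pixel_pct", "high_hue_ratio", "mean_intensity")],
                list(label = feats$label), mean)
mu[-1] <- round(mu[-1], 3)
mu
#>      label red_pixel_pct high_hue_ratio mean_intensity
#> 1   anemic         0.801          0.156        182.713
#> 2 moderate         0.952          0.549        171.995
#> 3   normal         1.000          0.807        109.328
```

The two redness features fall, and mean intensity rises, as pallor
deepens — the ordering the classifier exploits. Training and evaluating
with the stratified 90/10 split reports both resubstitution and held-out
metrics:

```r
ev <- evaluate_split(feats, seed = 44)
ev
#> Stratified split evaluation: 42 train / 3 test
#> -- resubstitution (training data) --
#> Classification metrics (n = 42)
#>   overall accuracy: 100.0%
#> ...
#> -- held-out 10% --
#> Classification metrics (n = 3)
#>   overall accuracy: 100.0%
#>   AUC: anemic=1.000 moderate=1.000 normal=1.000
```

Screening a single image end to end:

```r
fit <- pallor_mlp(label ~ . - image_path, feats, seed = 9)
r    <- render_eye_image("anemic", seed = 1234)
path <- file.path(tempdir(), "subject.png")
write_image(r$image, path)
out <- run_screening(path, fit, lat = 10.79, lon = 78.70,
                     record_id = "SCR-0001", seed = 2)
out$record
#>   record_id  label probability   lat  lon                timestamp
#> 1  SCR-0001 anemic    0.999974 10.79 78.7 2026-10-01T00:27:37+0000
```

The synthetic classes are separable by design; perfect small-sample
metrics here demonstrate that the pipeline preserves class structure,
not clinical performance (see the vignette's limitations section).

A thin CLI over the same functions ships in `inst/cli/pallor.R`
(`simulate`, `segment`, `features`, `train`, `evaluate`, `predict`,
`map`).

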