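# hueseg

Vegetation segmentation for RGB crop-field imagery by threshold detection
from hue histograms.

Precision-agriculture pipelines (weed mapping, crop-row detection, canopy
monitoring) start by splitting every pixel of a field image into
*vegetation* vs *background soil*. With low-cost RGB cameras — no NIR band —
the classical route is a color index (ExG, ExGR, NGRDI, CIVE, ...) plus Otsu
thresholding, which is fast but brittle under changing illumination because
the index values mix color with brightness. `hueseg` implements an
alternative that operates purely on the hue channel of HSV, where the color
of a surface is decoupled from how brightly it is lit.

## The method

1. **RGB → HSV.** Per pixel, with normalized channels R′ = R/255 (likewise
   G′, B′), M = max(R′,G′,B′), m = min, chroma C = M − m:

   - H = 60°·(((G′−B′)/C) mod 6) when M = R′, 60°·((B′−R′)/C + 2) when
     M = G′, 60°·((R′−G′)/C + 4) when M = B′, and 0 when C = 0;
   - S = C/M (0 when M = 0); V = M.

2. **Hue histogram.** 360 one-degree bins; bins holding fewer than 0.001 %
   of the image's pixels are removed as outlier colors.

3. **Gaussian model.** The filtered histogram is fitted by
   Levenberg–Marquardt least squares with a two-term peak model
   y = Σᵢ aᵢ·exp(−((x−bᵢ)/cᵢ)²) — one component per color class (soil,
   vegetation); an implausible second component is dropped.

4. **Five candidate thresholds.** The dominant class is soil when the
   dominant centroid is below 60° (green spans 60–180°), vegetation
   otherwise; the threshold is searched toward the other class. Candidates:
   - **th₁** — dominant centroid ± k·σ, with k the highest of {3, 2, 1}
     whose interval stays inside the distance S2 to the far end of the
     histogram support;
   - **th₂** — the valley of the fitted curve between the two peaks;
   - **th₃/th₄/th₅** — three local-minimum rules walked along the surviving
     histogram bins (valley lower than the next valley; valley followed by
     two rises; the smaller valley flanking a peak lower than its
     successor). Their stops are restricted to 30–70° and averaged.

5. **Final threshold & binarization.** The mean of the present candidates
   cuts the hue image into a 0/255 vegetation mask (vegetation capped at
   180°).

The package also ships the classical baselines (nine color indices + an
exact Otsu detector), a pixel-accuracy evaluator with IoU/precision/recall,
and a seeded synthetic field-scene generator with exact ground-truth masks
for benchmarking (soil hue ~ N(40°, 8°), vegetation ~ N(110°, 12°) by
default, with row/patch/scattered layouts and an illumination-gradient
control).

## Worked example

```r
library(hueseg)
scene <- generate_field(field_spec(height = 256, width = 256,
                                   veg_fraction = 0.3, seed = 42))
res <- segment_hue(scene$image)
res$report
#> <threshold_report: case3, dominant non_vegetation, search increasing_hue>
#>   th1=63.44 (k=3, S2=30.5)  th2=69.81  th3=N/A  th4=N/A  th5=N/A
#>   final threshold: 66.62 deg
pixel_accuracy(res$mask, scene$truth)
#> 99.97
pixel_accuracy(baseline_segment(scene$image, "ExG")$mask, scene$truth)
#> 88.89
```

Reading the report: soil dominates (dominant centroid ≈ 40° < 60°), so this
is a two-peak soil-dominant image (case 3) and the threshold is searched
toward higher hue. The 3σ confidence border of the soil peak (63.4°) and
the fitted inter-peak valley (69.8°) are present; the three histogram-valley
rules found no admissible stops on this smooth histogram. Their mean, 66.6°,
splits soil (~40°) from vegetation (~110°), giving 99.97 % pixel agreement
with the exact ground truth, versus 88.89 % for ExG + Otsu on the same
scene.

A shell entry point is installed with the package:

```sh
$(Rscript -e 'cat(system.file("cli", "hueseg", package = "hueseg"))') \
  simulate --output scenes --fractions 0.2,0.6 --seed 7
```

with `segment` and `evaluate` subcommands for batch runs.

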