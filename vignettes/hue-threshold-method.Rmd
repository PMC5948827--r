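---
title: "Hue-histogram threshold detection for vegetation segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hue-histogram threshold detection for vegetation segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hueseg)
```

## The segmentation problem and the model

An RGB image of a cropped field contains, to a first approximation, two
colors: green vegetation and yellow–brown soil. In HSV space those two
classes separate along the hue axis — soil hues cluster roughly between 20°
and 60°, plant greens between 60° and 180° — while saturation and value
absorb most of the illumination variation. `hueseg` therefore detects a
single global hue threshold per image and binarizes the hue plane with it.

The hue histogram (360 bins of 1°) is modeled as a sum of up to two
Gaussian-shaped peaks,

$$y(x) = \sum_{i=1}^{n} a_i \, e^{-\left(\frac{x - b_i}{c_i}\right)^2},
\qquad n \le 2,$$

one component per color class. Note the exponent carries no factor 2: under
this form the width parameter satisfies $c = \sqrt{2}\,\sigma$, and all
confidence-interval arithmetic uses $\sigma = c/\sqrt 2$. A config switch
(`gauss_half_exponent`) selects the conventional
$e^{-((x-b)/c)^2/2}$ form instead; the default is the literal model above.

The two-class assumption weakens at extreme growth stages — a bare field or
a closed canopy has essentially one hue mode — so the detector classifies
each image into four cases (one vs two peaks × soil- vs
vegetation-dominant) and only uses the rules that are defined for the case
at hand. The dominant class is read off the dominant fitted centroid with a
60° boundary (green starts at yellow ≈ 60°; the boundary itself counts as
vegetation), and the threshold search runs from the dominant mode *toward*
the other class: toward increasing hue when soil dominates, decreasing when
vegetation dominates.

## The five candidate thresholds

Two candidates come from the fitted curve:

* **th₁** (Gaussian border): `mean_dominant ± k·σ` along the search
  direction. `k` is the *highest allowable* multiple among {3, 2, 1}: a
  multiple is rejected unless `k·σ < S2`, where S2 is the distance from the
  dominant centroid to the end of the histogram support on the side
  *opposite* the search. The rationale is a symmetry check — if a k·σ
  interval does not fit inside the observed distribution on the quiet side,
  the Gaussian did not credibly fit the data. S2 from the histogram support
  is the default (`s2_mode = "histogram"`); a fitted-curve variant
  (centroid ± 3σ) is available because a fitted Gaussian has no finite end
  of its own.
* **th₂** (inter-peak valley): the minimum of the fitted curve between the
  two centroids, found by a 0.1° grid scan plus local refinement; defined
  only when two peaks exist and the second lies in the search direction.

Three more come from the filtered histogram itself, walked bin-by-bin from
the highest surviving bin (`main_hue`) in the search direction. Equal-count
plateaus are collapsed to their first bin; a collapsed run strictly below
both neighbors is a valley, strictly above a peak, so valleys and peaks
alternate:

* **th₃**: every valley whose count is lower than the *next* valley's is a
  stop.
* **th₄**: every valley followed immediately by two bins of strictly
  increasing counts is a stop (applied to the raw walk bins, so a plateau
  valley never qualifies).
* **th₅**: for every peak lower than the next peak, the smaller of its two
  flanking valleys is a stop (ties to the earlier valley; a peak missing a
  flanking valley contributes nothing).

Real hue histograms fluctuate, so each rule typically fires several times
along the walk. All qualifying stops are collected, stops outside the
admissible 30–70° window are discarded, and the survivors are averaged —
the window reflects the empirical observation that sub-30° and super-70°
local minima cut into one of the classes. The window applies to
th₃/th₄/th₅ only; `bounds_all_candidates = TRUE` extends it to th₁/th₂.

The final threshold is the unweighted mean of the present candidates; none
present is a detection failure (optionally replaced by Otsu on the hue
histogram via `fallback_otsu`). Binarization keeps threshold-equal pixels
with the dominant class and caps vegetation at 180° (`veg_hue_max`), so
magenta/red hues never count as vegetation. Achromatic pixels (C = 0) carry
hue 0 by the transform's convention and thus always fall on the
non-vegetation side — documented behavior, not an error.

## Fitting: initialization, restarts, and peak-count reduction

`fit_hue_gaussians()` runs Levenberg–Marquardt nonlinear least squares
(`minpack.lm::nlsLM`) on the surviving `(bin, count)` pairs. Starting
values: dominant centroid at the highest-count bin, second centroid at the
highest-count bin ≥ 30° away, amplitudes at those counts, widths 10°. If
the optimizer fails, up to `n_restarts = 5` jittered restarts are tried;
the jitter is drawn in a local RNG scope seeded from `fit_seed`, so a whole
run is bit-reproducible from its config. Amplitudes are bounded below by 0
and widths by 0.25° to keep the model identifiable on narrow histograms.

The fitted second component is discarded — and the model refitted with one
term — when any of these hold: amplitude below 5 % of the dominant one
(`amp_ratio_min`), centroid outside [0°, 360°), width above 120°
(`max_width`), or centroid separation below 20° (`min_separation`). The
first three screen out noise components; the separation rule is this
package's own addition, needed because a two-term fit of a genuinely
unimodal histogram often *splits* the peak into two overlapping components
of comparable amplitude that the amplitude screen alone would keep. Two
color classes 20° apart are not meaningfully separable by a 1°-binned hue
histogram in any case. If every fit attempt fails, the detector falls back
to raw-histogram peak picking with `converged = FALSE`.

## Tunables

| field | default | meaning |
|---|---|---|
| `filter_fraction` | 1e-5 | small-presence bin cutoff (fraction of pixels; strictly-below bins are removed) |
| `veg_boundary` | 60° | dominant-class boundary; ≥ 60° is vegetation |
| `veg_hue_max` | 180° | upper hue cap of the vegetation class |
| `sigma_multiples` | 3, 2, 1 | confidence multiples tried for th₁, highest first |
| `stop_bounds` | 30–70° | admissible window for th₃/th₄/th₅ stops |
| `s2_mode` | "histogram" | how the far support end for S2 is located |
| `n_restarts`, `fit_seed` | 5, 42 | fit restart policy (deterministic) |
| `amp_ratio_min`, `max_width`, `min_separation` | 0.05, 120°, 20° | second-component plausibility screens |
| `index_convention` | "chromatic" | channel scale for color indices (CIVE always raw) |
| `exr_coef` | 1.3 | red coefficient of ExR (1.4 circulates in the literature) |
| `index_polarity` | per index | which side of the Otsu cut is vegetation |

The 0.001 % filter cutoff is strikingly small (≈ 120 pixels on a 12 MP
frame); a 0.1 % reading is plausible but unverifiable, so the smaller value
is the default and `filter_fraction` is exposed.

Baseline notes: ExG/ExR/ExGR/NDI/NGRDI/VEG use chromatic coordinates
(r = R/(R+G+B), ...), the dominant convention in the index literature,
while CIVE uses raw 8-bit channels — its additive constant 18.78745
presumes them. NGRDI is (G−R)/(G+R) and VEG is g/(r^0.667·b^0.333), both
standard external definitions. COM1 is implemented as the plain sum
ExG + CIVE + ExGR + VEG and COM2 as 0.36·ExG + 0.47·CIVE + 0.17·VEG; in
both, the raw-scale CIVE term dominates numerically, so their default
polarity is vegetation-low, like CIVE's and ExR's. The Otsu detector
quantizes to 256 levels (360 for hue), maximizes between-class variance
exactly, and breaks ties toward the lowest level.

## The synthetic scene generator

Field images at the relevant scale are essentially two hue populations
arranged in rows, patches, or scattered plants. `generate_field()` draws a
vegetation support from the chosen layout, corrects it by seeded uniform
pixel flips to hit the requested vegetation fraction exactly, samples
per-pixel hue from the class distribution (soil N(40°, 8°), vegetation
N(110°, 12°) by default — soil mass left of 60°, vegetation mass inside
60–180°, matching the qualitative histograms of real canola/soybean/bean
fields), draws S and V uniformly (S ∈ [0.3, 0.9], V ∈ [0.3, 0.95]),
optionally multiplies both by a horizontal illumination ramp, and renders
to 8-bit RGB. Sampled hues are clipped, not wrapped, at [0°, 360°): the
class means sit far from the boundary, so the clipping bias is negligible.
The ground truth is recorded from the support before rendering and is
exact, so a perfect segmenter scores 100 %.

What the generator does *not* emulate: leaf-level texture and specular
highlights, cast shadows with penumbra, mixed soil types, sensor noise and
demosaicing artifacts, and blur from flight motion. Passing the synthetic
benchmark therefore demonstrates the method's decision logic and its
illumination invariance (hue is mathematically unchanged by the S/V ramp,
up to 8-bit re-quantization jitter), not field-grade accuracy on real UAV
frames. An `irrigated_field_spec()` preset pushes the soil hue mean to 65°,
past the class boundary — the regime (wet, dark organic soil) where
hue-based separation genuinely degrades and the dominant-class rule can
misclassify; it exists as a stress case, not part of the default
conditions.

## Numerical and degenerate-input choices

* Hue is stored in degrees [0, 360) as floating point and treated linearly
  (no circular statistics): both color classes live in [0°, 180°], far
  from the wrap point.
* 1° bins match the integer-degree precision at which hue thresholds are
  meaningfully reported; the bin label k covers [k, k+1).
* 16-bit inputs are rescaled to 8 bits on load (÷257, round); grayscale
  input is rejected; RGBA alpha is stripped by default.
* Valley/peak comparisons use strict inequality with ties resolved by
  walk order (first bin of a plateau run).
* A constant-hue image survives to the fitting stage with a single bin and
  fails there with a named error — callers (and the `segment` command) turn
  that into a nonzero exit, never a crash.
* Fewer than 3 surviving bins beyond `main_hue` yield empty valley/peak
  sequences, so th₃/th₄/th₅ are simply absent on tiny or one-sided
  histograms.

## Problem sizes used in the shipped checks

The test suite exercises the scalar-reference HSV equivalence at 10⁴ random
triples, Otsu against exhaustive search on 50 seeded random images, centroid
recovery on 50 seeded Poisson-noise bimodal histograms, the three stop rules
against brute-force enumeration on 100 seeded random histograms, and the
end-to-end pipeline on 512×512 scenes across vegetation fractions
0.1–0.9. The benchmark script crosses that growth series with two
illumination amplitudes (ten 512×512 scenes, five methods). These sizes
give stable statistics for every seeded property while keeping a full run
in the order of seconds.

## Known limitations

* One global threshold per image: spatially varying soil color or partial
  shadow is not handled by design.
* The 60° dominant-class rule misreads images whose soil is greenish (wet
  organic soil) or whose vegetation is yellowed; the irrigated preset
  reproduces this failure mode.
* Accuracy is overall pixel agreement, which is generous under heavy class
  imbalance; IoU, precision, and recall are emitted alongside it by
  `mask_metrics()` for that reason.
* No morphological post-processing is applied to masks; the raw threshold
  quality is what is measured.
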