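---
title: "Methods: automatic breast thermogram segmentation and asymmetry screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic breast thermogram segmentation and asymmetry screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermaseg)
```

## The screening problem

Malignant breast tissue and the angiogenesis that precedes it raise local
skin temperature. A radiometric infrared camera pointed at a seated,
thermally stabilized patient therefore carries diagnostic signal: if the
mean skin temperature of one breast exceeds the other by about 1 °C, the
asymmetry is suspicious. Turning that idea into an automatic tool requires
four steps, all implemented here:

1. **Background removal.** The patient is warmer (brighter) than the room,
   so a global Otsu threshold separates body from background.
2. **Breast segmentation.** The inframammary fold — the skin-on-skin crease
   under each breast — is among the hottest structures in the frame and
   marks the lower breast boundary; the armpit notch of the raised-arm
   silhouette marks the upper one.
3. **Evaluation.** Gray levels are mapped back to °C and the two breast
   regions compared by their mean temperature.
4. **Hotspot localization.** When the asymmetry rule fires, a watershed
   transform of the hotter breast's temperatures partitions it into warm
   basins and the basin holding the hottest pixel is reported, with shape
   descriptors that help an expert distinguish a compact (tumor-like) from
   an elongated (vessel-like) pattern. No diagnostic label is emitted.

## Models and procedures

### Temperature calibration

An 8-bit thermogram stores gray `Tgray` per pixel; the camera software
records the scene range `[Tmin, Tmax]`. The per-pixel temperature is the
affine map

```
Tr = Tmin + Tgray / Tvgm * (Tmax - Tmin)
```

where `Tvgm` is the maximum gray level *present in the image*, not 255.
This makes the calibration image-dependent (two images of the same scene
with different maxima decode differently); we keep the convention exactly
because downstream decisions (the 1 °C rule) were validated under it. The
hottest pixel always decodes to `Tmax`; a zero pixel decodes to `Tmin`.

### Otsu thresholding

`otsu_threshold()` maximizes the between-class variance
`σB²(t) = w1(μ1 − μT)² + w2(μ2 − μT)²` exhaustively over all 256 candidate
thresholds (class 1 is `gray ≤ t`). `σB²` is defined as 0 when a class is
empty, and ties take the lowest threshold — deterministic and, on two-level
images, yields the natural separation. The implementation is histogram-
cumulative; tests verify it against a literal subset-and-average loop.
The body is taken as the *bright* class (`gray > t*`); `invert = TRUE`
handles hot-dark palettes. Because contour tracing downstream needs a
simply-connected silhouette, the raw foreground is cleaned: the largest
connected component is kept and its holes filled. A known scale-bar
rectangle can be zeroed *before* thresholding (trimming-first; the
alternative order only matters when the bar dominates the histogram).

### Fold detection

Pixels within 10 gray levels of the within-body maximum (`fold_offset`,
the established heuristic value) isolate the hottest structures. Two
robustness measures are applied around this rule, which is itself kept
verbatim:

* a 3 × 3 **median filter** before thresholding. The rule anchors on the
  *sample* maximum, which pixel noise inflates by several gray levels; on
  noisy images the supra-threshold band otherwise fragments into 1–2 px
  specks and the component ranking below becomes meaningless;
* a one-pixel **closing** of the supra-threshold mask to heal single-pixel
  gaps.

The fold is the *thickest* supra-threshold object: connected components
are ranked by the maximum of the Euclidean distance transform in their
interior (area breaks ties), one winner per lateral half; components
spanning the midline are split at the highest point of their top profile
near the midline (the junction of the two fold arcs). The winner's
per-column topmost pixels are the ridge points.

### Fold completion and the split point

Each side's ridge points are fit (independently, ordinary least squares)
with `y = a0 + a1·x + a2·x²`. The real root of the difference polynomial
nearest the midline, inside the ridge x-range, is the **split point**
separating left from right; when no real root is in range the midline at
the mean fold height is used and the result flagged low-confidence.

### Armpit detection

The body contour is extracted as the morphological gradient (mask minus
erosion) and each lateral contour parameterized top-to-bottom as `x(y)`.
The slope is the two-point secant `(f(y+h) − f(y−h)) / 2h` with `h = 10`
px, clamped to forward/backward differences at the ends. The armpit score
is the same secant formula applied to the slope profile (a slope-change
gradient): on a pixelated contour this peaks at the kink, whereas the
difference of *successive* slopes smears a sharp kink into a ragged
plateau about `2h` wide and can misplace the point by up to `h` rows.
Residual quantization ties are broken at the centre of the tie plateau.
The search runs strictly above the fold intersection row; a straight
contour (no kink) yields a `low_confidence` flag.

### Region assembly and evaluation

Each breast region is bounded above by the straight segment from the
armpit point to the split point (extended horizontally lateral of the
armpit), below by the fold polynomial minus `fold_margin = 8` rows,
laterally by the body mask, and medially by the continuous vertical
through the split point (strict inequalities, so mirroring an image swaps
the outputs exactly). The fold margin is a deliberate choice: the fold
ridge is a skin-contact artifact present on both sides regardless of
pathology, and including its thermal halo would let it dominate the
per-side maximum and the hotspot search. Eight rows ≈ the ridge thermal
width at the default ridge sharpness.

Per-side statistics (mean, max, min, population SD — the population form
is an explicit convention, documented, and differs from the sample SD by
well under 0.01 °C at realistic region sizes) feed the decision rule

```
|avg_left − avg_right| ≥ delta_t   =>  "problem detected"
```

with `delta_t = 1.0` °C by default (the literature quotes suspicious
ranges of 1–2.5 °C; the threshold is configurable). The boundary case is
positive. Max/min/SD differences are reported but never drive the verdict.

### Watershed hotspot

The watershed operator floods a topographic relief from its regional
minima; since we seek hot *peaks*, flooding is applied to the additive
inverse of temperature so each peak becomes a basin (8-neighbour
connectivity). Peaks of prominence below `delta_min = 0.5` °C are merged
into their neighbours, which curbs noise-driven over-segmentation; basin
count is non-increasing in this depth. Watershed lines are derived
deterministically as the pixels with a 4-neighbour in a lower-numbered
basin, so lines and basins tile the masked region and every basin stays
connected. The **hotspot** is the basin containing the hottest labeled
pixel (deterministic and assertable, unlike "the visually most salient
region"). Its centroid is weighted by temperature elevation above the
basin's coolest pixel — offset-free, and it tracks the heat mass rather
than the basin outline, which matters when a smooth warm field makes the
whole breast one basin. Shape descriptors (area, best-fit-ellipse
eccentricity, elongation) come from the second moments of the basin
pixels with a 1/12 px² diagonal correction so 1-px-wide basins stay
finite.

## The phantom generator

`generate_phantom()` renders the image structure the algorithms consume —
not thermal physics (no bioheat model):

* a torso silhouette with raised arms: the lateral contour slants outward
  above the armpit row (`arm_slope` ≈ 1.2 px/row) and is near-vertical
  below it, producing the abrupt slope change the armpit detector looks
  for; background 24.04 °C, skin baseline 32.5 °C by default;
* one parabolic fold ridge per side, rendered as a Gaussian ridge of
  contrast `ridge_dt = 4` °C and vertical σ 3 px, composed with `pmax` —
  skin-contact temperature is a ceiling, identical on both sides, so the
  fold remains the hottest structure even in lesion phantoms (as observed
  clinically) and the "max − 10" threshold finds both folds;
* an optional lesion: a focal Gaussian peak of contrast `dt`
  (σ = radius/2) plus a broad hypervascular component (amplitude
  0.925 · dt, σ = 1.3 × breast radius), both centred at the lesion and
  truncated to the affected side. The lesion sits by default at the
  centroid of the ground-truth breast mask (hence off the fold, so fold
  detection and hotspot localization stay decoupled). With this geometry
  the affected breast's *mean* elevation is ≈ 0.8 · dt, consistent with
  the 1.8–1.9 °C mean asymmetries reported for detected cases at moderate
  contrasts; contrasts of 1.5 °C and above clear the 1 °C rule with
  margin;
* additive Gaussian noise (default σ = 0.1 °C, camera sensitivity scale);
* quantization to 8 bits using the rendered scene min/max as the sidecar
  calibration — phantoms are self-calibrating, and decoding recovers the
  rendered field to within half a gray step.

The ground-truth verdict is computed from the noiseless field over the
truth masks, not assumed from lesion presence. `phantom_sweep()` draws
anatomy (torso width 48–62 px, armpit rows 72–90, fold curvature
0.016–0.024 px⁻¹, skin 31.5–33.5 °C, noise 0.05–0.15 °C), gives half the
phantoms a lesion with contrast 1.5–3.0 °C and radius 7–12 px, runs the
full pipeline and tabulates a confusion table, per-side IoU against truth,
and hotspot hits.

**What passing phantom tests does and does not show.** The phantom
reproduces the *geometry and contrast structure* of a protocol-compliant
frontal thermogram; it does not reproduce inter-patient anatomical
variability beyond the randomized ranges, asymmetric healthy physiology,
motion, or out-of-protocol captures. Clinical sensitivity/specificity and
the published unknown rate are therefore not reproducible from phantoms;
the sweeps establish that the implementation recovers known ground truth
under the stated conditions, nothing more.

## Screening metrics

`screening_metrics()` excludes unknowns from every rate denominator — a
convention forced by the arithmetic of the published tables (e.g. a
sensitivity of 18/23 in a study with 42 sick cases) — and reports the
unknown rate separately. Printed rates are *truncated* to 4 decimals
(5/23 = 0.21739… prints as 0.2173), so the object carries full-precision
values (on which `tpr + fnr = 1` and `fpr + specificity = 1` hold exactly)
plus a `$rounded` list in the printing convention. The mean per-class
match is the unweighted mean of the two per-class match rates.

## Numerical and interface conventions

* Coordinates are 1-based: `x` = column, `y` = row, origin top-left;
  "above" = smaller row. Sides are the **patient's**: the right breast is
  on the viewer's left (smaller columns).
* Gray depth is fixed at L = 256; other depths are rescaled on load.
* The split point is kept continuous; side membership uses strict
  inequalities, making horizontal mirroring an exact symmetry of the
  pipeline.
* Degenerate inputs (constant images, empty masks, all-zero thermograms,
  too-short contours) raise classed conditions; the pipeline maps
  segmentation failures to the `"unknown"` outcome (exit code 3) rather
  than crashing.
* Problem sizes used by the validation suite: 100 random 16 × 16 images
  for the Otsu oracle check and Monte-Carlo sweeps of 200 phantoms at
  320 × 240 px — large enough that the binomial uncertainty on the
  reported rates is a few percent.
* `stabilization_time()` needs a stability criterion the source protocol
  only implies (it reports a 25-minute recommendation, not a rule): the
  package uses "every subsequent successive slope ≤ 0.05 °C/min", the
  camera-sensitivity scale per minute.

## Known limitations

* Frontal views only; semi-oblique captures have different geometry.
* The image-dependent `Tvgm` calibration propagates any bright artifact
  into the temperature scale; trim scale bars before conversion.
* The fold threshold assumes the inframammary fold is among the hottest
  structures; patients or palettes violating this produce the `unknown`
  outcome by design.
* JPEG input is not read directly; convert to PNG/TIFF or supply the
  temperature matrix as CSV.
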