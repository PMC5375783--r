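# thermaseg

Automatic analysis of frontal breast thermograms for asymmetry-based
screening.

Infrared thermography is a non-invasive, radiation-free adjunct to
mammography: malignant tissue and the angiogenesis that precedes it raise
local skin temperature, and a bilateral difference in mean breast
temperature of **1 °C or more** is a recognized warning sign. The hard part
of making this automatic is not the rule but the segmentation — finding the
breast regions in a thermogram with no manual markers. `thermaseg`
implements a fully automatic geometric pipeline for protocol-compliant
frontal captures (patient seated, hands at the nape, thermally
stabilized):

1. **Background removal** — Otsu's threshold, maximizing the between-class
   variance `σB²(t) = w1(μ1 − μT)² + w2(μ2 − μT)²` over all gray levels
   `t`; the body is the bright class, cleaned to a single filled
   silhouette. (Hamadani's `k1·μT + k2·σT` threshold is included as an
   alternative.)
2. **Breast segmentation** — the inframammary fold is isolated by
   thresholding at the within-body gray maximum minus 10, ranking the
   resulting components by their interior distance-transform maximum
   (thickness) per lateral half, and completing each fold with a quadratic
   `y = a0 + a1x + a2x²` fit to the ridge points. The folds' intersection
   splits left from right; the armpits are found as the point of sharpest
   slope change of the silhouette contour (two-point secant slopes,
   `h = 10` px). The region between armpit–split segments and the fold
   curves, inside the body, is the breast mask.
3. **Evaluation** — gray levels map to °C via
   `Tr = Tmin + Tgray/Tvgm · (Tmax − Tmin)` (scene range from the
   radiometric sidecar, `Tvgm` = maximum gray present); the verdict is
   `|avg_left − avg_right| ≥ 1 °C` → *problem detected*.
4. **Hotspot localization** — when the rule fires, the hotter breast is
   partitioned by a morphological watershed on inverted temperature
   (peak-prominence suppression 0.5 °C) and the basin holding the hottest
   pixel is reported with its centroid and shape descriptors
   (eccentricity, elongation) to help an expert distinguish compact from
   vessel-like warm patterns.

A synthetic **phantom generator** renders torso thermograms with ground
truth (silhouette, fold ridges, armpit notches, optional lesion with
stated contrast) so every stage — and the pipeline end to end — is
testable without patient data. Screening bookkeeping (confusion tables,
sensitivity/specificity/FPR/FNR over resolved cases, unknown rate) is
included.

Sides are named from the **patient's** anatomy: the right breast appears on
the viewer's left. Coordinates are 1-based, `x` = column, `y` = row.

## Worked example

Generate a phantom with a 2.2 °C lesion in the left breast and run the
full pipeline:

```r
library(thermaseg)

spec <- phantom_spec(seed = 3, lesion = list(side = "left", dt = 2.2, radius = 9))
ph <- generate_phantom(spec)
report <- analyze_thermogram(ph$thermogram)
report
```

```
<thermo_report> problem detected
<evaluation_result>
 Temperature  Left Right Difference
     Average 34.34 32.50       1.84
         Max 34.84 32.89       1.95
         Min 33.55 32.22       1.33
          SD  0.18  0.10       0.08
verdict: problem detected (|dT| = 1.84 degC, threshold 1.00), hotter side: left
<hotspot_result> basin 1 at (197.4, 130.1), 2690 px, mean 34.34 / max 34.84 degC
```

The per-side table mirrors the standard report format (°C, two decimals).
The 1.84 °C mean difference trips the 1 °C rule, so the left breast was
watershed-segmented; the hotspot centroid (197.4, 130.1) lies inside the
true lesion disk (the generator placed it at the breast centroid,
(197.8, 129.9)), and the basin's shape descriptors
(`report$pattern$eccentricity` = 0.74 for this breast-shaped basin)
quantify how compact or vessel-like the warm region is.

Screening arithmetic works directly on printed study tables:

```r
screening_metrics(confusion_table(healthy = c(17, 4, 16), sick = c(5, 18, 19)))
```

```
<screening_metrics> (rates over resolved cases, 4 decimals truncated)
  sensitivity (TPR) 0.7826   FNR 0.2173
  specificity       0.8095   FPR 0.1904
  per-class match: healthy 0.8095, sick 0.7826 (mean 0.79605)
  unknown rate: 44.3% of all cases
```

File-based use (and the equivalent CLI in `inst/cli/thermaseg.R`):

```r
run_pipeline("phantom.png", "phantom.yaml", out_dir = "out")
# out/report.json, out/stats.csv, mask PNGs; labels.png + overlay.png when
# a problem is detected. Exit-code convention: 0 healthy, 2 problem, 3 unknown.
```

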