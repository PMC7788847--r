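# calciquant

Quantification of calcinosis cutis (CC) lesions in 2D finger images.

Calcinosis cutis — deposition of insoluble calcium salts in skin and
subcutaneous tissue — is common in systemic sclerosis and most often affects
the fingers. Trials of CC treatments need a precise, reproducible measure of
lesion burden, but on bone-window CT reformats both bone and CC lesions are
calcium hydroxyapatite with essentially identical intensity, so lesions
cannot be isolated by thresholding; measurement is normally done by hand by
a musculoskeletal radiologist. `calciquant` is for researchers who want that
measurement automated and auditable: it segments the healthy phalanges with
a small trainable encoder–decoder network, subtracts them, delineates the
residual calcified lesions by seeded region growing, and reports per-lesion
areas in mm², alongside the radiologists' manual estimate which it emulates
from axis measurements.

## The method

For an image *I* with pixel spacing *s* (mm/px):

1. **Phalanx segmentation.** A U-shaped convolutional network (3×3
   convolutions + ReLU, 2×2 max pooling, nearest-neighbour upsampling with
   skip concatenations, sigmoid head; Adam, BCE + soft-Dice loss) predicts
   the bone mask *B*. A classical baseline (threshold → 8-connected
   components → size filter → hole fill) is provided for separable
   intensities, and segmentation quality is scored by the Dice coefficient
   2|A∩B|/(|A|+|B|).
2. **Visibility gate.** Images whose phalanges are incompletely visualized
   (fewer than the expected components, or any component touching the
   border) are flagged, excluded and counted — quantification applies only
   to complete fingers.
3. **Bone subtraction.** Pixels in *B* dilated by a 1-px margin are set to
   the background floor.
4. **Region growing.** Seeds are intensity local maxima above a threshold;
   a region admits an 8-connected neighbour whose intensity is within a
   tolerance of the running region mean. Each lesion's area is
   `pixel count × s²` (mm²).
5. **Ellipse estimate.** Per lesion, the maximal long axis *a* (maximum
   Feret diameter over pixel centers) and maximal perpendicular short axis
   *b* give the manual-style estimate `a/2 × b/2 × π`; the companion
   ellipsoid factor for three orthogonal diameters is `π/6 ≈ 0.52`.
6. **Method agreement.** Two paired area series are compared with
   Spearman's ρ, Lin's concordance correlation coefficient (population
   moments, Fisher-z 95% CI) and Bland-Altman bias with 95% limits of
   agreement `bias ± 1.96 × SD(diff)`.

A synthetic phantom generator (three capsule-shaped phalanges, 0–3
star-convex lesions adjacent to bone, additive Gaussian noise, pixel-exact
ground truth) makes the entire pipeline testable end to end; see the
methods vignette (`vignettes/calciquant-methods.Rmd`) for the model details
and design rationale.

## Worked example

```r
library(calciquant)

p <- generate_phantom(phantom_spec(seed = 7, n_lesions = 2))
p
#> <phantom_sample> 64 x 64 px @ 0.25 mm/px, 3 phalanges, 2 lesion(s)
#>   true lesion areas (mm^2): 1.125, 4.500

q <- quantify_image(p$image, p$bone_mask)   # ground-truth bone mask
round(as.data.frame(q)[, c("lesion_id", "pixel_count", "area_mm2",
                           "long_axis_mm", "short_axis_mm",
                           "ellipse_area_mm2")], 3)
#>   lesion_id pixel_count area_mm2 long_axis_mm short_axis_mm ellipse_area_mm2
#> 1         1          72    4.500        2.795         1.901            4.172
#> 2         2          18    1.125        1.118         1.118            0.982
```

Both lesions are recovered at their exact ground-truth areas (4.5 and
1.125 mm²); the ellipse estimates run slightly low because the lesions are
irregular, which is precisely the manual method's approximation. Comparing
the two estimators over many phantoms quantifies that agreement:

```r
meas <- do.call(rbind, lapply(1:40, function(s) {
  ph <- generate_phantom(phantom_spec(seed = s, n_lesions = 1 + s %% 3))
  as.data.frame(quantify_image(ph$image, ph$bone_mask))
}))
validate_agreement(paired_series(meas$area_mm2, meas$ellipse_area_mm2))
#> <agreement_result> n = 80 pairs
#>   Spearman rho 0.976 (p = 2.861e-53, t-approximation) [significant at 0.05]
#>   Lin's CCC 0.958 (95% CI 0.941-0.971)
#>   Bland-Altman (x-y) bias -0.071 mm^2, 95% LoA -0.879 to 0.737 mm^2
```

The trainable segmenter and the full study design (generate 40 phantoms,
split 30/10, rotation-augment ×3 to 120 training inputs, train, segment,
quantify, validate) run through one call:

```r
mf <- run_study(run_config(seed = 42), out_dir = "study")
report(mf)
```

which writes the datasets, model checkpoint, per-lesion CSV, agreement
plots and a checksummed `manifest.json` under `study/`. A thin CLI over the
same functions is in `inst/cli/calciquant.R`
(`Rscript inst/cli/calciquant.R run-study --out study --seed 42`).

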