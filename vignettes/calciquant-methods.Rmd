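---
title: "Quantifying calcinosis cutis in finger images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying calcinosis cutis in finger images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Calcinosis cutis (CC) — deposition of insoluble calcium salts in skin and
subcutaneous tissue — affects a large fraction of patients with systemic
sclerosis, most often in the fingers. Clinical trials of CC treatments need a
precise, reproducible measure of lesion burden, but manual measurement on
bone-window CT reformats is slow and rater-dependent, and is complicated by
the fact that bone and CC lesions are both calcium hydroxyapatite: they have
essentially the same image intensity, so a lesion cannot be isolated by
thresholding alone.

`calciquant` implements the computer-vision pipeline for this problem:

1. **Segment** the healthy phalanges with a small trainable encoder-decoder
   network (a U-shaped architecture with skip connections), or with a
   classical intensity baseline when intensities happen to be separable.
2. **Gate** on visibility: images in which the phalanges are incompletely
   visualized (clipped by the image border, or fewer components than
   expected) are flagged and excluded from quantification, and counted.
3. **Subtract** the segmented bone (with a safety margin) from the image.
4. **Delineate** residual bright lesions by seeded region growing and report
   each lesion's area in mm² as pixel count × spacing².
5. **Emulate the manual estimate**: measure each lesion's maximal long axis
   and maximal perpendicular short axis and form the elliptical area
   estimate long/2 × short/2 × π (with the companion ellipsoid volume
   factor π/6 ≈ 0.52 for three orthogonal diameters).
6. **Validate agreement** between two paired series of area measurements
   with Spearman correlation, Lin's concordance correlation coefficient
   (CCC) with 95% CI, and Bland-Altman bias with 95% limits of agreement.

Everything is exercisable end to end on synthetic phantoms with pixel-exact
ground truth, so the pipeline's accuracy claims are testable without any
patient data.

## The phantom generator

`phantom_spec()` / `generate_phantom()` emulate a sagittal bone-window
finger reformat:

* three bright elongated phalanges (capsule shapes) arranged end-to-end
  along the finger axis with joint gaps, with mild intra-bone texture;
* 0–3 irregular bright lesions, rasterized star-convex polygons whose radius
  jitter is controlled by `lesion_irregularity`;
* additive Gaussian noise applied to the image *after* the ground-truth
  masks are fixed, then rounding/clamping to integers in [0, 4095] so that a
  16-bit TIFF round trip is lossless.

Key default choices, made once as representative study conditions:

| parameter | default | rationale |
|---|---|---|
| raster | 64 × 64 px | smallest raster that holds 3 phalanges + lesions; keeps CPU training in minutes |
| `spacing` | 0.25 mm/px | typical high-resolution extremity CT reformat |
| `bone_intensity`, `lesion_intensity` | 800, 800 | *identical on purpose*: both phases are hydroxyapatite, so intensity alone cannot separate them and a shape-aware segmenter is genuinely required |
| `background_intensity` | 50 | soft tissue on a pseudo-HU scale |
| `noise_sd` | 30 | clearly visible noise, ~25× contrast-to-noise for mineralised tissue |
| `lesion_radius_range` | 0.5–1.5 mm | "clinically evident" lesser-finger lesions at this spacing (≈ 13–120 px) |

Geometric contracts enforced by construction (and asserted in tests): every
lesion is one 8-connected blob, disjoint from bone, separated from it by at
least one background pixel but within 2 px of it, and separated from other
lesions by at least 2 px. The one-pixel gap means a 1-px bone exclusion
margin downstream never erodes lesion pixels; the inter-lesion gap means
8-connected delineation can never merge two lesions. If a lesion cannot be
placed under these constraints after a bounded number of attempts,
generation fails loudly rather than silently degrading the ground truth.

Rotation augmentation (`rotate_augment()`) applies image and mask rotations
jointly — the only coherent reading for supervised segmentation. The default
three rotations are 90°/180°/270°: lossless on a square raster, so the
augmentation count law (30 → 120 inputs, 90 additional) and mask
disjointness stay exactly testable. Arbitrary angles with nearest-neighbour
resampling sit behind `method = "arbitrary"`.

`apply_window()` implements the radiology display mapping; the bone-window
defaults (window 1500, level 450) are also the network's input
normalization.

## The segmenter

`train_segmenter()` fits a small U-shaped fully convolutional network: per
level two 3×3 same convolutions with ReLU, 2×2 max pooling down, nearest-
neighbour upsampling with skip concatenation up, and a 1×1 sigmoid output
head. It is implemented directly on base-R matrix algebra (im2col gathers
feeding BLAS matrix products) with hand-derived backpropagation, verified
against finite differences, and optimised with Adam.

Defaults: depth 3, base 8 channels (8/16/32, bottleneck 64), learning rate
10⁻³, batch 8, 30 epochs, loss = binary cross-entropy + soft-Dice ("sum").
These are sized for 64×64 phantoms, where held-out Dice plateaus near 0.99
within ~30 epochs on one CPU core in a few minutes. On real full-resolution
images a much longer schedule (hundreds of epochs) would be the operative
setting; `train_config()` exposes it but does not default to it.

The epoch count is chosen by `epoch_sweep()`: train at each grid point and
recommend the smallest epoch count whose held-out Dice is within 0.005 of
the sweep maximum — an automated, reproducible stand-in for picking the
training length by visually inspecting segmentations between runs.
Validation images are a random `validation_fraction` (default 0.15) of the
supplied pairs, drawn from the config seed; with a degenerate split (no
validation images) the Dice is reported as unavailable rather than invented.

Reproducibility: all randomness (weight init, split, shuffling) flows from
`config$seed` through a private RNG stream; two runs with identical data,
config and BLAS give bit-identical weights. No global random state is
touched by any function in the package.

`classical_segment_bone()` (threshold → 8-connected components → size filter
→ hole filling) is the CPU-cheap baseline. On a noise-free phantom with
separable intensities it reproduces the ground-truth bone mask exactly,
which anchors the evaluation harness of the learned segmenter: `dice()` is
computed against ground truth the classical path can recover independently.

### Visibility gating

The method only applies when all phalanges are visible: `check_visibility()`
declares an image complete when the bone mask has at least
`expected_components` (default 3) 8-connected components and none touches
the border margin (default 1 px). `quantify_image()` refuses to measure
incomplete images and returns a failure marker instead; `run_study()` counts
these as "k of n images not amenable". The gate intentionally also catches
badly undertrained segmenters, whose ragged masks rarely pass.

## Lesion quantification

`subtract_bone()` replaces pixels inside the (dilated) bone mask with the
background floor. Whether the original method subtracted intensities or
excluded mask pixels is not observable from its description; mask exclusion
with a 1-px dilation margin was adopted because it makes the downstream
contract exact — the margin absorbs the partial-volume rim at the bone
boundary that would otherwise seed false lesions.

`region_grow()` is a standard seeded formulation chosen so that it reduces
to an exactly testable primitive:

* **candidates**: pixels ≥ `intensity_threshold` outside the excluded zone;
* **seeds**: intensity local maxima (ties allowed, so plateaus seed) among
  candidates, processed in descending intensity;
* **admission**: a neighbouring candidate joins when its intensity is within
  `tolerance` of the running region mean (updated incrementally);
* **connectivity** 8 (package-wide convention), `min_lesion_px` 3 to reject
  noise specks; claimed pixels are never re-used, so masks are disjoint.

With `tolerance = Inf` the admission rule vanishes and the procedure is
provably plain connected-component labelling of the thresholded raster —
the oracle equivalence the tests check exhaustively against an independent
union-find labeller. Output ordering (descending size, centroid tie-break)
is fixed so results are deterministic.

With the default phantom conditions the delineation is essentially exact:
lesion pixels are ~25 noise SDs above background, so the only error source
is the (rare) early rejection of a pixel while the region mean is still
dominated by the bright seed. Area-recovery tests therefore ask for ≤10%
per-lesion error (median <5%) on lesions of at least 20 px, leaving
headroom for single-pixel effects on small lesions.

`measure_axes()` defines the long axis as the maximum Feret diameter over
*pixel centers* and the short axis as the perpendicular projection extent —
distances between centers, not pixel footprints, because that definition is
unambiguous and checkable against an O(n²) brute-force oracle to exact
equality. Consequences accepted knowingly: a single-pixel lesion has axes
(0, 0) and collinear pixels have short axis 0; these are flagged
`degenerate` rather than floored. When several pixel pairs tie for the
maximal distance, the lexicographically smallest pair (by 0-based row, then
column) defines the direction, on both the implementation and oracle sides.
Internally the search runs on the convex hull of the pixel centers (the
maximal pair always lies on the hull), which keeps large lesions cheap
without changing any result.

The ellipse estimate long/2 × short/2 × π underestimates irregular
star-shaped lesions (their area is smaller than their caliper ellipse, but
pixel-center axes also shrink the caliper); for rasterized elliptical masks
it agrees with pixel-count area to within 15%.

## Agreement statistics

`spearman()` uses average ranks; the p-value follows the t approximation
t = ρ√((n−2)/(1−ρ²)) for n ≥ 10 (which covers the 31-pair validation
design) and the exact permutation distribution for n < 10, where the t
approximation is poor and full enumeration is cheap.

`lin_ccc()` uses population (1/n) moments, per Lin's original estimator —
stated explicitly because 1/(n−1) moments change the value at small n
(e.g. the 3-point worked example gives 4/7 with population moments). The
default 95% CI applies the Fisher z transform with Lin's asymptotic
variance; a percentile bootstrap is available behind `ci = "bootstrap"`
since the CI method behind reported intervals is often unstated. CCC is
always attenuated relative to |Pearson r| — an inequality the tests check
over a thousand random series.

`bland_altman()` reports bias = mean difference and limits bias ± 1.96 ×
sample SD of differences. The difference direction is a parameter
(`"x-y"` default, recorded in the output): published summaries sometimes
flip sign between abstract and results, so the convention is explicit here
rather than assumed.

`validate_agreement()` composes the three, flags Spearman significance at
p ≤ α (default 0.05), and emits the scatter-with-identity and Bland-Altman
plots plus a CSV of plot coordinates so that the numbers remain testable
without graphics.

## The end-to-end study harness

`run_study()` reproduces the full study design at phantom scale: generate
40 images (30 train / 10 test, each with 1–3 lesions), augment ×3 to 120
training inputs, train, segment and quantify the test set with visibility
gating, and run the agreement analysis. The two "raters" compared are the
two estimators the pipeline itself produces for every lesion — the
region-growing pixel-count area and the ellipse estimate from the measured
axes; an image-derived pair, not two copies of one number. All artifacts
(datasets, checkpoint, measurement CSV, run summary, plots) are written
under the output directory with MD5 checksums in `manifest.json`; every
stage's randomness derives from the master seed, and two runs with the same
config are bit-identical up to manifest timestamps.

Problem sizes used by the test-suite and the acceptance script — chosen as
the package's desk-scale study conditions: 64×64 phantoms; 120 augmented
training pairs, 30 epochs; 50 phantoms for area recovery; 1,000 random
32×32 rasters for the region-growing/labelling equivalence; 200 replicates
of 31 paired areas (uniform on 0.5–41.5 mm², rater noise SD 2 mm²) for the
concordance simulation. The 0.5–41.5 mm² range matches the clinical span of
reported lesion areas; noise SD 2 mm² expresses two raters who agree to
within a few mm² on that span, i.e. the high-concordance regime whose
qualitative pattern (CCC ≳ 0.95, bias near 0) the validation is meant to
detect.

## What passing tests do and do not show

The phantoms share the real task's *structure* — three elongated bones,
adjacent equal-intensity lesions, additive noise, occasional truncation —
but not its nuisance variability: no anatomy variation beyond simple shape
jitter, no soft-tissue gradients, no beam hardening or partial-volume blur,
no jpeg compression, single-channel pseudo-HU rather than dual-energy data.
A segmenter that reaches Dice ≈ 0.99 here shows the pipeline and its
training machinery are correct, not that this small network would segment
patient images at that level; the operative conclusion transferable to real
data is the shape of the pipeline and the exactness of the quantification
and agreement stages downstream of segmentation.

Other known limitations, by design: 2D areas only (no 3D volumes or density
statistics); no DICOM/PACS handling; no pretrained weights shipped;
the ellipsoid factor utility is provided for the clinical three-diameter
convention but the pipeline itself never estimates volumes.
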