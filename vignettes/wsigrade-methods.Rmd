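---
title: "Methods: quality control, appearance migration and patch-based grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quality control, appearance migration and patch-based grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wsigrade)
```

This vignette is the package's account of the models and procedures it
implements, the parameters that matter, and the choices made where the
design was genuinely open.

## The problem

Gleason grading classifies prostate cancer tissue into growth patterns of
increasing aggressiveness (GP3, GP4, GP5); the two area-dominant patterns on
a slide give the Gleason score (primary + secondary, 6–10) and its five-tier
Grade Group. Patch-based AI models learn this classification from
pathologists' polygon annotations, but three things stand between a trained
model and routine use: inconsistent scan quality, appearance differences
between scanner models, and the cost of producing and maintaining
annotations. `wsigrade` implements one desk-scale instrument for each, plus
the evaluation layer that scores the result, and a synthetic-fixture
generator that makes every claim testable without slide data.

## Synthetic fixtures: what they emulate, and what they do not

`generate_tissue_image()` lays out connected class regions on a block grid
(exact block counts by largest-remainder apportionment, chunks of 3–8 blocks
laid along a serpentine path so every region is connected) and renders a
procedural texture per class: ring/gland motifs for benign tissue, small
well-separated discs for GP3, fused irregular blobs for GP4, diffuse fine
speckle for GP5, and a smooth striated pink field for stroma. The textures
are designed to be *separable by a simple classifier*, not to be
histologically realistic; passing tests therefore demonstrate the pipeline's
mechanics (windowing, weighting, fusion, updating, evaluation), not clinical
performance on real H&E. No nuclear morphology, stain-unmixing physics or
pyramidal WSI structure is modelled.

Three rendering layers exist purely to make the images behave like scanner
output at the distribution level: a low-frequency stain-density field
(20 px cells, amplitude 14 intensity units) over all tissue, an illumination
field (32 px cells, amplitude 5), slight optical blur (0.7 px), and Gaussian
sensor noise (sd 8). Together they make per-channel tissue histograms
smooth and quasi-continuous; without them the procedural palette produces
spiky histograms no 8-bit distribution-matching method could align, which
would say nothing about real data.

Scanner styles are the per-channel transform
`v' = clip(gain * (v/255)^gamma * 255 + offset)`. The shipped presets make
two darker cohorts ("scannerB", "scannerC") and one lighter ("scannerD"),
and they are deliberately offset-dominated (gains within ~5% of 1, gamma
within 0.07 of 1): strong gain/gamma compression or highlight clipping
destroys intensity levels irreversibly in 8-bit data, and distribution
matching — the package's remedy — can only undo transforms that preserve the
level structure. Lightening is applied mostly as an offset with near-unity
gamma for the same reason: a large positive offset or gain would clip the
bright gland lumens inside tissue.

Partial annotations (`generate_annotation_set()`) trace connected
single-class regions by contour following (minimum region area 100 px to
avoid slivers) and keep a seeded subset whose area approximates the
requested completeness, emulating the non-exhaustive way pathologists
annotate.

## Quality control

Tiles (default 512 px; fixtures use 128 px) with tissue fraction ≤ 0.1 are
background and excluded. Five scores are computed per tile:

| score | definition | flag |
|---|---|---|
| focus | log10 variance of the 3×3 Laplacian of grayscale | `< focus_min` (0.9) |
| contrast | (P95 − P5)/255 of σ=2.5 low-passed grayscale tissue | `< contrast_min` (0.14) |
| saturation | clipped pixels (any channel ≥ 254, or all ≤ 2) over tissue ∪ clipped | `> saturation_max` (0.05) |
| artifact | tissue pixels outside the H&E hue envelope (hue ∈ [0.62, 1] ∪ [0, 0.10], or very dark) | `> artifact_max` (0.05) |
| uniformity | CV of 32 px-block grayscale variances | `< uniformity_min` (0.15) |

A tile is low quality when ≥ 2 flags are raised, and slides are summarized
by the low-quality percentage over tissue tiles. Three operator details are
worth recording. The contrast score is measured on a low-passed copy so it
captures the breadth of the intensity distribution rather than sharpness —
otherwise every out-of-focus tile also flags contrast and the two issues
become indistinguishable. The saturation denominator adds clipped pixels
back explicitly because clipped-white regions are indistinguishable from
slide background and would otherwise vanish from the tissue mask. All five
scores are invariant to 90° rotations and flips (for tile sides divisible by
32), and blurring a tile can only lower its focus score.

The thresholds above were calibrated once on a seeded 200-tile degradation
suite (`qc_fixture_suite()`) and then frozen; on independently seeded suites
every flag attains sensitivity and specificity ≥ 0.9. All thresholds are
overridable in code or YAML (`read_qc_config()`).

## Appearance migration

The reference is a per-channel 256-bin PDF averaged over the per-image
normalized tissue histograms of a reference cohort (per-image averaging, not
pooled pixels, so slides with unequal tissue areas contribute equally).
Migration builds, per channel, the monotone map
`T = invCDF_ref ∘ CDF_src` from the image's tissue pixels — both CDFs
continuity-corrected at bin midpoints, the inverse linearly interpolated,
ties resolved toward the lowest intensity — and applies it to *all* pixels
(leaving background unmapped would create visible seams). A constant source
channel maps to the reference median with a warning.

The tissue mask behind these statistics calls a pixel background when it is
bright *and* unsaturated; the brightness threshold is expressed relative to
the image's own white point (99th-percentile brightness, floored at an
absolute 180) so the mask is stable under the very scanner shifts migration
is meant to remove. Small specks are dropped and enclosed holes (gland
lumens) filled.

Two facts shape how migration quality is judged. First, an 8-bit image can
only be remapped bin-to-bin: wherever `T` locally expands or compresses the
intensity axis, the output histogram acquires a comb of gaps and doubled
bins worth a few percent of histogram intersection even for a perfect
transport. Second, those combs differ from slide to slide, so they average
out across a cohort. The package therefore reports and tests histogram
intersection at dataset level — reference-cohort PDF versus migrated-cohort
PDF — where intersections ≥ 0.95 are reached for every shipped style, while
per-slide intersection is asserted to strictly increase. Migration is
idempotent to within one intensity unit on channel means, and never touches
label rasters.

Whether source CDFs should be estimated per image or per dataset is not
fixed by the problem; per-image matching was chosen because it adapts to
slide-level staining variation and needs no batch bookkeeping. Its known
cost is a composition assumption: matching a slide whose tissue composition
differs grossly from the reference cohort's will recolor real differences,
which is why reference cohorts should be drawn from the same tissue type —
at desk scale, fixture cohorts share one layout specification.

## Patch pipeline and classifier

Windows of odd side `x` slide with stride `(x−1)/2` (overlap
`(x+1)/2x`); the study sides are 251/501/1001/2001 at 0.5 µm/pixel, resized
to 224 px — effective resolutions 0.56/1.12/2.23/4.47 µm/pixel by
`x·0.5/224` (the package reports the formula value 2.23 for side 1001). Test
fixtures use a custom 101 px side to keep slides small; nothing in the
geometry depends on the absolute scale. A window becomes a training patch
only when a *single* class covers more than 70% of it; windows that reach
70% only by mixing classes are ambiguous and yield nothing. Whether such
mixed windows should instead take a majority label is an open design point;
exclusion was chosen as the conservative reading. Resizing is exact area
averaging via bilinear interpolation of the integral image — deterministic
and alias-free in both integer and fractional ratios.

Augmentation offers the eight exact dihedral orientations (no interpolation)
and per-channel color jitter with gain ∈ [0.9, 1.1], offset ∈ [−20, 20],
gamma ∈ [0.9, 1.1]; the scanner presets shift these ranges dark (B, C) or
light (D). Class weights are inverse-frequency, normalized to mean 1 over
present classes; equal counts therefore reproduce unweighted training
exactly.

The baseline classifier is a fixed 40-dimensional feature map (8-bin
per-channel histograms, channel moments, Laplacian and gradient energy,
local-variance statistics, hue/saturation summaries, near-white and dark
fractions) with a ridge-penalized weighted multinomial-logistic head fit by
BFGS (`reltol 1e-14`, λ = 1e-3; the ridge makes the optimum unique). It
stands in for CNN backbones at desk scale; its macro-F1 on held-out fixture
patches is ≥ 0.8 by test, and an independent `nnet::multinom` fit on the
same features agrees with it. External models implementing `predict(...,
type = "prob")` drop in unchanged.

Incremental updating mirrors pathologist-AI interaction: corrections are
appended to a buffer and the *head only* is refit on the buffer with a
quadratic anchor (α = 5e-3) toward the base head, warm-started from the
current parameters. The refit is strictly convex, so two sequential updates
and one combined update converge to the same head (tested to 1e-6 on
probabilities), the original training patches are never needed, and an empty
update is a no-op.

## Inference, fusion and simplification

Every window inside the tissue bounding box with ≥ 50% tissue is scored
once; its probability vector is added to all of its pixels and its argmax
class receives one vote. Fusion takes, per pixel, the class with most votes
(`max_votes`) or the highest mean score (`max_mean_score`); ties break first
by higher mean score, then toward the more severe class
(GP5 > GP4 > GP3 > benign > stroma) — when in doubt, never the less severe
call. Pixels no window covers are "unscored" (code 0) and excluded from all
downstream metrics. Accumulation is unweighted across neighbors and
order-independent, and fusion is tested for exact equality against an
independent per-pixel gather recomputation.

For human review, `simplify_prediction()` alternates a majority smoothing
filter with absorption of regions below 100 px into their dominant neighbor
until nothing changes; running it to its fixed point makes the operation
idempotent by construction, and class areas move by less than 10%.

## Evaluation

Annotated instances are reconciled against the prediction raster by largest
pixel area (ties to the more severe class); instances more than half
unscored are excluded as a quality guard. Per-class precision/sensitivity/F1
are one-vs-rest with macro-F1 their arithmetic mean; binary metrics group
GP3/GP4/GP5 as Malignant versus benign/stroma. Slide-level grading takes the
malignant pattern with the largest predicted area as primary; the secondary
is the next pattern holding at least 5% of the malignant area (a common
clinical convention — the floor is configurable), else the primary doubles.
Score-to-group mapping: 6→GG1, 3+4→GG2, 4+3→GG3, 8→GG4, 9–10→GG5; no
malignant pixels means no group. Quadratic weighted kappa uses
`w_ij = (i−j)²/(k−1)²` on observed proportions versus the marginal product,
is computed over Grade Groups 1–5 (k = 5) with benign slides excluded
pairwise, and returns 1 for two identical constant raters (a 0/0 case the
formula leaves undefined). Timing summaries report means, fold speedup
(1 decimal) and percent reduction (integer), with a paired two-sided t-test
when the conditions pair up.

## Problem sizes and numerical choices

The shipped tests run the whole pipeline on seeded fixtures: 200-tile QC
suites at 128 px tiles; migration cohorts of 8 reference and 8 evaluation
slides at 384²; fusion-oracle checks on 20 random slides between 240² and
400² (plus one 1004² slide at the published 251 px scale); cross-scanner
consistency on 10 slides at 320²; and 1000 random vector pairs for the kappa
oracle. These sizes were chosen so each property is exercised well past its
edge cases while the full suite stays comfortable on a single CPU. All
randomness flows through explicit seeds; every generator restores the
caller's RNG state.

Known limitations, restated: procedural textures bound what fixture results
can say about clinical data; migration assumes comparable tissue composition
between an image and the reference cohort and cannot undo clipping; the
baseline classifier is not a CNN and its absolute accuracy on real H&E is
not a claim this package makes; and the exact rule by which a segmentation
becomes primary/secondary patterns in clinical systems varies — the 5% floor
is one defensible convention, exposed as a parameter.
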