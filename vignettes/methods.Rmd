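---
title: "Geometric and embedded features for photographic strabismus screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric and embedded features for photographic strabismus screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The screening problem

Strabismus screening from a single frontal photograph exploits two
geometric regularities of the orthotropic face: the irises sit symmetrically
between the medial and lateral canthi, and the corneal light reflex (CLR) of
a co-axial point light sits at the centre of each pupil (the Hirschberg
principle). Deep image embeddings capture texture and shape but are blind to
these *positional* cues, and with only tens of labelled images a classifier
cannot rediscover them; `strabscreen` therefore measures them explicitly and
fuses them with a low-dimensional embedding before classification.

## Pipeline and model

For each subject the pipeline runs:

1. **Eye-region extraction.** A landmark provider returns six landmarks per
   eye (medial canthus, lateral canthus, four eyelid points); the crop is
   the landmark bounding box expanded by a fractional margin (default 0.25,
   chosen so the full limbus is always inside the crop). Two providers
   ship: a ground-truth provider for synthetic scenes, and an
   intensity-contrast detector that finds the two dark iris groups and
   traces each eye opening along the iris-centre row. The detector assumes
   a luminance step between sclera and skin, which synthetic scenes
   guarantee; photographic images should wrap an external facial-landmark
   model as a provider function — the pipeline is agnostic to the source.
2. **Iris segmentation.** Two binary masks are intersected: Otsu's
   threshold on the grayscale crop (dark foreground), and an HSV
   value-channel band \[0, v\] with v the rounded mean gray of the crop.
   Their conjunction is robust to either method over-segmenting. Connected
   components below 1% of the crop area are discarded as eyelash/noise
   specks before limbus sampling.
3. **Pupil-centre estimation.** For every column touching the mask, the
   bottom-most foreground pixel is taken — the *lower* limbus arc, which the
   upper eyelid cannot occlude (we read the bottom-to-top scan this way;
   taking upper-arc points as well would break under ptosis and partial
   occlusion). A circle is fitted by the Kåsa algebraic least-squares
   method (closed form, deterministic); a geometric refinement minimising
   radial distances is available via `refine = TRUE` but is not the default,
   because the algebraic fit is already within 0.1 px of the geometric
   optimum at the noise levels relevant here.
4. **Position features.** `S = max(R1/R2, L1/L2) / min(R1/R2, L1/L2)` with
   Euclidean pupil-to-canthus distances (matching the drawn measurement
   segments; horizontal-only distances would ignore vertical deviations).
   Within each eye the first index is the medial canthus. The CLR ratio is
   `(D1 + D3)/(D2 + D4)`, with each medial limbus point one fitted radius
   from the pupil centre along the horizontal toward the nose; reflexes are
   detected by bright-polarity Otsu inside the fitted iris disc (shrunk to
   90% of the radius so limbus leakage is not mistaken for a reflex), and a
   detection must cover at least 2 px and at most 10% of the disc —
   anything larger is an occluding lid or the iris itself, not a specular
   dot. Reflex absence is a value, not an error.
5. **Missing-CLR imputation** happens inside each evaluation experiment,
   never globally: training images use their labels (0.468 — the midpoint
   of the 0.448–0.488 orthotropic reference band — if normal, 0 if
   strabismic); test images are label-free, receiving 0.468 when their
   `S` is at or below the criterion (the midpoint between the largest
   normal and the smallest strabismic training `S`) and 0 otherwise. We
   read "the median value between" two scalars as their midpoint, the only
   defensible interpretation.
6. **Fusion and classification.** Embeddings of an 84 × 84 bilinear resize
   of the two-eye crop are reduced to `k = 5` principal components — PCA is
   refitted on each experiment's 30 training embeddings so no test
   information leaks into the rotation. The fused vector
   `(pc1..pc5, S, clr)` is standardised with training means and population
   (1/n) standard deviations (the usual feature-scaling convention), and a
   linear SVM with `C = 1` is trained. Kernel and `C` are exposed; linear
   is the default because the few-shot regime (30 training points in 7
   dimensions) leaves no room to fit anything richer. A decision value of
   exactly zero is classified as strabismus — for a screening instrument
   the tie should favour sensitivity.

## Evaluation protocol

`evaluate_screening()` repeats: draw 15 training subjects per class without
replacement (the remaining 15 + 15 are the test set), run step 5–6, and
count the confusion. Per-experiment seeds are `base_seed + i - 1`, so any
single experiment is reproducible in isolation. Sensitivity is the fraction
of strabismic test images flagged, specificity the fraction of normal test
images cleared; with equal test class sizes, accuracy is exactly their
mean. The 95% confidence interval is the normal approximation
`mean ± 1.96·sd/√n` across experiments (zero-width for a single
experiment). The protocol default is 5,000 experiments; the package's tests
and acceptance script use 500 (and 200 per point on the deviation-gap
grid), which already pins the metric means to ±0.01 on the synthetic
cohorts.

## What the synthetic generator emulates — and what it does not

`make_eye_dataset()` renders, per scene, two eye-opening ellipses (semi-axes
45/320 of the width and 28/120 of the height, eyes centred at w/4 and 3w/4)
on skin, a dark iris disc per eye, an optional bright reflex dot, an
optional occluding upper lid, and additive Gaussian noise, with hard-edged
rasterisation so a pixel is foreground exactly when its centre falls in the
ideal disc — segmentation oracles are therefore exact, and anti-aliasing is
deliberately absent. Ground truth (canthi, pupil centres, radii, reflex
centres, label) describes the rendered geometry exactly.

The default conditions mirror a small screening study: 30 + 30 subjects,
with reflex-free scenes assignable as exact per-class counts (e.g. 8 of 30
normal and 13 of 30 strabismic). Normal scenes draw per-axis iris offsets
uniformly in ±2 px; strabismic scenes deviate one randomly chosen eye by
8–15 px, mostly horizontally (esotropia/exotropia dominate clinically),
with the reflex decentred opposite the deviation at 0.4 px per pixel of
deviation, a Hirschberg-like coupling. A scene is labelled strabismic when
its largest per-eye deviation exceeds 5 px. These choices make the classes
separable by construction — which is the point: the tests verify that the
*pipeline* recovers the geometry and that the *protocol* is leak-free and
calibrated, not that strabismus is easy. Passing them says nothing about
photographic skin/iris texture, illumination, head pose, eyelash clutter,
or detector robustness on real faces, none of which the renderer models.

A label-randomised control deserves a note: permuting 60 labels once leaves
chance feature–label correlations that *both* train and test splits inherit,
so a single permutation can sit several points from 0.5 on any cohort. The
null simulation therefore averages 10 seeded permutations × 50 experiments,
which centres on 0.5 as it should.

## Numerical choices and degenerate inputs

* Otsu ties resolve to the lowest threshold; a constant image is an error.
* Grayscale conversion uses BT.601 luma weights (0.299, 0.587, 0.114).
* The HSV upper bound is inclusive (`V ≤ v`), so a uniform crop is all
  foreground.
* Fewer than 3 limbus points, collinear points, or a non-positive fitted
  radius are errors, as are zero pupil-to-canthus distances in `S`.
* PCA component signs are fixed (largest-magnitude entry non-negative), so
  fits are bit-reproducible; `k` above the data rank is an error.
* Zero variance in any fused dimension aborts standardisation with the
  dimension named — on real cohorts this flags a degenerate feature (e.g.
  every CLR imputed to the same value) rather than silently dividing by 0.
* The Kaiser rule (`choose_k_by_eigenvalue()`) is a diagnostic on
  correlation-standardised features; the pipeline default stays `k = 5`.
  Applying eigenvalue-greater-than-1 to uncentred deep embeddings is
  statistically loose, which is why it is not on the default path.

## Known limitations

The intensity detector is not a face detector; real photographs need an
external landmark provider. The default embedding is a seeded random pixel
projection — deterministic and sufficient to exercise PCA, fusion and the
SVM, but carrying no learned invariances; a pretrained network can be
plugged in through `embedding_provider()` without touching anything
downstream. Ellipse-shaped eye openings and disc irises ignore corneal
curvature, so the CLR decentration model is linear rather than truly
Hirschberg-angular. The classifier consumes one embedding per subject (the
two-eye crop); concatenating per-eye embeddings is possible via a custom
provider but is not the default.

```{r example}
library(strabscreen)
cohort <- make_eye_dataset(30, 30, seed = 1,
                           reflex_missing_rate = c(8/30, 13/30))
features <- process_cohort(cohort)
ev <- evaluate_screening(features, n_experiments = 500, base_seed = 10001)
tidy(ev)
autoplot(ev)
```
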