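# strabscreen

Strabismus — misalignment of the eyes when fixating a target — is routinely
screened from frontal photographs: in a well-aligned (orthotropic) face the
two irises sit symmetrically between the eye corners, and the specular
reflection of a point light (the corneal light reflex, CLR) sits at the
centre of each pupil. `strabscreen` implements an automated photo-screening
pipeline for this task, aimed at settings where labelled clinical images are
scarce: it extracts per-eye regions around the canthus landmarks, segments
the iris, fits the limbus with a least-squares circle to estimate the pupil
centre, derives two geometric alignment features, fuses them with
PCA-reduced image embeddings, and classifies normal vs. strabismic with a
linear SVM under a repeated random-split protocol.

The two geometric features are:

* **Position-similarity ratio.** With `R1, R2` the Euclidean distances from
  the right pupil centre to the medial and lateral canthus and `L1, L2` the
  same for the left eye,

  ```
  S = max(R1/R2, L1/L2) / min(R1/R2, L1/L2)
  ```

  `S = 1` for symmetric eye positions and grows with ocular deviation.

* **CLR ratio.** With `D1, D3` the distances from each eye's reflex centre
  to its medial corneal limbus and `D2, D4` the iris diameters,

  ```
  CLR ratio = (D1 + D3) / (D2 + D4)
  ```

  which is exactly 0.5 for perfectly centred reflexes; the orthotropic
  reference band is 0.448–0.488 (midpoint 0.468). Images without a visible
  reflex are imputed: training images by their label (0.468 if normal, 0 if
  strabismic), test images label-free by comparing `S` with the midpoint
  between the largest normal and smallest strabismic training `S`.

The fused feature vector (5 PCA components of an image embedding, `S`, CLR
ratio) is standardised on training statistics and classified with a linear
SVM; performance is reported as mean accuracy, sensitivity and specificity
with 95% confidence intervals over repeated random 15/15-per-class splits.

Because clinical photographs cannot be redistributed, the package ships a
parametric synthetic eye-scene generator (`make_eye_dataset()`) with exact
ground-truth geometry — iris offsets, canthi, reflex positions, eyelid
occlusion, noise — so every stage of the pipeline is verifiable.

## Worked example

```r
library(strabscreen)

cohort <- make_eye_dataset(30, 30, seed = 1,
                           reflex_missing_rate = c(8/30, 13/30))
features <- process_cohort(cohort)
dplyr::select(features, subject_id, label, S, clr_measured)
#> # A tibble: 60 × 4
#>   subject_id label      S clr_measured
#>   <chr>      <chr>  <dbl>        <dbl>
#> 1 S001       normal  1.03       NA
#> 2 S002       normal  1.04       NA
#> 3 S003       normal  1.05        0.501
#> 4 S004       normal  1.01        0.499
#> # i 56 more rows

ev <- evaluate_screening(features, n_experiments = 500, base_seed = 10001)
ev
#> Screening evaluation: 500 experiments (base seed 10001, 15+15 split)
#>   accuracy    0.981 (95% CI 0.979-0.984)
#>   sensitivity 0.962 (95% CI 0.957-0.968)
#>   specificity 1.000 (95% CI 1.000-1.000)
```

Normal scenes sit at `S ≈ 1` with measured CLR ratios near 0.5 (`NA` marks
scenes rendered without a reflex, later imputed per experiment); strabismic
scenes separate clearly in both features, and the repeated-split SVM flags
96% of strabismic and clears 100% of normal test images on this synthetic
cohort. `tidy(ev)`, `glance(ev)` and `autoplot(ev)` give the per-metric
tibble, a one-row summary and a distribution plot;
`plot_position_features(features)` shows the `S`–CLR feature plane.

A thin command-line front end covers the same steps
(`inst/cli/strabscreen synth|extract|segment|features|evaluate`).

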