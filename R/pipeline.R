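## End-to-end orchestration: scene -> eye regions -> iris circles ->
## position features + CLR -> subject embedding. One row per subject.

resolve_provider <- function(landmark_provider, truth) {
  if (is.function(landmark_provider)) return(landmark_provider)
  switch(match.arg(landmark_provider, c("truth", "detector")),
         truth = truth_landmark_provider(truth),
         detector = intensity_landmark_provider())
}

## Crop spanning both eyes' landmarks (plus margin), resized and embedded.
subject_embedding <- function(face, regions, provider, margin = 0.25) {
  pts <- rbind(regions$right$landmarks, regions$left$landmarks)
  h <- dim(face)[1]
  w <- dim(face)[2]
  bx <- range(pts[, 1])
  by <- range(pts[, 2])
  x0 <- max(0, floor(bx[1] - margin * diff(bx)))
  x1 <- min(w - 1, ceiling(bx[2] + margin * diff(bx)))
  y0 <- max(0, floor(by[1] - margin * diff(by)))
  y1 <- min(h - 1, ceiling(by[2] + margin * diff(by)))
  crop <- face[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), , drop = FALSE]
  embed_image(resize_for_embedding(crop), provider)
}

canthi_from_regions <- function(regions) {
  list(medial_right = regions$right$canthus_medial,
       lateral_right = regions$right$canthus_lateral,
       medial_left = regions$left$canthus_medial,
       lateral_left = regions$left$canthus_lateral)
}

#' Run the image-processing pipeline over a cohort
#'
#' For each scene: extract both eye regions around their landmarks, segment
#' the iris and fit the limbus circle to estimate pupil centre and iris
#' radius, compute the position-similarity ratio S from the estimated
#' pupil centres and the provider's canthus landmarks, detect the corneal
#' light reflex and — when both eyes have one — the measured CLR ratio, and
#' embed a crop spanning both eyes (resized to 84 x 84) with the embedding
#' provider. Missing reflexes yield `clr_measured = NA`; imputation happens
#' later, inside each evaluation experiment, because the training rule
#' needs labels and the test rule needs a training-derived criterion.
#'
#' @param dataset Cohort tibble from [make_eye_dataset()] (columns `image`,
#'   `truth`, `label`, `subject_id`).
#' @param landmark_provider `"truth"` (ground-truth landmarks), `"detector"`
#'   (the intensity-contrast detector) or a provider function.
#' @param embedding_provider An [embedding_provider()].
#' @param margin Crop margin passed to [detect_and_extract()].
#' @param refine Use geometric refinement of the circle fit?
#' @return A tibble with one row per subject: estimated pupil centres and
#'   iris radii per eye, `R1`, `R2`, `L1`, `L2`, `S`, `clr_measured`
#'   (`NA` when either reflex is undetected), `clr_provenance`, and an
#'   `embedding` list-column.
#' @export
process_cohort <- function(dataset, landmark_provider = "truth",
                           embedding_provider = random_projection_provider(),
                           margin = 0.25, refine = FALSE) {
  rows <- lapply(seq_len(nrow(dataset)), function(i) {
    face <- dataset$image[[i]]
    provider <- resolve_provider(landmark_provider, dataset$truth[[i]])
    regions <- detect_and_extract(face, provider, margin = margin)
    circles <- lapply(regions, function(rg) {
      estimate_pupil_center(rg$crop, refine = refine)
    })
    pupil_face <- lapply(c(right = "right", left = "left"), function(side) {
      to_face_coords(regions[[side]], circles[[side]]$center)
    })
    ps <- position_similarity(pupil_face$right, pupil_face$left,
                              canthi_from_regions(regions))
    reflex <- lapply(c(right = "right", left = "left"), function(side) {
      detect_clr_center(regions[[side]]$crop, circles[[side]])
    })
    clr <- NA_real_
    if (!is.null(reflex$right) && !is.null(reflex$left)) {
      clr <- clr_ratio(reflex$right, reflex$left,
                       circles$right, circles$left)$ratio
    }
    emb <- subject_embedding(face, regions, embedding_provider, margin)
    dplyr::bind_cols(
      tibble::tibble(
        subject_id = dataset$subject_id[i], label = dataset$label[i],
        pupil_x_right = pupil_face$right[1], pupil_y_right = pupil_face$right[2],
        pupil_x_left = pupil_face$left[1], pupil_y_left = pupil_face$left[2],
        iris_radius_right = circles$right$radius,
        iris_radius_left = circles$left$radius
      ),
      ps,
      tibble::tibble(
        clr_measured = clr,
        clr_provenance = ifelse(is.na(clr), "missing", "measured"),
        embedding = list(emb)
      )
    )
  })
  dplyr::bind_rows(rows)
}

#' Features computed from ground-truth geometry
#'
#' The same per-subject feature table as [process_cohort()], but with S and
#' the CLR ratio computed directly from the generator's ground truth
#' (pupil centres, canthi, iris radii, reflex centres) instead of from
#' image estimates. Embeddings still come from the rendered images so the
#' table can drive [evaluate_screening()]. Used to isolate the error
#' contributed by segmentation and circle fitting.
#'
#' @inheritParams process_cohort
#' @return A tibble with the same columns as [process_cohort()].
#' @export
truth_features <- function(dataset,
                           embedding_provider = random_projection_provider(),
                           margin = 0.25) {
  rows <- lapply(seq_len(nrow(dataset)), function(i) {
    tr <- dataset$truth[[i]]
    canthi <- list(medial_right = tr$canthus_medial_right,
                   lateral_right = tr$canthus_lateral_right,
                   medial_left = tr$canthus_medial_left,
                   lateral_left = tr$canthus_lateral_left)
    ps <- position_similarity(tr$pupil_center_right, tr$pupil_center_left,
                              canthi)
    clr <- NA_real_
    if (!is.null(tr$reflex_center_right) && !is.null(tr$reflex_center_left)) {
      cir_r <- list(center = tr$pupil_center_right, radius = tr$iris_radius_right)
      cir_l <- list(center = tr$pupil_center_left, radius = tr$iris_radius_left)
      clr <- clr_ratio(tr$reflex_center_right, tr$reflex_center_left,
                       cir_r, cir_l)$ratio
    }
    face <- dataset$image[[i]]
    provider <- truth_landmark_provider(tr)
    regions <- detect_and_extract(face, provider, margin = margin)
    emb <- subject_embedding(face, regions, embedding_provider, margin)
    dplyr::bind_cols(
      tibble::tibble(
        subject_id = dataset$subject_id[i], label = dataset$label[i],
        pupil_x_right = tr$pupil_center_right[1],
        pupil_y_right = tr$pupil_center_right[2],
        pupil_x_left = tr$pupil_center_left[1],
        pupil_y_left = tr$pupil_center_left[2],
        iris_radius_right = tr$iris_radius_right,
        iris_radius_left = tr$iris_radius_left
      ),
      ps,
      tibble::tibble(
        clr_measured = clr,
        clr_provenance = ifelse(is.na(clr), "missing", "measured"),
        embedding = list(emb)
      )
    )
  })
  dplyr::bind_rows(rows)
}
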