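## Parametric renderer for two-eye scenes with exact ground-truth geometry.
##
## The renderer draws, on a skin-coloured canvas, one ellipse (the eye
## opening, filled with sclera) per eye, a dark iris disc whose centre may be
## offset from the eye's geometric rest position (the mid-canthus point), an
## optional bright specular reflex dot inside the iris, and an optional
## eyelid band occluding the upper limbus. Rasterisation is hard-edged (no
## anti-aliasing) so segmentation oracles are exact: a pixel belongs to a
## disc iff its centre lies inside the ideal circle.
##
## Fixed geometry constants (relative to the image size):
##   * eye rest centres: (w/4, h/2) for the subject's right eye (image left)
##     and (3w/4, h/2) for the left eye;
##   * eye-opening ellipse semi-axes: a = 45/320 * w, b = 28/120 * h;
##   * canthi at the ellipse's horizontal extremes; four further eyelid
##     landmarks at x = cx +/- a/2 on the ellipse boundary.

EYE_A_FRAC <- 45 / 320
EYE_B_FRAC <- 28 / 120

#' Specify a synthetic two-eye scene
#'
#' Builds a validated scene specification for [render_eye_pair()]. All
#' lengths are in pixels and intensities on the 0-255 gray scale. Offsets are
#' `(dx, dy)` with x rightward and y downward; iris offsets are relative to
#' each eye's rest position (its mid-canthus point), reflex offsets relative
#' to the iris centre.
#'
#' @param image_width,image_height Canvas size in pixels.
#' @param iris_radius Iris radius in pixels.
#' @param iris_center_offset_right,iris_center_offset_left `(dx, dy)` iris
#'   deviation of the subject's right / left eye.
#' @param reflex_present_right,reflex_present_left Draw the corneal light
#'   reflex dot in that eye?
#' @param reflex_offset_right,reflex_offset_left `(dx, dy)` reflex position
#'   relative to the iris centre.
#' @param reflex_radius Reflex dot radius in pixels.
#' @param eyelid_occlusion_fraction Fraction of the iris height covered by
#'   the upper eyelid, in `[0, 0.5]`.
#' @param intensity_skin,intensity_sclera,intensity_iris,intensity_reflex
#'   Gray levels; must satisfy `iris < sclera <= skin < reflex`.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise
#'   (gray levels); 0 for a noiseless scene.
#' @param deviation_threshold Deviation magnitude (pixels) above which the
#'   scene is labelled `"strabismus"`; at or below it, `"normal"`.
#' @param seed Integer seed making the rendering (noise included) a pure
#'   function of the spec.
#'
#' @return An object of class `eye_scene_spec`.
#' @export
#' @examples
#' spec <- eye_scene_spec(iris_center_offset_right = c(10, 0))
#' scene <- render_eye_pair(spec)
#' scene$truth$label
eye_scene_spec <- function(image_width = 320,
                           image_height = 120,
                           iris_radius = 20,
                           iris_center_offset_right = c(0, 0),
                           iris_center_offset_left = c(0, 0),
                           reflex_present_right = TRUE,
                           reflex_present_left = TRUE,
                           reflex_offset_right = c(0, 0),
                           reflex_offset_left = c(0, 0),
                           reflex_radius = 2,
                           eyelid_occlusion_fraction = 0,
                           intensity_skin = 220,
                           intensity_sclera = 200,
                           intensity_iris = 40,
                           intensity_reflex = 255,
                           noise_sd = 0,
                           deviation_threshold = 5,
                           seed = 1L) {
  spec <- structure(
    list(
      image_width = image_width, image_height = image_height,
      iris_radius = iris_radius,
      iris_center_offset_right = as.numeric(iris_center_offset_right),
      iris_center_offset_left = as.numeric(iris_center_offset_left),
      reflex_present_right = isTRUE(reflex_present_right),
      reflex_present_left = isTRUE(reflex_present_left),
      reflex_offset_right = as.numeric(reflex_offset_right),
      reflex_offset_left = as.numeric(reflex_offset_left),
      reflex_radius = reflex_radius,
      eyelid_occlusion_fraction = eyelid_occlusion_fraction,
      intensity_skin = intensity_skin, intensity_sclera = intensity_sclera,
      intensity_iris = intensity_iris, intensity_reflex = intensity_reflex,
      noise_sd = noise_sd,
      deviation_threshold = deviation_threshold,
      seed = as.integer(seed)
    ),
    class = "eye_scene_spec"
  )
  validate_eye_scene_spec(spec)
  spec
}

validate_eye_scene_spec <- function(spec) {
  with(spec, {
    if (image_width < 40 || image_height < 20) {
      stop("scene too small to hold two eye regions", call. = FALSE)
    }
    if (!(intensity_iris < intensity_sclera &&
          intensity_sclera <= intensity_skin &&
          intensity_skin < intensity_reflex)) {
      stop("intensity ordering violated: need iris < sclera <= skin < reflex",
           call. = FALSE)
    }
    if (eyelid_occlusion_fraction < 0 || eyelid_occlusion_fraction > 0.5) {
      stop("eyelid_occlusion_fraction must lie in [0, 0.5]", call. = FALSE)
    }
    if (iris_radius <= 0 || reflex_radius <= 0) {
      stop("radii must be positive", call. = FALSE)
    }
    if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  })
  geom <- eye_geometry(spec$image_width, spec$image_height)
  for (side in c("right", "left")) {
    off <- spec[[paste0("iris_center_offset_", side)]]
    stopifnot_point(off, paste0("iris_center_offset_", side))
    ## iris disc must lie fully inside the eye-opening ellipse
    th <- seq(0, 2 * pi, length.out = 361)
    px <- off[1] + spec$iris_radius * cos(th)
    py <- off[2] + spec$iris_radius * sin(th)
    if (any((px / geom$a)^2 + (py / geom$b)^2 > 1 + 1e-9)) {
      stop(sprintf("iris of the %s eye (offset %g, %g; radius %g) leaves its eye region",
                   side, off[1], off[2], spec$iris_radius), call. = FALSE)
    }
    if (spec[[paste0("reflex_present_", side)]]) {
      roff <- spec[[paste0("reflex_offset_", side)]]
      stopifnot_point(roff, paste0("reflex_offset_", side))
      if (sqrt(sum(roff^2)) + spec$reflex_radius > spec$iris_radius + 1e-9) {
        stop(sprintf("reflex of the %s eye lies outside the iris disc", side),
             call. = FALSE)
      }
    }
  }
  invisible(spec)
}

## Fixed renderer geometry for a w x h canvas: eye centres, ellipse
## semi-axes, canthus and eyelid landmark positions (0-based coordinates).
eye_geometry <- function(w, h) {
  a <- EYE_A_FRAC * w
  b <- EYE_B_FRAC * h
  cy <- (h - 1) / 2
  cx_right <- (w - 1) / 4       # subject's right eye: image-left half
  cx_left <- 3 * (w - 1) / 4
  lid_dy <- b * sqrt(3) / 2
  landmarks_for <- function(cx, medial_sign) {
    list(
      canthus_medial = c(cx + medial_sign * a, cy),
      canthus_lateral = c(cx - medial_sign * a, cy),
      lids = rbind(
        c(cx - a / 2, cy - lid_dy), c(cx + a / 2, cy - lid_dy),
        c(cx - a / 2, cy + lid_dy), c(cx + a / 2, cy + lid_dy)
      )
    )
  }
  list(
    a = a, b = b, cy = cy,
    center_right = c(cx_right, cy), center_left = c(cx_left, cy),
    right = landmarks_for(cx_right, +1),   # medial (nasal) is +x for the right eye
    left = landmarks_for(cx_left, -1)
  )
}

#' Render a synthetic eye pair with its ground truth
#'
#' Deterministically rasterises the scene described by an [eye_scene_spec()]
#' and returns the RGB image together with the exact geometry it encodes.
#'
#' @param spec An [eye_scene_spec()].
#' @return A list with `image` (h x w x 3 array, 0-255) and `truth`, a list
#'   of class `eye_truth` holding canthus landmarks, pupil centres, iris
#'   radii, reflex centres (`NULL` when absent) and the scene `label`
#'   (`"normal"` or `"strabismus"` by the spec's `deviation_threshold`).
#' @export
render_eye_pair <- function(spec) {
  if (!inherits(spec, "eye_scene_spec")) {
    stop("spec must be an eye_scene_spec", call. = FALSE)
  }
  validate_eye_scene_spec(spec)
  w <- spec$image_width
  h <- spec$image_height
  geom <- eye_geometry(w, h)
  g <- pixel_grid(h, w)
  canvas <- matrix(spec$intensity_skin, nrow = h, ncol = w)

  truth <- list(label = NULL)
  for (side in c("right", "left")) {
    ec <- geom[[paste0("center_", side)]]
    off <- spec[[paste0("iris_center_offset_", side)]]
    ic <- ec + off
    ell <- ((g$X - ec[1]) / geom$a)^2 + ((g$Y - ec[2]) / geom$b)^2 <= 1
    canvas[ell] <- spec$intensity_sclera
    iris <- (g$X - ic[1])^2 + (g$Y - ic[2])^2 <= spec$iris_radius^2
    canvas[iris] <- spec$intensity_iris
    rc <- NULL
    if (spec[[paste0("reflex_present_", side)]]) {
      rc <- ic + spec[[paste0("reflex_offset_", side)]]
      dot <- (g$X - rc[1])^2 + (g$Y - rc[2])^2 <= spec$reflex_radius^2
      canvas[dot] <- spec$intensity_reflex
    }
    if (spec$eyelid_occlusion_fraction > 0) {
      lid_y <- ic[2] - spec$iris_radius +
        spec$eyelid_occlusion_fraction * 2 * spec$iris_radius
      canvas[ell & g$Y < lid_y] <- spec$intensity_skin
    }
    truth[[paste0("canthus_medial_", side)]] <- geom[[side]]$canthus_medial
    truth[[paste0("canthus_lateral_", side)]] <- geom[[side]]$canthus_lateral
    truth[[paste0("pupil_center_", side)]] <- ic
    truth[[paste0("iris_radius_", side)]] <- spec$iris_radius
    truth[[paste0("reflex_center_", side)]] <- rc
  }
  dev <- max(sqrt(sum(spec$iris_center_offset_right^2)),
             sqrt(sum(spec$iris_center_offset_left^2)))
  truth$label <- if (dev > spec$deviation_threshold) "strabismus" else "normal"
  truth$deviation <- dev
  class(truth) <- "eye_truth"

  canvas <- withr::with_seed(spec$seed, {
    if (spec$noise_sd > 0) {
      clamp(canvas + matrix(rnorm(h * w, 0, spec$noise_sd), h, w), 0, 255)
    } else {
      canvas
    }
  })
  list(image = gray_to_rgb(canvas), truth = truth)
}

#' Generate a labelled synthetic cohort
#'
#' Draws `n_normal` near-orthotropic and `n_strab` deviated scenes.
#' Normal scenes receive small independent per-axis iris offsets in
#' `[-normal_jitter, normal_jitter]`; strabismic scenes deviate one randomly
#' chosen eye by a magnitude drawn from `deviation_range` (mostly
#' horizontal, with a small vertical component), with the reflex dot
#' decentred against the deviation (Hirschberg principle, factor
#' `reflex_decenter_factor`). Missing corneal reflexes are assigned to an
#' exact per-class count of `round(rate * n)` subjects (both eyes), so a
#' cohort composition such as 8/30 normal and 13/30 strabismic
#' reflex-free scenes is reproduced exactly.
#'
#' @param n_normal,n_strab Subjects per class.
#' @param seed Integer seed; the cohort is a pure function of the arguments.
#' @param deviation_range Length-2 range (pixels) for strabismic deviation
#'   magnitudes.
#' @param reflex_missing_rate Probability that a subject's scene lacks the
#'   reflex dot; scalar, or length 2 as `c(normal, strabismic)`.
#' @param noise_sd,eyelid_occlusion_fraction,deviation_threshold Passed to
#'   every [eye_scene_spec()].
#' @param normal_jitter Half-width (pixels) of the per-axis offset jitter of
#'   normal scenes; must stay below `deviation_threshold / sqrt(2)`.
#' @param reflex_decenter_factor Reflex displacement per pixel of deviation.
#' @param ... Further arguments forwarded to [eye_scene_spec()]
#'   (e.g. `image_width`, `iris_radius`).
#'
#' @return A tibble with one row per scene: `subject_id`, `label`,
#'   `image` (list of RGB arrays) and `truth` (list of `eye_truth`).
#' @export
make_eye_dataset <- function(n_normal = 30, n_strab = 30, seed = 1L,
                             deviation_range = c(8, 15),
                             reflex_missing_rate = 0,
                             noise_sd = 0,
                             eyelid_occlusion_fraction = 0,
                             deviation_threshold = 5,
                             normal_jitter = 2,
                             reflex_decenter_factor = 0.4,
                             ...) {
  stopifnot(n_normal >= 0, n_strab >= 0,
            length(deviation_range) == 2, deviation_range[1] <= deviation_range[2])
  if (min(deviation_range) <= deviation_threshold) {
    stop("deviation_range must lie above deviation_threshold so labels are consistent",
         call. = FALSE)
  }
  if (normal_jitter * sqrt(2) > deviation_threshold) {
    stop("normal_jitter too large for deviation_threshold", call. = FALSE)
  }
  rate <- rep_len(as.numeric(reflex_missing_rate), 2L)
  if (any(rate < 0 | rate > 1)) stop("reflex_missing_rate must be in [0, 1]", call. = FALSE)
  n <- n_normal + n_strab
  labels <- rep(c("normal", "strabismus"), c(n_normal, n_strab))

  specs <- withr::with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
    missing_id <- c(
      sample(which(labels == "normal"), round(rate[1] * n_normal)),
      sample(which(labels == "strabismus"), round(rate[2] * n_strab))
    )
    lapply(seq_len(n), function(i) {
      off <- list(right = runif(2, -normal_jitter, normal_jitter),
                  left = runif(2, -normal_jitter, normal_jitter))
      refl <- list(right = c(0, 0), left = c(0, 0))
      if (labels[i] == "strabismus") {
        eye <- sample(c("right", "left"), 1)
        mag <- runif(1, deviation_range[1], deviation_range[2])
        dy <- runif(1, -0.25, 0.25) * mag
        dx <- sample(c(-1, 1), 1) * sqrt(mag^2 - dy^2)
        off[[eye]] <- c(dx, dy)
        refl[[eye]] <- -reflex_decenter_factor * off[[eye]]
      }
      present <- !(i %in% missing_id)
      eye_scene_spec(
        iris_center_offset_right = off$right,
        iris_center_offset_left = off$left,
        reflex_present_right = present, reflex_present_left = present,
        reflex_offset_right = refl$right, reflex_offset_left = refl$left,
        noise_sd = noise_sd,
        eyelid_occlusion_fraction = eyelid_occlusion_fraction,
        deviation_threshold = deviation_threshold,
        seed = sub_seeds[i],
        ...
      )
    })
  })
  scenes <- lapply(specs, render_eye_pair)
  tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    label = vapply(scenes, function(s) s$truth$label, character(1)),
    image = lapply(scenes, `[[`, "image"),
    truth = lapply(scenes, `[[`, "truth"),
    spec = specs
  )
}

## Flatten an eye_truth into a one-row data frame (NA for absent reflexes).
truth_to_row <- function(truth) {
  pt <- function(p) if (is.null(p)) c(NA_real_, NA_real_) else p
  out <- list(label = truth$label)
  for (side in c("right", "left")) {
    for (f in c("canthus_medial", "canthus_lateral", "pupil_center", "reflex_center")) {
      p <- pt(truth[[paste0(f, "_", side)]])
      out[[paste0(f, "_", side, "_x")]] <- p[1]
      out[[paste0(f, "_", side, "_y")]] <- p[2]
    }
    out[[paste0("iris_radius_", side)]] <- truth[[paste0("iris_radius_", side)]]
  }
  tibble::as_tibble(out)
}

#' Read a cohort written by [write_eye_dataset()]
#'
#' Rebuilds the cohort tibble (images plus `eye_truth` ground truth) from a
#' directory of per-scene PNGs and the `truth.csv` sidecar.
#'
#' @param dir Directory created by [write_eye_dataset()].
#' @return A tibble with `subject_id`, `label`, `image`, `truth`.
#' @export
read_eye_dataset <- function(dir) {
  tab <- utils::read.csv(file.path(dir, "truth.csv"), stringsAsFactors = FALSE)
  truth <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    tr <- list(label = row$label)
    for (side in c("right", "left")) {
      for (f in c("canthus_medial", "canthus_lateral", "pupil_center",
                  "reflex_center")) {
        x <- row[[paste0(f, "_", side, "_x")]]
        y <- row[[paste0(f, "_", side, "_y")]]
        tr[[paste0(f, "_", side)]] <- if (is.na(x)) NULL else c(x, y)
      }
      tr[[paste0("iris_radius_", side)]] <- row[[paste0("iris_radius_", side)]]
    }
    class(tr) <- "eye_truth"
    tr
  })
  images <- lapply(tab$subject_id, function(id) {
    png::readPNG(file.path(dir, paste0(id, ".png"))) * 255
  })
  tibble::tibble(subject_id = tab$subject_id, label = tab$label,
                 image = images, truth = truth)
}

#' Write a synthetic cohort to disk
#'
#' Writes one PNG per scene plus a `truth.csv` sidecar table with one row
#' per scene (all ground-truth coordinates, radii, reflex centres and the
#' label; absent reflexes are `NA`).
#'
#' @param dataset A cohort tibble from [make_eye_dataset()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the path to the sidecar CSV.
#' @export
write_eye_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(dataset))) {
    png::writePNG(dataset$image[[i]] / 255,
                  file.path(out_dir, paste0(dataset$subject_id[i], ".png")))
  }
  rows <- dplyr::bind_rows(lapply(dataset$truth, truth_to_row))
  rows <- dplyr::bind_cols(tibble::tibble(subject_id = dataset$subject_id), rows)
  csv <- file.path(out_dir, "truth.csv")
  utils::write.csv(rows, csv, row.names = FALSE)
  invisible(csv)
}
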