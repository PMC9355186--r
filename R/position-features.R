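## Geometric screening features.
##
## Two scale-free scalars summarise ocular alignment in a frontal photo:
##
## * the position-similarity ratio S: each eye's ratio of
##   pupil-to-medial-canthus over pupil-to-lateral-canthus distance is
##   computed, and S is the larger ratio over the smaller. Symmetric eye
##   positions give S = 1; deviation drives S above 1.
## * the corneal-light-reflex (CLR) ratio (D1 + D3) / (D2 + D4), where D1,
##   D3 are the distances from each eye's reflex centre to its medial
##   corneal limbus and D2, D4 are the iris diameters. Reflexes centred in
##   both irises give exactly 0.5; the orthotropic reference range is
##   0.448-0.488 (Hirschberg photo-screening), midpoint 0.468.

#' Reference range of the CLR ratio
#'
#' The orthotropic (normal) reference band of the corneal-light-reflex
#' ratio and the abnormal cut-offs, from Hirschberg-test photographic
#' measurement. The midpoint of the normal band, 0.468, is the value
#' imputed for normal images lacking a reflex.
#'
#' @return A list: `normal_low` (0.448), `normal_high` (0.488),
#'   `abnormal_below` (0.440), `abnormal_above` (0.497).
#' @export
clr_reference_range <- function() {
  list(normal_low = 0.448, normal_high = 0.488,
       abnormal_below = 0.440, abnormal_above = 0.497)
}

## Imputation constant: midpoint of the normal CLR band.
clr_impute_normal_value <- function() {
  r <- clr_reference_range()
  (r$normal_low + r$normal_high) / 2
}

#' Position-similarity ratio of the two irises
#'
#' Computes the per-eye ratios `R1/R2` (right) and `L1/L2` (left) of the
#' Euclidean pupil-to-medial-canthus over pupil-to-lateral-canthus
#' distances, and their symmetry ratio
#' `S = max(R1/R2, L1/L2) / min(R1/R2, L1/L2)`.
#'
#' @param pupil_right,pupil_left `(x, y)` pupil centres.
#' @param canthi A list with elements `medial_right`, `lateral_right`,
#'   `medial_left`, `lateral_left`, each an `(x, y)` point in the same
#'   frame as the pupil centres.
#' @return A one-row tibble with columns `R1`, `R2`, `L1`, `L2`, `S`.
#' @export
#' @examples
#' canthi <- list(medial_right = c(10, 0), lateral_right = c(-10, 0),
#'                medial_left = c(30, 0), lateral_left = c(50, 0))
#' position_similarity(c(0, 0), c(40, 0), canthi)$S  # 1: symmetric
position_similarity <- function(pupil_right, pupil_left, canthi) {
  stopifnot_point(pupil_right, "pupil_right")
  stopifnot_point(pupil_left, "pupil_left")
  for (nm in c("medial_right", "lateral_right", "medial_left", "lateral_left")) {
    stopifnot_point(canthi[[nm]], paste0("canthi$", nm))
  }
  R1 <- euclid(pupil_right, canthi$medial_right)
  R2 <- euclid(pupil_right, canthi$lateral_right)
  L1 <- euclid(pupil_left, canthi$medial_left)
  L2 <- euclid(pupil_left, canthi$lateral_left)
  if (any(c(R1, R2, L1, L2) == 0)) {
    stop("zero pupil-to-canthus distance: similarity undefined", call. = FALSE)
  }
  ratios <- c(R1 / R2, L1 / L2)
  tibble::tibble(R1 = R1, R2 = R2, L1 = L1, L2 = L2,
                 S = max(ratios) / min(ratios))
}

#' Detect the corneal light reflex inside a fitted iris
#'
#' Applies Otsu's threshold with bright polarity to the pixels of the iris
#' disc and returns the centroid of the bright pixels. Absence is a value,
#' not an error: `NULL` is returned when no pixel is bright, when the
#' bright area is smaller than `min_area` (specular dots cover at least a
#' few pixels) or larger than `max_area_frac` of the disc (a "reflex" that
#' large is the iris itself or an occluding lid, not a specular dot).
#'
#' @param crop RGB array or grayscale matrix (0-255).
#' @param iris An `iris_circle` in the crop frame.
#' @param min_area Minimum bright-pixel count (default 2).
#' @param max_area_frac Maximum bright area as a fraction of the iris disc
#'   (default 0.1).
#' @param shrink Fraction of the fitted radius searched (default 0.9);
#'   keeps sclera pixels leaking across a slightly over-estimated limbus
#'   out of the bright class.
#' @return `(x, y)` centroid of the reflex, or `NULL` when absent.
#' @export
detect_clr_center <- function(crop, iris, min_area = 2, max_area_frac = 0.1,
                              shrink = 0.9) {
  gray <- as_gray(crop)
  g <- pixel_grid(nrow(gray), ncol(gray))
  disc <- (g$X - iris$center[1])^2 + (g$Y - iris$center[2])^2 <=
    (shrink * iris$radius)^2
  vals <- gray[disc]
  if (length(vals) < 2 || length(unique(round(vals))) < 2) return(NULL)
  thr <- otsu_threshold(matrix(vals))
  bright <- disc & gray > thr
  n <- sum(bright)
  if (n < min_area || n > max_area_frac * sum(disc)) return(NULL)
  c(mean(g$X[bright]), mean(g$Y[bright]))
}

#' Corneal-light-reflex ratio from both eyes
#'
#' Each eye's medial corneal limbus point is located on the horizontal line
#' through the pupil centre, one iris radius toward the nose: `+x` for the
#' subject's right eye (which sits on the image's left), `-x` for the left
#' eye. `D1`, `D3` are the Euclidean distances from each reflex centre to
#' that limbus point; `D2`, `D4` are the iris diameters; the ratio is
#' `(D1 + D3) / (D2 + D4)`.
#'
#' @param reflex_right,reflex_left `(x, y)` reflex centres (each in the
#'   same frame as its own eye's iris circle).
#' @param iris_right,iris_left `iris_circle` fits.
#' @return A one-row tibble: `D1`, `D2`, `D3`, `D4`, `ratio`,
#'   `provenance = "measured"`.
#' @export
clr_ratio <- function(reflex_right, reflex_left, iris_right, iris_left) {
  stopifnot_point(reflex_right, "reflex_right")
  stopifnot_point(reflex_left, "reflex_left")
  if (iris_right$radius <= 0 || iris_left$radius <= 0) {
    stop("degenerate iris radius", call. = FALSE)
  }
  limbus_right <- iris_right$center + c(iris_right$radius, 0)
  limbus_left <- iris_left$center - c(iris_left$radius, 0)
  D1 <- euclid(reflex_right, limbus_right)
  D3 <- euclid(reflex_left, limbus_left)
  D2 <- 2 * iris_right$radius
  D4 <- 2 * iris_left$radius
  tibble::tibble(D1 = D1, D2 = D2, D3 = D3, D4 = D4,
                 ratio = (D1 + D3) / (D2 + D4), provenance = "measured")
}

#' Impute a missing CLR ratio for a training image
#'
#' Training images have known labels, so a missing reflex is replaced by
#' the class-typical value: the normal-range midpoint 0.468 for normal
#' images, 0 for strabismic images.
#'
#' @param label `"normal"` or `"strabismus"` (vectorised).
#' @return Imputed ratio(s).
#' @export
impute_clr_train <- function(label) {
  if (!all(label %in% c("normal", "strabismus"))) {
    stop("label must be 'normal' or 'strabismus'", call. = FALSE)
  }
  ifelse(label == "normal", clr_impute_normal_value(), 0)
}

#' Decision criterion for label-free CLR imputation
#'
#' The midpoint between the maximum similarity ratio S among normal
#' training images and the minimum S among strabismic training images.
#'
#' @param train_S_normal,train_S_strab Non-empty numeric vectors of
#'   training S values per class.
#' @return The criterion value.
#' @export
clr_criterion <- function(train_S_normal, train_S_strab) {
  if (length(train_S_normal) == 0 || length(train_S_strab) == 0) {
    stop("both classes must be present to form the imputation criterion",
         call. = FALSE)
  }
  (max(train_S_normal) + min(train_S_strab)) / 2
}

#' Impute a missing CLR ratio for a test image
#'
#' Test labels are unknown, so the similarity ratio decides: images with
#' `S <= criterion` (boundary inclusive) receive the normal-range midpoint
#' 0.468, the rest 0.
#'
#' @param S Similarity ratio(s), each `>= 1`.
#' @param criterion Criterion from [clr_criterion()].
#' @return Imputed ratio(s).
#' @export
impute_clr_test <- function(S, criterion) {
  stopifnot(is.finite(criterion), all(is.finite(S)))
  ifelse(S <= criterion, clr_impute_normal_value(), 0)
}
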