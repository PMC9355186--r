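## Eye-region extraction behind a pluggable landmark provider.
##
## A landmark provider is a function(face_image) returning
## list(right = <6 x 2 landmark matrix>, left = <...>) in 0-based face-frame
## coordinates, rows ordered (medial canthus, lateral canthus, then four
## eyelid points). Providers throw "no face" / "N faces" errors themselves.
## The pipeline never depends on which provider produced the landmarks.

#' Landmark provider that returns known ground truth
#'
#' Bypasses detection for synthetic scenes: canthus landmarks are copied
#' from the scene's `eye_truth` and the four eyelid landmarks are placed on
#' the renderer's eye-opening ellipse (aspect `b/a` fixed by the renderer's
#' geometry constants).
#'
#' @param truth An `eye_truth` from [render_eye_pair()].
#' @return A landmark-provider function.
#' @export
truth_landmark_provider <- function(truth) {
  force(truth)
  function(face) {
    lapply(stats::setNames(c("right", "left"), c("right", "left")), function(side) {
      m <- truth[[paste0("canthus_medial_", side)]]
      l <- truth[[paste0("canthus_lateral_", side)]]
      cx <- (m[1] + l[1]) / 2
      cy <- (m[2] + l[2]) / 2
      a <- abs(m[1] - l[1]) / 2
      b <- a * EYE_B_FRAC * 120 / (EYE_A_FRAC * 320)  # renderer ellipse aspect
      lid_dy <- b * sqrt(3) / 2
      rbind(m, l,
            c(cx - a / 2, cy - lid_dy), c(cx + a / 2, cy - lid_dy),
            c(cx - a / 2, cy + lid_dy), c(cx + a / 2, cy + lid_dy),
            deparse.level = 0)
    })
  }
}

#' Intensity-contrast landmark detector
#'
#' A self-contained detector for synthetic-style frontal scenes: irises are
#' found as dark pixel groups separated by an x-gap, and each eye opening is
#' traced along the iris-centre row as the run of pixels darker than the
#' skin estimate (the image's median gray). Requires a luminance step
#' between sclera and skin; photographic face images should instead use an
#' external landmark model wrapped as a provider function.
#'
#' @param min_gap Minimum x-gap (pixels) separating dark pixel groups.
#' @param skin_margin Gray levels below the median that still count as
#'   eye-opening (sclera) rather than skin.
#' @return A landmark-provider function. It raises a `"no face"` error on
#'   images without exactly two iris groups from one face, and an error
#'   naming the count when the dark groups suggest several faces.
#' @export
intensity_landmark_provider <- function(min_gap = 25, skin_margin = 10) {
  function(face) {
    gray <- as_gray(face)
    skin <- stats::median(gray)
    dark <- which(gray < (skin + min(gray)) / 2, arr.ind = TRUE)
    if (nrow(dark) < 10 || diff(range(gray)) < 2 * skin_margin) {
      stop("no face found in image", call. = FALSE)
    }
    xs <- sort(unique(dark[, "col"]))
    grp_id <- cumsum(c(1, diff(xs) > min_gap))
    n_grp <- max(grp_id)
    if (n_grp != 2) {
      if (n_grp >= 4 && n_grp %% 2 == 0) {
        stop(sprintf("expected one face but found %d", n_grp / 2), call. = FALSE)
      }
      stop("no face found in image", call. = FALSE)
    }
    groups <- split(xs, grp_id)
    eye_landmarks <- function(cols, medial_sign) {
      px <- dark[dark[, "col"] %in% cols, , drop = FALSE]
      cx <- mean(px[, "col"]) - 1   # 0-based iris centroid
      cy <- mean(px[, "row"]) - 1
      row <- gray[round(cy) + 1, ]
      ## opening = darker than skin (sclera/iris) or far brighter (reflex dot)
      open <- row < skin - skin_margin | row > skin + skin_margin
      ## the opening run containing the iris columns
      runs <- rle(open)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1
      k <- which(runs$values & starts <= round(cx) + 1 & ends >= round(cx) + 1)
      if (length(k) != 1) stop("no face found in image", call. = FALSE)
      x0 <- starts[k] - 1
      x1 <- ends[k] - 1
      ecx <- (x0 + x1) / 2
      a <- (x1 - x0) / 2
      b <- a * EYE_B_FRAC * 120 / (EYE_A_FRAC * 320)
      lid_dy <- b * sqrt(3) / 2
      m <- c(ecx + medial_sign * a, round(cy))
      l <- c(ecx - medial_sign * a, round(cy))
      rbind(m, l,
            c(ecx - a / 2, round(cy) - lid_dy), c(ecx + a / 2, round(cy) - lid_dy),
            c(ecx - a / 2, round(cy) + lid_dy), c(ecx + a / 2, round(cy) + lid_dy),
            deparse.level = 0)
    }
    list(right = eye_landmarks(groups[[1]], +1),   # image-left group = subject's right eye
         left = eye_landmarks(groups[[2]], -1))
  }
}

new_eye_region <- function(crop, origin, landmarks, side) {
  structure(
    list(crop = crop, origin = origin, landmarks = landmarks,
         canthus_medial = landmarks[1, ], canthus_lateral = landmarks[2, ],
         side = side),
    class = "eye_region"
  )
}

#' Extract both eye regions from a face image
#'
#' Runs the landmark provider, then crops each eye around its six landmarks
#' with a fractional margin so the full limbus is included. Coordinates are
#' 0-based with the origin at the image's top-left corner.
#'
#' @param face An RGB array or grayscale matrix (0-255).
#' @param provider A landmark-provider function, e.g.
#'   [truth_landmark_provider()] or [intensity_landmark_provider()].
#' @param margin Fractional expansion of the landmark bounding box
#'   (default 0.25).
#' @return A list with elements `right` and `left`, each of class
#'   `eye_region`: `crop` (RGB array), `origin` (x, y of the crop's first
#'   pixel in the face frame), `landmarks` (6 x 2, face frame),
#'   `canthus_medial`, `canthus_lateral`, `side`.
#' @export
detect_and_extract <- function(face, provider, margin = 0.25) {
  if (is.matrix(face)) face <- gray_to_rgb(face)
  h <- dim(face)[1]
  w <- dim(face)[2]
  lm <- provider(face)
  out <- lapply(c(right = "right", left = "left"), function(side) {
    pts <- lm[[side]]
    stopifnot(is.matrix(pts), nrow(pts) == 6, ncol(pts) == 2)
    bx <- range(pts[, 1])
    by <- range(pts[, 2])
    mx <- margin * diff(bx)
    my <- margin * diff(by)
    x0 <- max(0, floor(bx[1] - mx))
    x1 <- min(w - 1, ceiling(bx[2] + mx))
    y0 <- max(0, floor(by[1] - my))
    y1 <- min(h - 1, ceiling(by[2] + my))
    crop <- face[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), , drop = FALSE]
    new_eye_region(crop, c(x0, y0), pts, side)
  })
  out
}

#' Map points between the face frame and an eye region's crop frame
#'
#' @param region An `eye_region`.
#' @param pts A numeric `(x, y)` pair or an n x 2 matrix.
#' @return Points translated by the crop origin; the round trip is exact.
#' @export
to_crop_coords <- function(region, pts) {
  if (is.null(dim(pts))) pts - region$origin else sweep(pts, 2, region$origin)
}

#' @rdname to_crop_coords
#' @export
to_face_coords <- function(region, pts) {
  if (is.null(dim(pts))) pts + region$origin else sweep(pts, 2, region$origin, `+`)
}

## Bilinear resampling on the 0-255 scale. Output pixel centre (i, j) maps
## to source coordinate (i + 0.5) * h_in / h_out - 0.5 (and likewise in x),
## clamped to the source grid; no aspect preservation.
bilinear_resize_gray <- function(gray, out_h, out_w) {
  h <- nrow(gray)
  w <- ncol(gray)
  sy <- clamp((seq_len(out_h) - 0.5) * h / out_h - 0.5, 0, h - 1)
  sx <- clamp((seq_len(out_w) - 0.5) * w / out_w - 0.5, 0, w - 1)
  y0 <- pmin(floor(sy), h - 1)
  x0 <- pmin(floor(sx), w - 1)
  y1 <- pmin(y0 + 1, h - 1)
  x1 <- pmin(x0 + 1, w - 1)
  fy <- sy - y0
  fx <- sx - x0
  A <- gray[y0 + 1, x0 + 1, drop = FALSE]
  B <- gray[y0 + 1, x1 + 1, drop = FALSE]
  C <- gray[y1 + 1, x0 + 1, drop = FALSE]
  D <- gray[y1 + 1, x1 + 1, drop = FALSE]
  FY <- matrix(fy, out_h, out_w)
  FX <- matrix(fx, out_h, out_w, byrow = TRUE)
  A * (1 - FY) * (1 - FX) + B * (1 - FY) * FX + C * FY * (1 - FX) + D * FY * FX
}

#' Resize an eye crop to the embedding input resolution
#'
#' Direct (aspect-ignoring) bilinear resize to `size` x `size`, the input
#' contract of the embedding providers.
#'
#' @param region An `eye_region`, or an image (matrix / RGB array).
#' @param size Output side length in pixels (default 84).
#' @return An RGB array of dimension `size` x `size` x 3.
#' @export
resize_for_embedding <- function(region, size = 84) {
  img <- if (inherits(region, "eye_region")) region$crop else region
  if (is.matrix(img)) img <- gray_to_rgb(img)
  if (length(img) == 0 || any(dim(img)[1:2] == 0)) {
    stop("cannot resize an empty crop", call. = FALSE)
  }
  out <- array(0, dim = c(size, size, 3))
  for (ch in 1:3) out[, , ch] <- bilinear_resize_gray(img[, , ch], size, size)
  out
}
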