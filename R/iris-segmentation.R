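## Iris segmentation and pupil-centre estimation.
##
## The iris is isolated by intersecting two masks — Otsu's histogram
## threshold (dark polarity) and an HSV value-channel band [0, v] with v the
## crop's rounded mean gray — then the lower limbus arc is sampled column by
## column (bottom-to-top first hit) and a circle fitted by the Kåsa
## algebraic least-squares method. The lower arc is used because the upper
## limbus is routinely occluded by the eyelid.

#' Otsu threshold of a grayscale image
#'
#' The gray level maximising the between-class variance of the 256-bin
#' histogram; ties resolve to the lowest threshold.
#'
#' @param gray Numeric matrix on the 0-255 scale (values are rounded into
#'   bins).
#' @return Integer threshold in `0:255`.
#' @export
otsu_threshold <- function(gray) {
  v <- clamp(round(as.vector(gray)), 0, 255)
  if (length(unique(v)) < 2) {
    stop("constant image: Otsu threshold undefined", call. = FALSE)
  }
  counts <- tabulate(v + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  w0 <- cumsum(p)
  m0 <- cumsum(p * levels)
  mt <- m0[256]
  w1 <- 1 - w0
  ## between-class variance at threshold t (foreground = levels <= t)
  sb <- ifelse(w0 > 0 & w1 > 0, (mt * w0 - m0)^2 / (w0 * w1), -Inf)
  which.max(sb) - 1L
}

#' Dark-foreground Otsu mask of an eye crop
#'
#' Thresholds the grayscale crop at the Otsu optimum; foreground (TRUE) are
#' the pixels at or below the threshold — the dark iris.
#'
#' @param crop RGB array or grayscale matrix (0-255).
#' @return Logical matrix aligned with the crop.
#' @export
otsu_mask <- function(crop) {
  gray <- as_gray(crop)
  gray <= otsu_threshold(gray)
}

#' HSV value-band mask of an eye crop
#'
#' Keeps pixels whose HSV value channel (max of R, G, B, 0-255 scale) lies
#' in `[0, v]`, with the upper bound `v` set automatically to the rounded
#' mean gray of the crop; hue and saturation are unrestricted (full
#' `[0, 180]` and `[0, 255]` bands). The bound is inclusive.
#'
#' @inheritParams otsu_mask
#' @return Logical matrix aligned with the crop.
#' @export
hsv_mask <- function(crop) {
  if (is.matrix(crop)) crop <- gray_to_rgb(crop)
  v <- round(mean(as_gray(crop)))
  value <- pmax(crop[, , 1], crop[, , 2], crop[, , 3])
  value <= v
}

#' Intersect two binary masks
#'
#' Pixel-wise logical AND — the "common parts" fusion of the Otsu and HSV
#' segmentations.
#'
#' @param a,b Logical matrices of identical dimension.
#' @return Logical matrix.
#' @export
combine_masks <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("mask dimensions differ: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), call. = FALSE)
  }
  a & b
}

## 4-connected component labelling by breadth-first expansion.
label_components <- function(mask) {
  h <- nrow(mask)
  n <- length(mask)
  lab <- integer(n)
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s] > 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier)) {
      r <- ((frontier - 1L) %% h) + 1L
      nb <- c(frontier[r > 1L] - 1L, frontier[r < h] + 1L,
              frontier - h, frontier + h)
      nb <- unique(nb[nb >= 1L & nb <= n])
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      frontier <- nb
    }
  }
  matrix(lab, nrow = h)
}

## Drop connected components smaller than min_frac of the mask area
## (eyelash / noise specks).
clean_mask <- function(mask, min_frac = 0.01) {
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_frac * length(mask))
  matrix(lab %in% keep, nrow = nrow(mask))
}

#' Sample lower-limbus points from a binary mask
#'
#' For every column that intersects the foreground, rows are scanned bottom
#' to top and the first foreground pixel is recorded, tracing the lower
#' limbus arc (the arc least affected by eyelid occlusion). Components
#' smaller than `min_component_frac` of the crop area are removed first.
#'
#' @param mask Logical matrix (iris segmentation).
#' @param min_component_frac Minimum component size, as a fraction of the
#'   mask area, to survive cleanup (default 0.01).
#' @return An n x 2 matrix of 0-based `(x, y)` points.
#' @export
sample_limbus_points <- function(mask, min_component_frac = 0.01) {
  if (sum(mask) >= 3) mask <- clean_mask(mask, min_component_frac)
  cols <- which(colSums(mask) > 0)
  pts <- vapply(cols, function(j) c(j - 1, max(which(mask[, j])) - 1),
                numeric(2))
  if (length(cols) < 3) {
    stop("fewer than 3 limbus points sampled: circle underdetermined",
         call. = FALSE)
  }
  t(pts)
}

#' Least-squares (Kåsa) circle fit
#'
#' Solves the algebraic least-squares problem
#' \eqn{\min \sum_i (x_i^2 + y_i^2 + D x_i + E y_i + F)^2} in closed form;
#' the centre is \eqn{(-D/2, -E/2)} and the radius
#' \eqn{\sqrt{(D^2+E^2)/4 - F}}. Optionally refines by minimising the
#' geometric (radial) distances from the algebraic solution.
#'
#' @param points An n x 2 matrix (n >= 3) of `(x, y)` coordinates.
#' @param refine Run a geometric (radial-distance) refinement after the
#'   algebraic fit? Default `FALSE`; the closed-form fit is deterministic
#'   and is the standard path.
#' @return An object of class `iris_circle`: `center` (x, y), `radius`,
#'   `rms_residual` (root-mean-square radial deviation), `n_points`.
#' @export
fit_circle_lsm <- function(points, refine = FALSE) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need at least 3 points", call. = FALSE)
  x <- points[, 1]
  y <- points[, 2]
  A <- cbind(x, y, 1)
  qrA <- qr(A)
  if (qrA$rank < 3) {
    stop("points are collinear: circle fit singular", call. = FALSE)
  }
  coef <- qr.coef(qrA, -(x^2 + y^2))
  center <- c(-coef[1] / 2, -coef[2] / 2)
  r2 <- sum(center^2) - coef[3]
  if (!is.finite(r2) || r2 <= 0) {
    stop("degenerate circle fit (non-positive radius)", call. = FALSE)
  }
  radius <- sqrt(r2)
  if (refine) {
    obj <- function(p) sum((sqrt((x - p[1])^2 + (y - p[2])^2) - p[3])^2)
    opt <- stats::optim(c(center, radius), obj, method = "BFGS",
                        control = list(reltol = 1e-12, maxit = 500))
    center <- opt$par[1:2]
    radius <- opt$par[3]
  }
  d <- sqrt((x - center[1])^2 + (y - center[2])^2)
  structure(
    list(center = unname(center), radius = unname(radius),
         rms_residual = sqrt(mean((d - radius)^2)), n_points = nrow(points)),
    class = "iris_circle"
  )
}

#' Estimate the pupil centre of an eye crop
#'
#' The full segmentation chain: Otsu mask AND HSV mask, lower-limbus
#' sampling, Kåsa circle fit. The fitted circle's centre serves as the
#' pupil centre and its radius as the iris radius.
#'
#' @inheritParams otsu_mask
#' @inheritParams sample_limbus_points
#' @inheritParams fit_circle_lsm
#' @return An `iris_circle` in the crop's 0-based pixel frame.
#' @export
estimate_pupil_center <- function(crop, min_component_frac = 0.01,
                                  refine = FALSE) {
  mask <- combine_masks(otsu_mask(crop), hsv_mask(crop))
  pts <- sample_limbus_points(mask, min_component_frac)
  fit_circle_lsm(pts, refine = refine)
}
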