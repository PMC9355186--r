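## Shared low-level helpers. All are internal.

## Luma grayscale conversion (ITU-R BT.601 weights). Accepts a grayscale
## matrix (returned unchanged) or an h x w x 3 array on the 0-255 scale.
as_gray <- function(img) {
  if (is.matrix(img)) return(img)
  d <- dim(img)
  if (length(d) == 3L && d[3] >= 3L) {
    return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  }
  if (length(d) == 3L && d[3] == 1L) return(img[, , 1])
  stop("expected a grayscale matrix or an h x w x 3 RGB array", call. = FALSE)
}

## Replicate a grayscale matrix into an RGB array.
gray_to_rgb <- function(gray) {
  array(rep(gray, 3L), dim = c(nrow(gray), ncol(gray), 3L))
}

euclid <- function(p, q) sqrt(sum((p - q)^2))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_point <- function(p) is.numeric(p) && length(p) == 2L && all(is.finite(p))

stopifnot_point <- function(p, what) {
  if (!is_point(p)) stop(what, " must be a finite (x, y) pair", call. = FALSE)
}

## Coordinate grids for an h x w raster, 0-based pixel-centre coordinates.
## Returns list(X, Y) matrices aligned with the image matrix.
pixel_grid <- function(h, w) {
  list(
    X = matrix(rep(seq_len(w) - 1, each = h), nrow = h),
    Y = matrix(rep(seq_len(h) - 1, times = w), nrow = h)
  )
}
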