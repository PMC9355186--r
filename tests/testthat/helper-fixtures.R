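# Programmatic fixtures shared across test files.

# Logical raster of a disc: pixel centres (0-based) inside the circle.
disc_mask <- function(h, w, cx, cy, r) {
  X <- matrix(rep(seq_len(w) - 1, each = h), nrow = h)
  Y <- matrix(rep(seq_len(h) - 1, times = w), nrow = h)
  (X - cx)^2 + (Y - cy)^2 <= r^2
}

# Grayscale crop with a dark disc on a bright background.
disc_crop <- function(h, w, cx, cy, r, fg = 40, bg = 200) {
  img <- matrix(bg, h, w)
  img[disc_mask(h, w, cx, cy, r)] <- fg
  img
}

# Brute-force Otsu oracle: exhaustive search over all 256 thresholds for
# the maximal between-class variance, lowest threshold on ties.
otsu_brute_force <- function(gray) {
  v <- pmin(pmax(round(as.vector(gray)), 0), 255)
  best_t <- NA_integer_
  best_var <- -Inf
  for (t in 0:255) {
    lo <- v[v <= t]
    hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(v)
    bc <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (bc > best_var + 1e-12) {
      best_var <- bc
      best_t <- t
    }
  }
  best_t
}

# Independent geometric circle-fit oracle: Gauss-Newton on the radial
# residuals, started from the data centroid.
circle_fit_geometric_oracle <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  p <- c(mean(x), mean(y), mean(sqrt((x - mean(x))^2 + (y - mean(y))^2)))
  for (it in 1:100) {
    dx <- x - p[1]; dy <- y - p[2]
    d <- sqrt(dx^2 + dy^2)
    r <- d - p[3]
    J <- cbind(-dx / d, -dy / d, -1)
    step <- qr.solve(crossprod(J), crossprod(J, -r))
    p <- p + as.numeric(step)
    if (sqrt(sum(step^2)) < 1e-12) break
  }
  list(center = p[1:2], radius = p[3])
}

# Small standard cohorts, memoised so multiple test files can reuse them.
.fixture_env <- new.env(parent = emptyenv())

fixture_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- make_eye_dataset(6, 6, seed = 101)
  }
  .fixture_env$cohort
}

fixture_features <- function() {
  if (is.null(.fixture_env$features)) {
    .fixture_env$features <- process_cohort(fixture_cohort())
  }
  .fixture_env$features
}

# Full-protocol-scale cohort with a wide deviation gap: the classes are
# effortlessly separable, so every 15/15 experiment should score 30/30.
fixture_features_wide <- function() {
  if (is.null(.fixture_env$features_wide)) {
    ds <- make_eye_dataset(30, 30, seed = 202, deviation_range = c(12, 16))
    .fixture_env$features_wide <- process_cohort(ds)
  }
  .fixture_env$features_wide
}
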