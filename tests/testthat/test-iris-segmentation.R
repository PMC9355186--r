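test_that("Otsu matches the brute-force 256-threshold search on varied images", {
  bimodal <- matrix(c(rep(50, 200), rep(200, 200)), 20, 20)
  expect_identical(otsu_threshold(bimodal), otsu_brute_force(bimodal))
  expect_identical(otsu_mask(bimodal), bimodal == 50)

  suite <- list(
    disc_crop(40, 60, 30, 20, 12),
    disc_crop(40, 60, 30, 20, 12) + matrix(rnorm(2400, 0, 8), 40, 60),
    matrix(runif(900, 0, 255), 30, 30),
    matrix(rep(seq(0, 255, length.out = 50), each = 10), 10, 50)
  )
  sc <- render_eye_pair(eye_scene_spec(seed = 4, noise_sd = 2))
  rg <- detect_and_extract(sc$image, truth_landmark_provider(sc$truth))
  suite <- c(suite, list(0.299 * rg$right$crop[, , 1] +
                           0.587 * rg$right$crop[, , 2] +
                           0.114 * rg$right$crop[, , 3]))
  for (img in suite) {
    expect_identical(otsu_threshold(img), otsu_brute_force(img))
  }
})

test_that("Otsu rejects constant images and segments noiseless eye crops well", {
  expect_error(otsu_threshold(matrix(7, 5, 5)), "constant")

  sc <- render_eye_pair(eye_scene_spec(reflex_present_right = FALSE,
                                       reflex_present_left = FALSE))
  rg <- detect_and_extract(sc$image, truth_landmark_provider(sc$truth))$right
  mask <- otsu_mask(rg$crop)
  tr <- sc$truth
  ctr <- tr$pupil_center_right - rg$origin
  truth_disc <- disc_mask(nrow(mask), ncol(mask), ctr[1], ctr[2],
                          tr$iris_radius_right)
  iou <- sum(mask & truth_disc) / sum(mask | truth_disc)
  expect_gte(iou, 0.9)
})

test_that("the HSV value band is inclusive and set by the mean gray", {
  uniform <- matrix(123, 10, 10)
  expect_true(all(hsv_mask(uniform)))

  half <- matrix(c(rep(40, 50), rep(200, 50)), 10, 10)   # v = 120
  expect_identical(hsv_mask(half), half == 40)

  speck <- matrix(255, 16, 16)
  speck[8, 8] <- 0
  m <- hsv_mask(speck)
  expect_true(m[8, 8])
  expect_equal(sum(m), 1)
})

test_that("mask intersection follows AND semantics", {
  A <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)
  B <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2)
  expect_identical(combine_masks(A, A), A)
  empty <- matrix(FALSE, 2, 2)
  expect_identical(combine_masks(A, empty), empty)
  comb <- combine_masks(A, B)
  expect_true(all(!comb | A))
  expect_true(all(!comb | B))
  expect_lte(sum(comb), min(sum(A), sum(B)))
  expect_error(combine_masks(A, matrix(TRUE, 3, 3)), "dimensions differ")
})

test_that("lower-limbus sampling traces the bottom arc and survives occlusion", {
  mask <- disc_mask(60, 60, 30, 28, 15)
  pts <- sample_limbus_points(mask)
  d <- sqrt((pts[, 1] - 30)^2 + (pts[, 2] - 28)^2)
  expect_true(all(abs(d - 15) <= 1))

  occluded <- mask
  occluded[1:floor(0.4 * 60), ] <- FALSE
  expect_identical(sample_limbus_points(occluded), pts)

  single_col <- matrix(FALSE, 30, 30)
  single_col[5:25, 7] <- TRUE
  expect_error(sample_limbus_points(single_col), "fewer than 3")
})

test_that("small components are removed before sampling", {
  mask <- disc_mask(60, 60, 30, 25, 15)
  speckled <- mask
  speckled[55, 10] <- TRUE   # isolated 1-px eyelash speck below the disc
  expect_identical(sample_limbus_points(speckled), sample_limbus_points(mask))
})

test_that("the Kåsa fit is exact on exact circles", {
  four <- rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
  fit <- fit_circle_lsm(four)
  expect_equal(fit$center, c(0, 0), tolerance = 1e-9)
  expect_equal(fit$radius, 1, tolerance = 1e-9)
  expect_equal(fit$rms_residual, 0, tolerance = 1e-9)

  three <- rbind(c(0, 0), c(2, 0), c(0, 2))
  fit3 <- fit_circle_lsm(three)
  expect_equal(fit3$center, c(1, 1), tolerance = 1e-9)
  expect_equal(fit3$radius, sqrt(2), tolerance = 1e-9)

  expect_error(fit_circle_lsm(cbind(1:5, 2 * (1:5) + 3)), "collinear")
})

test_that("the Kåsa fit agrees with a geometric least-squares oracle on noisy circles", {
  pts <- withr::with_seed(77, {
    th <- runif(40, 0, 2 * pi)
    cbind(10 + 7 * cos(th) + rnorm(40, 0, 0.1),
          5 + 7 * sin(th) + rnorm(40, 0, 0.1))
  })
  fit <- fit_circle_lsm(pts)
  oracle <- circle_fit_geometric_oracle(pts)
  expect_lt(sqrt(sum((fit$center - oracle$center)^2)), 0.1)
  expect_lt(abs(fit$radius - oracle$radius), 0.1)
  # the in-package geometric refinement lands on the oracle even tighter
  refined <- fit_circle_lsm(pts, refine = TRUE)
  expect_lt(sqrt(sum((refined$center - oracle$center)^2)), 1e-4)
})

test_that("circle fitting is translation- and rotation-equivariant", {
  pts <- withr::with_seed(3, {
    th <- runif(25, 0, 1.6 * pi)
    cbind(3 + 9 * cos(th) + rnorm(25, 0, 0.2),
          -2 + 9 * sin(th) + rnorm(25, 0, 0.2))
  })
  base <- fit_circle_lsm(pts)
  shifted <- fit_circle_lsm(sweep(pts, 2, c(-12.5, 8.25), `+`))
  expect_equal(shifted$center, base$center + c(-12.5, 8.25),
               tolerance = 1e-9)
  expect_equal(shifted$radius, base$radius, tolerance = 1e-9)

  a <- 0.7
  Rm <- rbind(c(cos(a), -sin(a)), c(sin(a), cos(a)))
  rotated <- fit_circle_lsm(pts %*% t(Rm))
  expect_equal(rotated$center, as.numeric(Rm %*% base$center),
               tolerance = 1e-9)
  expect_equal(rotated$radius, base$radius, tolerance = 1e-9)
})

test_that("rasterised discs of radius 8-40 px are recovered within 1 px", {
  for (r in c(8, 13, 20, 28, 40)) {
    for (ctr in list(c(r + 4, r + 3), c(r + 5.4, r + 4.7))) {
      side <- 2 * r + 12
      mask <- disc_mask(side, side, ctr[1], ctr[2], r)
      fit <- fit_circle_lsm(sample_limbus_points(mask, min_component_frac = 0))
      expect_lt(sqrt(sum((fit$center - ctr)^2)), 1)
      expect_lt(abs(fit$radius - r), 1)
    }
  }
})

test_that("estimate_pupil_center recovers truth within 1 px, occluded or not", {
  for (occ in c(0, 0.4)) {
    sc <- render_eye_pair(eye_scene_spec(
      iris_center_offset_right = c(4.5, -1.5),
      eyelid_occlusion_fraction = occ
    ))
    regions <- detect_and_extract(sc$image, truth_landmark_provider(sc$truth))
    for (side in c("right", "left")) {
      fit <- estimate_pupil_center(regions[[side]]$crop)
      est <- to_face_coords(regions[[side]], fit$center)
      tr_ctr <- sc$truth[[paste0("pupil_center_", side)]]
      expect_lt(sqrt(sum((est - tr_ctr)^2)), 1)
      expect_lt(abs(fit$radius - sc$truth[[paste0("iris_radius_", side)]]), 1)
    }
  }
  expect_error(estimate_pupil_center(matrix(100, 50, 50)), "constant")
})
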