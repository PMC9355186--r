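canthi_box <- list(medial_right = c(10, 0), lateral_right = c(-10, 0),
                   medial_left = c(30, 0), lateral_left = c(50, 0))

test_that("the similarity ratio follows its defining formula", {
  # perfect symmetry: all four distances equal
  ps <- position_similarity(c(0, 0), c(40, 0), canthi_box)
  expect_equal(ps$S, 1.0)
  expect_equal(c(ps$R1, ps$R2, ps$L1, ps$L2), c(10, 10, 10, 10))

  # R1=10, R2=20, L1=12, L2=18 -> ratios 0.5, 2/3 -> S = 4/3
  ps2 <- position_similarity(
    c(0, 0), c(42, 0),
    list(medial_right = c(10, 0), lateral_right = c(-20, 0),
         medial_left = c(30, 0), lateral_left = c(60, 0))
  )
  expect_equal(c(ps2$R1, ps2$R2, ps2$L1, ps2$L2), c(10, 20, 12, 18))
  expect_equal(ps2$S, (12 / 18) / (10 / 20))
  expect_equal(ps2$S, 4 / 3)

  # swapping the eye pairs leaves S unchanged (max/min symmetry)
  swapped <- position_similarity(
    c(42, 0), c(0, 0),
    list(medial_right = c(30, 0), lateral_right = c(60, 0),
         medial_left = c(10, 0), lateral_left = c(-20, 0))
  )
  expect_equal(swapped$S, ps2$S)

  expect_error(position_similarity(c(10, 0), c(40, 0), canthi_box),
               "zero.*distance")
})

test_that("S is at least 1 and invariant to scaling and rigid rotation", {
  pts <- withr::with_seed(12, replicate(20, list(
    pr = runif(2, -5, 5), pl = c(40, 0) + runif(2, -5, 5)
  ), simplify = FALSE))
  rot <- function(p, a) c(cos(a) * p[1] - sin(a) * p[2],
                          sin(a) * p[1] + cos(a) * p[2])
  for (case in pts) {
    S0 <- position_similarity(case$pr, case$pl, canthi_box)$S
    expect_gte(S0, 1)
    scaled <- position_similarity(3.7 * case$pr, 3.7 * case$pl,
                                  lapply(canthi_box, `*`, 3.7))
    expect_equal(scaled$S, S0, tolerance = 1e-12)
    a <- 0.9
    rotated <- position_similarity(rot(case$pr, a), rot(case$pl, a),
                                   lapply(canthi_box, rot, a))
    expect_equal(rotated$S, S0, tolerance = 1e-12)
  }
})

test_that("reflex detection finds the specular centroid or reports absence", {
  cases <- list(c(0, 0), c(3, -2))
  for (off in cases) {
    sc <- render_eye_pair(eye_scene_spec(reflex_offset_right = off,
                                         reflex_offset_left = off))
    rg <- detect_and_extract(sc$image, truth_landmark_provider(sc$truth))$right
    iris <- estimate_pupil_center(rg$crop)
    ctr <- detect_clr_center(rg$crop, iris)
    truth_ctr <- to_crop_coords(rg, sc$truth$reflex_center_right)
    expect_false(is.null(ctr))
    expect_lt(sqrt(sum((ctr - truth_ctr)^2)), 0.5)
  }

  off_sc <- render_eye_pair(eye_scene_spec(reflex_present_right = FALSE,
                                           reflex_present_left = FALSE))
  rg <- detect_and_extract(off_sc$image,
                           truth_landmark_provider(off_sc$truth))$right
  iris <- estimate_pupil_center(rg$crop)
  expect_null(detect_clr_center(rg$crop, iris))
})

test_that("the CLR ratio follows (D1 + D3) / (D2 + D4) with medial limbus points", {
  circ <- function(ctr, r) structure(list(center = ctr, radius = r),
                                     class = "iris_circle")
  # reflexes exactly at the iris centres -> 0.5
  centred <- clr_ratio(c(20, 30), c(80, 30), circ(c(20, 30), 10),
                       circ(c(80, 30), 10))
  expect_equal(centred$ratio, 0.5)
  expect_equal(c(centred$D1, centred$D3), c(10, 10))

  # D1=5, D2=11, D3=5.5, D4=11 -> 10.5/22, inside the normal range
  r <- 5.5
  ratio2 <- clr_ratio(c(0 + r - 5, 0), c(100 - r + 5.5, 0),
                      circ(c(0, 0), r), circ(c(100, 0), r))
  expect_equal(c(ratio2$D1, ratio2$D2, ratio2$D3, ratio2$D4),
               c(5, 11, 5.5, 11))
  expect_equal(ratio2$ratio, 10.5 / 22)
  rng <- clr_reference_range()
  expect_gt(ratio2$ratio, rng$normal_low)
  expect_lt(ratio2$ratio, rng$normal_high)

  # right reflex 2 px toward the medial limbus, radius 10 -> 18/40
  ratio3 <- clr_ratio(c(2, 0), c(50, 0), circ(c(0, 0), 10),
                      circ(c(50, 0), 10))
  expect_equal(ratio3$ratio, (8 + 10) / (20 + 20))
  expect_equal(ratio3$ratio, 0.45)

  expect_error(clr_ratio(c(0, 0), c(50, 0), circ(c(0, 0), 0),
                         circ(c(50, 0), 10)), "degenerate")
})

test_that("measured CLR ratios of reflexes inside the iris stay in [0, 1]", {
  circ <- function(ctr, r) structure(list(center = ctr, radius = r),
                                     class = "iris_circle")
  withr::with_seed(8, {
    for (i in 1:25) {
      r1 <- runif(1, 5, 15); r2 <- runif(1, 5, 15)
      o1 <- runif(2, -1, 1); o1 <- o1 / sqrt(sum(o1^2)) * runif(1, 0, r1)
      o2 <- runif(2, -1, 1); o2 <- o2 / sqrt(sum(o2^2)) * runif(1, 0, r2)
      ratio <- clr_ratio(c(0, 0) + o1, c(60, 0) + o2,
                         circ(c(0, 0), r1), circ(c(60, 0), r2))$ratio
      expect_gte(ratio, 0)
      expect_lte(ratio, 1)
    }
  })
})

test_that("missing-reflex imputation follows the training and test rules", {
  expect_equal(impute_clr_train("normal"), 0.468)
  expect_equal(impute_clr_train("strabismus"), 0)
  rng <- clr_reference_range()
  expect_equal((rng$normal_low + rng$normal_high) / 2, 0.468)
  expect_equal(impute_clr_train("normal"),
               (rng$normal_low + rng$normal_high) / 2)
  expect_error(impute_clr_train("other"), "label")

  expect_equal(clr_criterion(c(1.05, 1.12), c(1.34, 1.5)), 1.23)
  expect_equal(clr_criterion(1.2, 1.2), 1.2)
  expect_equal(clr_criterion(c(1.002, 1.139), c(1.333, 2.877)),
               (1.139 + 1.333) / 2)
  expect_error(clr_criterion(numeric(0), 1.3), "both classes")

  expect_equal(impute_clr_test(1.05, 1.23), 0.468)
  expect_equal(impute_clr_test(1.5, 1.23), 0)
  expect_equal(impute_clr_test(1.23, 1.23), 0.468)  # inclusive boundary
  expect_equal(impute_clr_test(c(1.0, 1.24), 1.23), c(0.468, 0))
})

test_that("zero-deviation scenes give S near 1 and CLR near 0.5 end to end", {
  ds <- make_eye_dataset(4, 0, seed = 55, normal_jitter = 0)
  pf <- process_cohort(ds)
  expect_true(all(abs(pf$S - 1) <= 0.02))
  expect_true(all(abs(pf$clr_measured - 0.5) <= 0.02))
})

test_that("pipeline S tracks ground-truth S within 2% on noiseless scenes", {
  pf <- fixture_features()
  tf <- truth_features(fixture_cohort())
  expect_true(all(abs(pf$S - tf$S) / tf$S <= 0.02))
})
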