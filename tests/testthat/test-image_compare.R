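test_that("gap interpolation averages non-missing neighbors", {
  chi <- matrix(0.4, 3, 3)
  gaps <- matrix(FALSE, 3, 3); gaps[2, 2] <- TRUE
  chi[2, 2] <- 0
  out <- interpolate_gaps(tiny_image(chi, gaps))
  expect_equal(out$chi[2, 2], 0.4)
  expect_true(out$gap_mask[2, 2])  # original gaps stay recorded

  chi <- matrix(c(0, 0, 0, 0, 0, 1, 1, 1, 1), 3, 3)
  chi[2, 2] <- 0
  gaps <- matrix(FALSE, 3, 3); gaps[2, 2] <- TRUE
  out <- interpolate_gaps(tiny_image(chi, gaps))
  expect_equal(out$chi[2, 2], 0.5)

  expect_error(interpolate_gaps(tiny_image(matrix(0, 2, 2),
                                           matrix(TRUE, 2, 2))),
               "all pixels are gaps")
})

test_that("multi-sweep filling matches the literal sweep simulation", {
  set.seed(41)
  for (rep in 1:5) {
    m <- 5
    chi <- matrix(runif(m * m), m, m)
    gaps <- matrix(FALSE, m, m)
    gaps[2:4, 2:4] <- TRUE           # 3x3 block: needs 2 sweeps
    chi[gaps] <- 0
    out <- interpolate_gaps(tiny_image(chi, gaps))
    expect_equal(out$chi, interpolate_oracle(chi, gaps), tolerance = 1e-12)
    # non-gap pixels untouched
    expect_equal(out$chi[!gaps], chi[!gaps])
  }
})

test_that("bicubic resize reproduces identity, constants and linear ramps", {
  set.seed(42)
  chi <- matrix(runif(36), 6, 6); chi <- (chi + t(chi)) / 2
  img <- tiny_image(chi)
  same <- resize_image(img, 6)
  expect_equal(same$chi, chi, tolerance = 1e-9)

  const <- resize_image(tiny_image(matrix(0.7, 5, 5)), 11)
  expect_equal(const$chi, matrix(0.7, 11, 11), tolerance = 1e-9)

  # linear ramp: bicubic convolution is exact on degree-1 surfaces away
  # from the replicate-padded borders
  m <- 8; tm <- 16
  f <- function(x, y) (x + 2 * y) / 30
  src <- outer(seq_len(m), seq_len(m), function(y, x) f(x, y))
  out <- resize_image(tiny_image(src), tm)
  u <- (seq_len(tm) - 0.5) * (m / tm) + 0.5
  expected <- outer(u, u, function(y, x) f(x, y))
  interior <- 4:13
  expect_equal(out$chi[interior, interior], expected[interior, interior],
               tolerance = 1e-6)

  expect_error(resize_image(img, 1), "target_m")
})

test_that("resize propagates the gap mask by nearest neighbor", {
  gaps <- matrix(FALSE, 6, 6); gaps[3, 3] <- TRUE
  img <- tiny_image(matrix(0.5, 6, 6), gaps)
  out <- resize_image(interpolate_gaps(img), 12)
  # source pixel (3,3) covers target pixels with round(u) == 3
  u <- (seq_len(12) - 0.5) * 0.5 + 0.5
  hit <- which(round(u) == 3)
  expect_true(all(out$gap_mask[hit, hit]))
  expect_equal(sum(out$gap_mask), length(hit)^2)
})

test_that("fit_similarity recovers exact and least-squares transforms", {
  pts <- cbind(c(1, 10), c(1, 10), c(1, 10), c(1, 10))
  tf <- fit_similarity(pts)
  expect_equal(tf$scale, 1, tolerance = 1e-12)
  expect_equal(tf$rotation, 0, tolerance = 1e-12)
  expect_equal(tf$translation, c(0, 0), tolerance = 1e-12)

  mv <- cbind(c(1, 5, 9), c(1, 5, 1))
  pts <- cbind(mv, mv + matrix(rep(c(3, -2), each = 3), ncol = 2))
  tf <- fit_similarity(pts)
  expect_equal(tf$scale, 1, tolerance = 1e-12)
  expect_equal(tf$translation, c(3, -2), tolerance = 1e-12)

  # scale 2, rotation pi/2 about the origin
  mv <- cbind(c(1, 4, 2), c(0, 3, 5))
  known <- similarity_transform(2, pi / 2, c(0, 0))
  tf <- fit_similarity(cbind(mv, st_apply(known, mv)))
  expect_equal(tf$scale, 2, tolerance = 1e-9)
  expect_equal(tf$rotation, pi / 2, tolerance = 1e-9)

  # property: noiseless generated pairs are recovered to 1e-9
  set.seed(43)
  for (rep in 1:20) {
    known <- similarity_transform(runif(1, 0.5, 2), runif(1, -3, 3),
                                  runif(2, -10, 10))
    mv <- matrix(runif(2 * sample(2:6, 1), 0, 40), ncol = 2)
    if (nrow(mv) == 2 && all(mv[1, ] == mv[2, ])) next
    tf <- fit_similarity(cbind(mv, st_apply(known, mv)))
    expect_equal(tf$scale, known$scale, tolerance = 1e-9)
    expect_equal(tf$rotation, known$rotation, tolerance = 1e-9)
    expect_equal(tf$translation, known$translation, tolerance = 1e-7)
  }

  expect_error(fit_similarity(cbind(c(2, 2), c(3, 3), c(1, 5), c(2, 6))),
               "degenerate")
  expect_error(fit_similarity(matrix(1, 1, 4)), "n >= 2")
})

test_that("image distance follows the printed mean-squared formula", {
  a <- tiny_image(matrix(c(0, 1, 1, 0), 2, 2))
  b <- tiny_image(matrix(1, 2, 2))
  expect_equal(image_distance(a, b), 0.5)
  expect_equal(image_distance(a, a), 0)
  expect_equal(image_distance(a, b), image_distance(b, a))

  # mutual gap at one pixel; remaining squared diffs 0.04, 0.09, 0.16
  g <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  x <- tiny_image(matrix(c(0, 0.5, 0.2, 0.4), 2, 2), g)
  y <- tiny_image(matrix(c(0.9, 0.7, 0.5, 0.0), 2, 2), g)
  expect_equal(image_distance(x, y), 0.0725)

  expect_error(image_distance(a, tiny_image(matrix(0, 3, 3))), "mismatch")
})

test_that("gap measure counts union gaps normalized by image size", {
  a <- tiny_image(matrix(0, 10, 10))
  b <- tiny_image(matrix(0, 10, 10))
  expect_equal(gap_measure(a, b), 0)

  ga <- matrix(FALSE, 10, 10); ga[1, 1:4] <- TRUE
  gb <- matrix(FALSE, 10, 10); gb[1, 3:7] <- TRUE   # union: 7 pixels
  expect_equal(gap_measure(tiny_image(matrix(0, 10, 10), ga),
                           tiny_image(matrix(0, 10, 10), gb)), 0.07)

  expect_equal(gap_measure(tiny_image(matrix(0, 4, 4), matrix(TRUE, 4, 4)),
                           tiny_image(matrix(0, 4, 4))), 1)
  expect_error(gap_measure(a, tiny_image(matrix(0, 3, 3))), "mismatch")
})

test_that("warping with a fitted transform undoes a known shift", {
  spec <- synthetic_family_spec(m = 40, n_realizations = 80, seed = 5,
                                gap_frac = 0)
  tf <- similarity_transform(1, 0, c(2, 0))
  pr <- generate_registered_pair(spec, tf, noise_sd = 0)

  init <- similarity_transform()   # identity: wrong by 2 px
  d0 <- image_distance(pr$base, warp_image(pr$moving, init, 40))
  ref <- refine_by_maximum_similarity(pr$moving, pr$base, init)
  d1 <- attr(ref, "distance")
  expect_lt(d1, d0)
  expect_lt(abs(ref$translation[1] - 2), 0.5)
  expect_lt(abs(ref$translation[2] - 0), 0.5)

  # moving == base with identity init: identity retained, distance 0
  ref0 <- refine_by_maximum_similarity(pr$base, pr$base,
                                       similarity_transform())
  expect_equal(attr(ref0, "distance"), 0)
  expect_equal(ref0$scale, 1)
  expect_equal(ref0$translation, c(0, 0))
})

test_that("refinement never worsens the initial distance", {
  set.seed(44)
  spec <- synthetic_family_spec(m = 30, n_realizations = 40, seed = 6,
                                gap_frac = 0.05)
  pr <- generate_registered_pair(spec, similarity_transform(1.05, 0.02,
                                                            c(1, -1)),
                                 noise_sd = 0.05)
  mov <- interpolate_gaps(pr$moving)
  for (init in list(similarity_transform(),
                    similarity_transform(1.1, 0.05, c(3, 2)),
                    fit_similarity(pr$control_points))) {
    d0 <- image_distance(pr$base, warp_image(mov, init, 30))
    ref <- refine_by_maximum_similarity(mov, pr$base, init, max_sweeps = 10)
    expect_lte(attr(ref, "distance"), d0 + 1e-15)
  }
})

test_that("compare_pair symmetrizes and recovers noiseless known transforms", {
  spec <- synthetic_family_spec(m = 40, n_realizations = 80, seed = 7,
                                gap_frac = 0)
  pr <- generate_registered_pair(spec, similarity_transform(1, 0, c(2, 3)),
                                 noise_sd = 0)
  rec <- compare_pair(pr$base, pr$moving, cp_xy = pr$control_points)
  expect_lt(rec$euclidean, 1e-3)
  expect_identical(rec$direction, "SYMMETRIZED")

  # identical images, identity control points
  rec0 <- compare_pair(pr$base, pr$base)
  expect_equal(rec0$euclidean, 0)
  expect_equal(rec0$gap_measure, 0)

  # swapping images together with control-point roles changes nothing
  cp_rev <- pr$control_points[, c(3, 4, 1, 2)]
  rec_swap <- compare_pair(pr$moving, pr$base, cp_xy = cp_rev)
  expect_equal(rec_swap$euclidean, rec$euclidean, tolerance = 1e-12)
  expect_equal(rec_swap$gap_measure, rec$gap_measure, tolerance = 1e-12)
})
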