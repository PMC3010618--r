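small_spec <- function(...) {
  args <- utils::modifyList(
    list(n_proteins = 3, m = 24, n_realizations = 40, flip_prob = 0.3,
         mutation_rate = 0.1, gap_frac = 0, seed = 101),
    list(...))
  do.call(synthetic_family_spec, args)
}

test_that("family specs validate blocks and probabilities", {
  expect_s3_class(small_spec(), "SyntheticFamilySpec")
  expect_error(small_spec(flip_prob = 1.5), "\\[0, 1\\]")
  expect_error(small_spec(blocks = data.frame(start = 1, end = 30,
                                              kind = "RIGID")),
               "start <= end <= m")
  expect_error(small_spec(blocks = data.frame(start = c(1, 5),
                                              end = c(6, 10),
                                              kind = "RIGID")),
               "overlap")
  expect_error(small_spec(blocks = data.frame(start = 1, end = 5,
                                              kind = "WOBBLY")),
               "RIGID or FLEXIBLE")
})

test_that("generators are deterministic and produce valid objects", {
  spec <- small_spec(gap_frac = 0.1)
  e1 <- generate_ensemble(spec, 1)
  e2 <- generate_ensemble(spec, 1)
  expect_identical(e1, e2)
  expect_s3_class(validate_ensemble(e1), "RigidityStateEnsemble")

  s1 <- generate_idf_signal(spec, 1)
  s2 <- generate_idf_signal(spec, 1)
  expect_identical(s1, s2)
  expect_identical(s1$kind, "IDF")
  expect_equal(sum(s1$gap_mask), round(0.1 * spec$m))

  img <- compute_susceptibility(e1)
  expect_true(all(img$chi >= 0 & img$chi <= 1))

  # different members differ once mutations are likely
  spec_hi <- small_spec(mutation_rate = 0.95)
  expect_false(identical(generate_ensemble(spec_hi, 0)$realizations,
                         generate_ensemble(spec_hi, 2)$realizations))
  expect_error(generate_ensemble(spec, 5), "member_index")
})

test_that("flip_prob = 0 freezes the ensemble and zeroes susceptibility", {
  spec <- small_spec(flip_prob = 0)
  ens <- generate_ensemble(spec, 0)
  expect_true(all(vapply(ens$realizations, identical, TRUE,
                         ens$realizations[[1]])))
  expect_true(all(compute_susceptibility(ens)$chi == 0))
})

test_that("block-interior fluctuation follows the closed form p(1-p)", {
  # one RIGID block, flip_prob = 0.5: inside the block n_jk is -1 w.p. 0.5
  # and 0 otherwise, so chi = <n^2> - <n>^2 = p - p^2 = 0.25
  spec <- small_spec(m = 12, n_realizations = 2000, flip_prob = 0.5,
                     mutation_rate = 0,
                     blocks = data.frame(start = 3, end = 9, kind = "RIGID"))
  chi <- compute_susceptibility(generate_ensemble(spec, 0))$chi
  expect_equal(chi[3, 9], 0.25, tolerance = 0.05)
  # off-block pairs never fluctuate
  expect_equal(chi[1, 12], 0)
})

test_that("idf signals are near zero in an all-covering rigid block", {
  spec <- small_spec(blocks = data.frame(start = 1, end = 24,
                                         kind = "RIGID"),
                     mutation_rate = 0)
  s <- generate_idf_signal(spec, 0)
  expect_true(all(s$values >= 0))
  expect_true(all(s$values < 0.1))
})

test_that("mutation_rate = 0 makes members identical end to end", {
  # all between-member variation is driven by block mutations, so a family
  # without mutations collapses to identical members and zero distances
  spec <- small_spec(mutation_rate = 0)
  s0 <- generate_idf_signal(spec, 0)
  s1 <- generate_idf_signal(spec, 1)
  expect_identical(s0$values, s1$values)
  expect_equal(dtw_distance(s0, s1)$distance, 0)
  e0 <- compute_susceptibility(generate_ensemble(spec, 0))
  e1 <- compute_susceptibility(generate_ensemble(spec, 1))
  rec <- compare_pair(e0, e1, refine = FALSE)
  expect_equal(rec$euclidean, 0)
  expect_equal(rec$gap_measure, 0)
})

test_that("mean DTW distance grows with mutation_rate", {
  rates <- c(0.05, 0.4, 0.9)
  means <- vapply(rates, function(rate) {
    d <- vapply(1:20, function(s) {
      spec <- small_spec(m = 60, mutation_rate = rate, seed = 1000 + s)
      dtw_distance(generate_idf_signal(spec, 0),
                   generate_idf_signal(spec, 1))$distance
    }, 0)
    mean(d)
  }, 0)
  expect_true(means[1] < means[2] && means[2] < means[3])
})

test_that("registered pairs carry exact control points and expected gaps", {
  spec <- small_spec(m = 60, n_realizations = 60, gap_frac = 0.1)
  pr <- generate_registered_pair(spec, similarity_transform(), noise_sd = 0)
  # control points are generated by the transform itself
  tf <- fit_similarity(pr$control_points)
  expect_equal(tf$scale, 1, tolerance = 1e-9)
  expect_equal(tf$translation, c(0, 0), tolerance = 1e-9)
  # identity + independent ~10% masks: union expectation 1 - 0.9^2 = 0.19
  rec <- compare_pair(pr$base, pr$moving, cp_xy = pr$control_points,
                      refine = FALSE)
  expect_lt(abs(rec$gap_measure - 0.19), 0.03)

  # a scaled pair improves after registration
  tf <- similarity_transform(1.1, 0, c(0, 0))
  pr <- generate_registered_pair(small_spec(m = 40, gap_frac = 0), tf, 0)
  pre <- image_distance(pr$base, warp_image(pr$moving,
                                            similarity_transform(), 40))
  post_rec <- compare_pair(pr$base, pr$moving, cp_xy = pr$control_points)
  expect_lt(post_rec$euclidean, pre)
})
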