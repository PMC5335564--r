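test_that("normalized distance follows the declared geometry", {
  b <- gwbone:::.mode_branch("S0", "S", 0, f = c(0.4, 0.8, 1.2, 1.6),
                             k = c(2, 2, 2, 2))
  expect_equal(normalized_distance(c(0.8, 2), b, 1.6, 6.28), 0)
  # pure-k offset against a flat branch
  expect_equal(normalized_distance(c(0.8, 2 + 0.03 * 6.28), b, 1.6, 6.28),
               0.03, tolerance = 1e-12)
  expect_gt(0.03, 0.025)       # that point is an outlier at default d0
  expect_equal(normalized_distance(c(1, 1), NULL, 1.6, 6.28), Inf)
  # the array resolution matches the default threshold
  expect_equal((pi / 20) / 6.283, 0.025, tolerance = 1e-3)
})

test_that("assignment takes the nearest branch, ties to the earlier slot", {
  # k_max = 8 keeps the normalized coordinates exactly representable, so
  # the midpoint is an exact tie
  b1 <- gwbone:::.mode_branch("A1", "A", 1, f = c(0.5, 1.5), k = c(2, 2))
  b2 <- gwbone:::.mode_branch("S1", "S", 1, f = c(0.5, 1.5), k = c(4, 4))
  dd <- dispersion_data(data.frame(f = c(1, 1, 1), k = c(2.1, 3.9, 3)),
                        f_max = 2, k_max = 8)
  asg <- assign_inliers(dd, list(b1, b2))
  expect_equal(asg$mode, c(1L, 2L, 1L))   # midpoint tie -> earlier branch
  expect_equal(asg$inlier, c(TRUE, TRUE, FALSE))
})

test_that("occupancy is 1 for perfect coverage and 0 for empty pairing", {
  p <- bone_plate(2)
  g <- dispersion_grid()
  br <- trace_plate_modes(p, g)
  dd <- sample_dispersion_points(br, g, extraction_noise_model(sigma_k = 0,
                                                              seed = 3))
  expect_equal(occupancy_rate(p, rep(TRUE, 10), dd), 1)
  expect_equal(occupancy_rate(p, rep(FALSE, 10), dd), 0)
})

test_that("occupancy is invariant to point order and duplication", {
  p <- bone_plate(2)
  g <- dispersion_grid()
  br <- trace_plate_modes(p, g)
  dd <- sample_dispersion_points(br, g, extraction_noise_model(
    sigma_k = pi / 80, n_outliers = 25, seed = 9))
  F1 <- occupancy_rate(p, rep(TRUE, 10), dd)
  perm <- sample(dd$n)
  dd2 <- dispersion_data(dd$points[perm, ], dd$f_max, dd$k_max, dd$L)
  expect_equal(occupancy_rate(p, rep(TRUE, 10), dd2), F1)
  dd3 <- dispersion_data(rbind(dd$points, dd$points), dd$f_max, dd$k_max,
                         dd$L)
  expect_equal(occupancy_rate(p, rep(TRUE, 10), dd3), F1)
})

test_that("candidate modes land in canonical pairing slots", {
  p <- bone_plate(2)
  m <- candidate_lamb_modes(p, dispersion_grid(), 10)
  expect_length(m, 10)
  lab <- gwbone:::.canonical_mode_labels(10)
  for (i in seq_along(m)) {
    if (!is.null(m[[i]])) expect_equal(m[[i]]$label, lab[i])
  }
  expect_equal(lab[1:4], c("A0", "S0", "A1", "S1"))
})


test_that("adding modes never decreases F when activation is off", {
  p <- bone_plate(2)
  g <- dispersion_grid()
  br <- trace_plate_modes(p, g)
  dd <- sample_dispersion_points(br, g, extraction_noise_model(
    sigma_k = pi / 80, n_outliers = 15, seed = 21))
  cfg <- objective_config(alpha_active = 0)
  modes <- candidate_lamb_modes(p, gwbone:::.default_inversion_grid(dd), 10)
  pairing <- rep(FALSE, 10)
  last <- 0
  for (i in 1:10) {
    pairing[i] <- TRUE
    F <- occupancy_rate(NULL, pairing, dd, cfg, modes = modes)
    expect_gte(F, last)
    last <- F
  }
})
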