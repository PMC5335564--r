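test_that("noiseless sampling reproduces branch points exactly", {
  p <- bone_plate(2)
  g <- dispersion_grid()
  br <- trace_plate_modes(p, g)
  dd <- sample_dispersion_points(br, g, extraction_noise_model(sigma_k = 0,
                                                              seed = 5))
  all_pts <- do.call(rbind, lapply(br, function(b) b$points))
  for (i in seq(1, dd$n, by = 23)) {
    d <- sqrt((all_pts[, "f"] - dd$points$f[i])^2 +
                (all_pts[, "k"] - dd$points$k[i])^2)
    expect_lt(min(d), 1e-12)
  }
})

test_that("sampling is reproducible from the seed and adds what it claims", {
  p <- bone_plate(2)
  g <- dispersion_grid()
  br <- trace_plate_modes(p, g)
  nm <- extraction_noise_model(sigma_k = pi / 80, p_drop_point = 0.2,
                               n_outliers = 15, seed = 42)
  d1 <- sample_dispersion_points(br, g, nm)
  d2 <- sample_dispersion_points(br, g, nm)
  expect_identical(d1$points, d2$points)
  d3 <- sample_dispersion_points(br, g, extraction_noise_model(seed = 43))
  expect_false(isTRUE(all.equal(d1$points, d3$points)))
  # dropout thins roughly by the requested fraction
  d0 <- sample_dispersion_points(br, g, extraction_noise_model(seed = 42))
  expect_lt(d1$n - 15, d0$n * 0.9)
})

test_that("occupancy at truth stays high under nominal noise", {
  p <- bone_plate(2)
  g <- dispersion_grid()
  br <- trace_plate_modes(p, g)
  nm <- extraction_noise_model(sigma_k = pi / 80, seed = 7)
  dd <- sample_dispersion_points(br, g, nm)
  expect_gt(occupancy_rate(p, rep(TRUE, 10), dd), 0.95)
})

test_that("RF simulation respects amplitudes, seeds and the Nyquist guard", {
  p <- bone_plate(2)
  g <- dispersion_grid()
  br <- trace_plate_modes(p, g)
  pick <- lapply(br[vapply(br, function(b) b$label, "") %in% c("S1", "A1")],
                 function(b) {
                   b$points <- b$points[b$points[, "k"] < 3.4, , drop = FALSE]
                   b
                 })
  rf0 <- simulate_rf(pick, probe_geometry(), amplitudes = 0, seed = 1)
  expect_true(all(rf0$plus$signals == 0))
  rf1 <- simulate_rf(pick, probe_geometry(), seed = 2)
  rf2 <- simulate_rf(pick, probe_geometry(), seed = 2)
  expect_identical(rf1$plus$signals, rf2$plus$signals)
  expect_equal(dim(rf1$plus$signals), c(5L, 24L, 1024L))
  expect_error(simulate_rf(br, probe_geometry(), seed = 1), "Nyquist")
})
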