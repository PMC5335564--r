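test_that("bulk velocities reproduce the reference arithmetic", {
  v <- bulk_velocities(14.7, 22.1, 4.6, 1.65)
  expect_equal(round(unname(v), 2), c(2.98, 3.66, 1.67))
  # isotropy collapses the two longitudinal velocities
  v2 <- bulk_velocities(20, 20, 5, 1.5)
  expect_equal(v2[["VL1"]], v2[["VL3"]])
  # cortical-range endpoint
  expect_equal(round(sqrt(4.7 / 1.83), 2), 1.60)
  expect_error(bulk_velocities(-1, 22.1, 4.6, 1.65), "positive")
})

test_that("plate constructor enforces the invariants", {
  p <- elastic_plate(2, 0.5, 1.5, 3.66, 1.67)
  expect_equal(p$VL1, 3.66 / sqrt(1.5))
  expect_error(elastic_plate(2, 1.3, 1.5, 3.66, 1.67), "stability")
  expect_error(elastic_plate(2, 0.5, 2.5, 2.0, 1.9), "exceed")
  expect_error(elastic_plate(-2, 0.5, 1.5, 3.66, 1.67), "positive")
})

test_that("bilayer system derives the nondimensional ratios", {
  p <- elastic_plate(1.8, 0.5, 1.5, 3.7, 1.54 / 0.83)
  bs <- bilayer_system(p, rho_s = 1.0 / 0.54, fluid_layer(1.54, 1.0, 2.25))
  nd <- nondim_params(bs)
  expect_equal(unname(nd), c(0.83, 1.25, 0.54), tolerance = 1e-10)
  # c_f = VT gives kappa_f = 1
  bs2 <- bilayer_system(elastic_plate(2, 0.5, 1.5, 3.66, 1.5), 1.65,
                        suppressWarnings(fluid_layer(1.5, 1.0, 4)))
  expect_equal(unname(nondim_params(bs2)[["kappa_f"]]), 1)
  expect_equal(1.00 / 1.65, 0.606, tolerance = 1e-3)
  expect_error(bilayer_system(p, NULL, fluid_layer(1.5, 1, 2)), "rho_s")
})

test_that("fluid layer warns outside the soft-tissue velocity band", {
  expect_warning(fluid_layer(1.2, 1.0, 5), "soft-tissue")
  expect_silent(fluid_layer(1.54, 1.03, 5))
})
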