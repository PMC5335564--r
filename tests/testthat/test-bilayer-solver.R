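test_that("bilayer reduces to the free plate in the decoupled limit", {
  p <- bone_plate(1.25)
  g <- dispersion_grid()
  bs <- bilayer_system(p, rho_s = 1e6,
                       suppressWarnings(fluid_layer(1.5, 1e-6 * 1e6 * 1.65,
                                                    1e-6 * 1.25)))
  # gamma = rho_f/rho_s ~ 1e-6*1.65, tau ~ 1e-6
  bb <- trace_bilayer_modes(bs, g)
  pb <- trace_plate_modes(p, g)
  k_plate <- sort(unlist(lapply(pb, function(b) b$points[, "k"])))
  for (b in bb) {
    for (i in seq(1, nrow(b$points), by = 9)) {
      expect_lt(min(abs(k_plate - b$points[i, "k"])), g$k_step)
    }
  }
})

test_that("the coating generates additional modes", {
  p <- elastic_plate(1.8, 0.5, 1.5, 3.7, 1.54 / 0.83)
  ks <- seq(0.02, 6.28, 0.02)
  n_roots <- function(v) sum(v[-1] * v[-length(v)] < 0)
  np <- n_roots(plate_characteristic(p, 1.4, ks, "S")) +
    n_roots(plate_characteristic(p, 1.4, ks, "A"))
  bs <- bilayer_system(p, 1.0 / 0.54, fluid_layer(1.54, 1.0, 1.25 * 1.8))
  nb <- n_roots(bilayer_characteristic(bs, 1.4, ks))
  expect_gt(nb, np)
})

test_that("mode count grows with coating thickness", {
  p <- bone_plate(1.25)
  counts <- vapply(c(2, 4, 6, 8), function(hf) {
    bs <- bilayer_system(p, bone_ref$rho, fluid_layer(1.43, 1.0, hf))
    length(trace_bilayer_modes(bs, dispersion_grid()))
  }, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("near-rigid solid leaves the closed-form fluid-layer modes", {
  cf <- 1.5; hf <- 6; f0 <- 1.0
  p <- elastic_plate(1.25, 7.6 / 14.7, 22.1 / 14.7, 100 * sqrt(22.1 / 1.65),
                     100 * sqrt(4.6 / 1.65))
  bs <- bilayer_system(p, 165, fluid_layer(cf, 1.0, hf))
  roots <- scan_roots_1d(function(k) bilayer_characteristic(bs, f0, k), 6.3)
  w2 <- (2 * pi * f0)^2
  arg <- w2 / cf^2 - ((2 * (1:10) - 1) * pi / (2 * hf))^2
  k_th <- sqrt(arg[arg > 0])
  for (kt in k_th) {
    expect_lt(min(abs(roots - kt)), 2e-3)
  }
})

test_that("bilayer residual is even in k, finite and normalized", {
  p <- bone_plate(2)
  bs <- bilayer_system(p, bone_ref$rho, fluid_layer(1.43, 1.0, 4))
  k <- c(0.5, 1.7, 3.3, 5.9)
  expect_equal(bilayer_characteristic(bs, 1.0, k),
               bilayer_characteristic(bs, 1.0, -k))
  f <- runif(200, 0.05, 2); kk <- runif(200, 0, 8)
  v <- bilayer_characteristic(bs, f, kk)
  expect_true(all(is.finite(v)))
  expect_true(all(abs(v) <= 1 + 1e-12))
})

test_that("traced bilayer branches satisfy the characteristic equation", {
  p <- bone_plate(1.25)
  bs <- bilayer_system(p, bone_ref$rho, fluid_layer(1.43, 1.0, 4))
  bb <- trace_bilayer_modes(bs, dispersion_grid())
  expect_gt(length(bb), 6)
  for (b in bb[seq(1, length(bb), by = 3)]) {
    r <- bilayer_characteristic(bs, b$points[, "f"], b$points[, "k"])
    expect_lt(max(abs(r)), 1e-6)
  }
})

test_that("mode shapes are singular vectors of the boundary conditions", {
  p <- bone_plate(1.25)
  bs <- bilayer_system(p, bone_ref$rho, fluid_layer(1.43, 1.0, 2))
  bb <- trace_bilayer_modes(bs, dispersion_grid())
  b <- bb[[3]]
  for (i in seq(1, nrow(b$points), by = 11)) {
    M <- gwbone:::.bilayer_bc_matrix(bs, b$points[i, "f"], b$points[i, "k"])$M
    d <- svd(M)$d
    expect_lt(d[6] / d[1], 1e-6)
  }
})

test_that("solid energy fraction separates plate-borne from fluid modes", {
  p <- bone_plate(1.25)
  bs <- bilayer_system(p, bone_ref$rho, fluid_layer(1.54, 1.03, 8))
  bb <- trace_bilayer_modes(bs, dispersion_grid())
  es <- unlist(detection_weights(bs, bb))
  # the gate spreads: some points near 1 (solid-guided), many near 0
  expect_gt(max(es), 0.8)
  expect_lt(min(es), 0.1)
  raw <- solid_energy_fraction(bs, bb[[2]]$points[, "f"], bb[[2]]$points[, "k"])
  expect_true(all(raw >= 0 & raw <= 1))
})
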