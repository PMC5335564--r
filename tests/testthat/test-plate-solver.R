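test_that("isotropic reduction matches the Rayleigh-Lamb oracle", {
  cL <- 5; cT <- 3; h <- 2
  p <- iso_plate(cL, cT, h)
  fs <- seq(0.45, 1.95, length.out = 20)
  worst <- 0
  for (f in fs) {
    for (fam in c("S", "A")) {
      r_pkg <- scan_roots_1d(function(k) plate_characteristic(p, f, k, fam), 8)
      r_orc <- scan_roots_1d(function(k) rayleigh_lamb(h, cL, cT, f, k, fam), 8)
      expect_equal(length(r_pkg), length(r_orc))
      if (length(r_orc)) {
        worst <- max(worst, max(abs(r_pkg - r_orc) / r_orc))
      }
    }
  }
  expect_lt(worst, 0.005)
})

test_that("cut-off frequencies at k ~ 0 sit at n*V/(2h)", {
  p <- bone_plate(2)
  fs <- seq(0.05, 3, by = 5e-4)
  found <- c()
  for (fam in c("S", "A")) {
    v <- plate_characteristic(p, fs, rep(1e-6, length(fs)), fam)
    idx <- which(v[-1] * v[-length(v)] < 0)
    for (i in idx) {
      lo <- fs[i]; hi <- fs[i + 1]
      for (it in 1:40) {
        mid <- (lo + hi) / 2
        if (plate_characteristic(p, mid, 1e-6, fam) *
            plate_characteristic(p, lo, 1e-6, fam) <= 0) hi <- mid else lo <- mid
      }
      found <- c(found, (lo + hi) / 2)
    }
  }
  expected <- sort(c((1:7) * p$VT / (2 * p$h_s), (1:4) * p$VL1 / (2 * p$h_s)))
  expected <- expected[expected < 3]
  for (fe in expected) {
    expect_lt(min(abs(found - fe)) / fe, 1e-4)
  }
})

test_that("bone-mimicking plate has a root below 6.28 rad/mm at 0.5 MHz", {
  p <- bone_plate(1.25)
  vS <- plate_characteristic(p, 0.5, seq(0.02, 6.28, 0.02), "S")
  vA <- plate_characteristic(p, 0.5, seq(0.02, 6.28, 0.02), "A")
  sign_changes <- function(v) sum(v[-1] * v[-length(v)] < 0)
  expect_gte(sign_changes(vS) + sign_changes(vA), 1)
})

test_that("residuals are normalized and finite", {
  p <- bone_plate(3)
  f <- runif(300, 0.05, 2); k <- runif(300, 0, 8)
  for (fam in c("S", "A")) {
    v <- plate_characteristic(p, f, k, fam)
    expect_true(all(is.finite(v)))
    expect_true(all(abs(v) <= 1 + 1e-12))
  }
})

test_that("traced plate branches satisfy the characteristic equation", {
  p <- bone_plate(2)
  br <- trace_plate_modes(p, dispersion_grid())
  expect_gt(length(br), 3)
  for (b in br) {
    r <- plate_characteristic(p, b$points[, "f"], b$points[, "k"], b$family)
    expect_lt(max(abs(r)), 1e-6)
    expect_true(all(diff(b$points[, "f"]) > 0))
  }
})

test_that("S0 tends to the thin-plate longitudinal velocity at low frequency", {
  p <- bone_plate(2)
  g <- dispersion_grid(f_min = 0.02, f_max = 0.3, f_step = 0.01,
                       k_max = 1.5, k_step = 0.005)
  br <- trace_plate_modes(p, g, families = "S")
  s0 <- br[[which(vapply(br, function(b) b$label, "") == "S0")]]
  vp <- 2 * pi * s0$points[1, "f"] / s0$points[1, "k"]
  v_plate <- sqrt((bone_ref$c33 - bone_ref$c13^2 / bone_ref$c11) / bone_ref$rho)
  expect_equal(round(v_plate, 2), 3.32)
  expect_lt(abs(vp - v_plate) / v_plate, 0.01)
})

test_that("A0 follows the thin-plate bending law k ~ sqrt(f)", {
  # the lowest decade available: the bending asymptote only holds for
  # vanishing frequency-thickness product
  p <- bone_plate(2)
  g <- dispersion_grid(f_min = 0.004, f_max = 0.04, f_step = 0.002,
                       k_max = 0.8, k_step = 0.002)
  br <- trace_plate_modes(p, g, families = "A")
  a0 <- br[[1]]
  fit <- stats::lm(log(k) ~ log(f), data = as.data.frame(a0$points))
  expect_equal(unname(coef(fit)[2]), 0.5, tolerance = 0.05)
})
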