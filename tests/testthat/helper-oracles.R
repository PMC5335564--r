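# Reference materials and independent oracles used across the tests.

bone_ref <- list(c11 = 14.7, c33 = 22.1, c13 = 7.6, c55 = 4.6, rho = 1.65)

# Classical Rayleigh-Lamb characteristic function for an isotropic plate
# (independent of the package's partial-wave construction).
rayleigh_lamb <- function(h, cL, cT, f, k, family) {
  w <- 2 * pi * f
  p <- sqrt(as.complex(w^2 / cL^2 - k^2))
  q <- sqrt(as.complex(w^2 / cT^2 - k^2))
  hh <- h / 2
  q2k2 <- w^2 / cT^2 - 2 * k^2   # q^2 - k^2
  if (family == "S") {
    Re(q2k2^2 * cos(p * hh) * sin(q * hh) / q +
         4 * k^2 * p * sin(p * hh) * cos(q * hh))
  } else {
    Re(q2k2^2 * sin(p * hh) * cos(q * hh) / p +
         4 * k^2 * q * cos(p * hh) * sin(q * hh))
  }
}

# Brute-force scan + bisection root finder on a 1-d function of k.
scan_roots_1d <- function(fun, k_max, k_step = 0.002) {
  ks <- seq(k_step, k_max, by = k_step)
  v <- vapply(ks, fun, 0)
  idx <- which(v[-1] * v[-length(v)] < 0)
  vapply(idx, function(i) {
    lo <- ks[i]; hi <- ks[i + 1]
    for (it in 1:50) {
      mid <- (lo + hi) / 2
      if (fun(mid) * fun(lo) <= 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }, 0)
}

iso_plate <- function(cL = 5, cT = 3, h = 2) {
  # isotropic limit: c11 = c33, c13 = c11 - 2 c55
  elastic_plate(h_s = h, r13 = (cL^2 - 2 * cT^2) / cL^2, r33 = 1,
                VL3 = cL, VT = cT)
}

bone_plate <- function(h) {
  plate_from_stiffness(bone_ref$c11, bone_ref$c33, bone_ref$c13,
                       bone_ref$c55, bone_ref$rho, h)
}

two_mode_rf <- function(seed = 7, tilt = 0, noise_floor = 0.02) {
  p <- bone_plate(2)
  g <- dispersion_grid()
  br <- trace_plate_modes(p, g)
  pick <- lapply(br[vapply(br, function(b) b$label, "") %in% c("S1", "A1")],
                 function(b) {
                   b$points <- b$points[b$points[, "k"] < 3.4, , drop = FALSE]
                   b
                 })
  list(branches = pick,
       rf = simulate_rf(pick, probe_geometry(), noise_floor = noise_floor,
                        tilt = tilt, seed = seed))
}

truth_error <- function(dd, branches) {
  vapply(seq_len(dd$n), function(i) {
    f0 <- dd$points$f[i]
    kt <- vapply(branches, function(b) {
      rng <- range(b$points[, "f"])
      if (f0 >= rng[1] && f0 <= rng[2]) {
        stats::approx(b$points[, "f"], b$points[, "k"], xout = f0)$y
      } else NA_real_
    }, 0)
    min(abs(dd$points$k[i] - kt), na.rm = TRUE)
  }, 0)
}

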