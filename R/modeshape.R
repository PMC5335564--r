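# Bilayer mode shapes and the solid-layer energy fraction.
#
# At a dispersion root the six partial-wave amplitudes (four solid
# combinations, two fluid) span the null space of the boundary-condition
# matrix. From them the displacement field across the thickness follows, and
# with it the share of the mode's (kinetic) energy carried by the solid
# layer. That share is what makes a mode detectable in an axial-transmission
# measurement dominated by the solid subsystem: coupled modes riding the
# solid plate keep a large solid share, nearly pure fluid-layer resonances a
# small one.

# 6x6 complex boundary-condition matrix at (f, k); columns are the two
# sin/cos combinations of each solid partial wave and the two fluid
# amplitudes (P, Q); rows: bottom normal/shear stress, interface shear,
# normal stress, normal displacement, top pressure.
.bilayer_bc_matrix <- function(system, f, k) {
  plate <- system$plate
  al <- plate$VL1^2; be <- plate$VL3^2
  de <- plate$r13 * al; ga <- plate$VT^2
  w2 <- (2 * pi * f)^2; k2 <- k^2
  A2c <- al * ga
  A1c <- al * (be * k2 - w2) + ga * (ga * k2 - w2) - (de + ga)^2 * k2
  A0c <- (ga * k2 - w2) * (be * k2 - w2)
  sq <- sqrt(as.complex(A1c^2 - 4 * A2c * A0c))
  X <- c((-A1c + sq) / (2 * A2c), (-A1c - sq) / (2 * A2c))
  q <- sqrt(X)
  hs <- plate$h_s
  wa <- al * X + ga * k2 - w2
  ahat <- (de + ga) * k
  Fj <- al * ahat * X - de * k * wa
  Gh <- k * ahat - wa               # (k a - q w)/q
  ch <- cos(q * hs)
  sh <- sin(q * hs)
  fl <- system$fluid
  qf <- sqrt(as.complex(w2 / fl$c_f^2 - k2))
  grho <- fl$rho_f / system$rho_s
  M <- matrix(0 + 0i, 6, 6)
  # columns: A1, B1, A2, B2, P, Q  (A: u1 ~ a sin(qz); B: u1 ~ a cos(qz))
  for (j in 1:2) {
    cA <- 2L * j - 1L; cB <- 2L * j
    M[1, cA] <- Fj[j]                       # sigma11 at z = 0
    M[2, cB] <- q[j] * Gh[j]                # sigma13 at z = 0
    M[3, cA] <- Gh[j] * q[j] * sh[j]        # sigma13 at z = hs
    M[3, cB] <- q[j] * Gh[j] * ch[j]
    M[4, cA] <- Fj[j] * ch[j]               # sigma11 + fluid pressure
    M[4, cB] <- -Fj[j] * sh[j]
    M[5, cA] <- ahat * q[j] * sh[j]         # u1 continuity
    M[5, cB] <- ahat * q[j] * ch[j]
  }
  M[4, 6] <- grho * w2
  M[5, 5] <- -qf
  M[6, 5] <- sin(qf * fl$h_f)
  M[6, 6] <- cos(qf * fl$h_f)
  list(M = M, q = q, qf = qf, ahat = ahat, wa = wa)
}

# Mode-shape metrics at bilayer roots: solid share of the mean
# kinetic-energy density, and the squared top-surface displacement per unit
# mean energy density (what an axial-transmission probe resting on the
# coating actually senses).
.mode_metrics <- function(system, f, k, n_nodes = 33L) {
  n <- max(length(f), length(k))
  f <- rep_len(f, n); k <- rep_len(k, n)
  plate <- system$plate
  fl <- system$fluid
  es <- numeric(n); D <- numeric(n)
  zs <- seq(0, plate$h_s, length.out = n_nodes)
  yf <- seq(0, fl$h_f, length.out = n_nodes)
  for (i in seq_len(n)) {
    bc <- .bilayer_bc_matrix(system, f[i], k[i])
    amp <- svd(bc$M)$v[, 6L]
    A <- amp[c(1L, 3L)]; B <- amp[c(2L, 4L)]
    P <- amp[5L]; Q <- amp[6L]
    q <- bc$q
    u1 <- rep(0 + 0i, n_nodes); u3 <- rep(0 + 0i, n_nodes)
    for (j in 1:2) {
      aj <- bc$ahat * q[j]; wj <- bc$wa[j]
      sn <- sin(q[j] * zs); cn <- cos(q[j] * zs)
      u1 <- u1 + aj * (A[j] * sn + B[j] * cn)
      u3 <- u3 + wj * (A[j] * cn - B[j] * sn)
    }
    dens_s <- mean(Mod(u1)^2 + Mod(u3)^2) * system$rho_s
    qf <- bc$qf
    phi <- P * sin(qf * yf) + Q * cos(qf * yf)
    u1f <- qf * (P * cos(qf * yf) - Q * sin(qf * yf))
    dens_f <- mean(Mod(u1f)^2 + (k[i]^2) * Mod(phi)^2) * fl$rho_f
    es[i] <- Re(dens_s) / (Re(dens_s) + Re(dens_f) + 1e-300)
    u1top <- qf * (P * cos(qf * fl$h_f) - Q * sin(qf * fl$h_f))
    mean_dens <- (Re(dens_s) * plate$h_s + Re(dens_f) * fl$h_f) /
      (plate$h_s + fl$h_f)
    D[i] <- Mod(u1top)^2 / (mean_dens + 1e-300)
  }
  list(es = es, D = D)
}

#' Solid-layer energy fraction of bilayer modes
#'
#' For points on a bilayer dispersion branch, computes the solid layer's
#' share of the mode's mean kinetic-energy density (energy per unit
#' thickness, so a thick coating does not dominate by volume alone). Values
#' near 1 indicate modes carried by the solid plate (the detectable
#' fingerprints of the bone mimic); values near 0 indicate nearly pure
#' fluid-layer resonances, which an axial-transmission measurement picks up
#' only sporadically.
#'
#' @param system A [bilayer_system()].
#' @param f,k Vectors of root coordinates (points on traced branches).
#' @param n_nodes Integration nodes per layer.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
solid_energy_fraction <- function(system, f, k, n_nodes = 33L) {
  .mode_metrics(system, f, k, n_nodes)$es
}

#' Top-surface detectability of bilayer modes
#'
#' Squared normal displacement at the free coating surface per unit mean
#' kinetic-energy density of the mode. This is what a probe resting on top
#' of the coating senses: supersonic modes (phase velocity above the fluid
#' velocity) carry a standing pressure pattern through the coating and have
#' order-one values regardless of coating thickness; subsonic plate modes
#' (notably A0) decay evanescently through the coating and lose an order of
#' magnitude per few tail lengths, which is why A0 is usable under thin
#' coatings and poor under thick ones.
#'
#' @inheritParams solid_energy_fraction
#' @return Numeric vector (dimensionless, order 1 for well-coupled modes).
#' @export
top_surface_detectability <- function(system, f, k, n_nodes = 33L) {
  .mode_metrics(system, f, k, n_nodes)$D
}

#' Detection weights for bilayer branches
#'
#' Per-point detection probabilities for a list of traced bilayer branches:
#' a steep logistic gate on the solid-layer energy fraction of each root.
#' The gate emulates the hard thresholds of the extraction chain (the Norm
#' peak floor and the repetition vote): modes carried by the solid plate are
#' recovered almost everywhere, hybrid segments sporadically, and nearly
#' pure fluid resonances only as scattered low-phase-velocity points -- the
#' composition observed in coated-phantom measurements.
#'
#' @param system The [bilayer_system()] the branches belong to.
#' @param branches List of `mode_branch` from [trace_bilayer_modes()].
#' @param midpoint,scale Logistic gate parameters on the energy fraction:
#'   detection probability `plogis((es - midpoint)/scale)`.
#' @return List of numeric vectors, parallel to `branches`.
#' @export
detection_weights <- function(system, branches, midpoint = 0.65,
                              scale = 0.1) {
  lapply(branches, function(b) {
    es <- solid_energy_fraction(system, b$points[, "f"], b$points[, "k"])
    stats::plogis((es - midpoint) / scale)
  })
}
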