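# Characteristic (dispersion) functions for the free plate and the bilayer.
#
# Both are built by the partial-wave method. In the sagittal plane the
# Christoffel equation of the transverse-isotropic solid gives, at fixed
# (f, k), a quadratic in X = q^2 (q = through-thickness wavenumber):
#
#   (al*X + ga*k^2 - w^2) * (ga*X + be*k^2 - w^2) = (de + ga)^2 * k^2 * X
#
# with al = VL1^2 = c11/rho, be = VL3^2 = c33/rho, de = c13/rho, ga = VT^2,
# w = 2*pi*f. Propagation is along x3 (the fiber/bone axis), thickness along
# x1. For each root X_j the partial-wave polarization is
# (a_j, w_j) = ((de+ga)*k*q_j, al*X_j + ga*k^2 - w^2), and the interface
# quantities per unit amplitude are
#   sigma11 ~ F_j = al*a_j*q_j - de*k*w_j,  sigma13 ~ G_j = k*a_j - q_j*w_j.
#
# All expressions are arranged to be even in each q_j, i.e. functions of X_j
# alone, so the residual is real whether the partial waves are propagating
# (X > 0), evanescent (X < 0), or a complex-conjugate pair. Real roots take a
# trigonometric/hyperbolic real path; complex-conjugate pairs fall back to
# complex arithmetic whose result is real by symmetry. Antisymmetric
# combinations are divided by (X1 - X2), which removes the removable zero the
# raw determinant has where the two partial waves degenerate. The
# symmetric-family determinant (and the bilayer determinant) carries a
# structural factor (ga*k^2 - w^2) vanishing on the transverse bulk-wave line
# k = w/VT without a guided mode existing there; it is divided out so that
# sign-change scans do not pick up that line. Finally the residual is
# normalized by the magnitude of its constituent terms, which bounds it to
# [-1, 1] and prevents overflow-driven false roots.

# cos(q*L) and sin(q*L)/q as functions of X = q^2, valid for real (either
# sign) and complex X.
.cosq <- function(X, L) {
  if (is.complex(X)) return(cos(sqrt(X) * L))
  out <- numeric(length(X))
  pos <- X >= 0
  out[pos] <- cos(sqrt(X[pos]) * L)
  out[!pos] <- cosh(sqrt(-X[!pos]) * L)
  out
}

.sincq <- function(X, L) {
  if (is.complex(X)) {
    q <- sqrt(X)
    out <- sin(q * L) / q
    small <- Mod(X) <= 1e-24
    if (any(small)) out[small] <- L
    return(out)
  }
  out <- numeric(length(X))
  pos <- X > 1e-24
  neg <- X < -1e-24
  mid <- !pos & !neg
  qp <- sqrt(X[pos]); qn <- sqrt(-X[neg])
  out[pos] <- sin(qp * L) / qp
  out[neg] <- sinh(qn * L) / qn
  out[mid] <- L
  out
}

.clip_zero <- function(g) {
  small <- abs(g) < 1e-30
  if (any(small)) g[small] <- 1e-30
  g
}

# Residual core shared by the real and complex root regimes.
# All inputs are vectors of the same length; X1/X2 real or complex.
.plate_residual <- function(X1, X2, k, k2, w2, al, de, ga, hh, family) {
  ahat <- (de + ga) * k
  wa1 <- al * X1 + ga * k2 - w2
  wa2 <- al * X2 + ga * k2 - w2
  F1 <- al * ahat * X1 - de * k * wa1
  F2 <- al * ahat * X2 - de * k * wa2
  G1 <- k * ahat - wa1
  G2 <- k * ahat - wa2
  c1 <- .cosq(X1, hh); c2 <- .cosq(X2, hh)
  s1 <- .sincq(X1, hh); s2 <- .sincq(X2, hh)
  if (family == "S") {
    P1 <- F1 * c1; P2 <- F2 * c2
    Q1 <- G1 * s1 * X1; Q2 <- G2 * s2 * X2
    g <- .clip_zero(ga * k2 - w2)
  } else {
    P1 <- F1 * s1; P2 <- F2 * s2
    Q1 <- G1 * c1; Q2 <- G2 * c2
    g <- 1
  }
  dX <- X1 - X2
  num <- Re((P1 * Q2 - P2 * Q1) / (dX * g))
  den <- (Mod(P1 * Q2) + Mod(P2 * Q1)) / (Mod(dX) * abs(g)) + 1e-300
  num / den
}

.bilayer_residual <- function(X1, X2, k, k2, w2, al, de, ga, hs,
                              cf, hf, grho) {
  ahat <- (de + ga) * k
  wa1 <- al * X1 + ga * k2 - w2
  wa2 <- al * X2 + ga * k2 - w2
  F1 <- al * ahat * X1 - de * k * wa1
  F2 <- al * ahat * X2 - de * k * wa2
  G1 <- k * ahat - wa1
  G2 <- k * ahat - wa2
  ch1 <- .cosq(X1, hs); ch2 <- .cosq(X2, hs)
  sh1 <- .sincq(X1, hs); sh2 <- .sincq(X2, hs)
  dX <- X1 - X2
  s1 <- (F2 * G1 * sh1 * X1 - F1 * G2 * sh2 * X2) / dX
  s2 <- (F1 * F2 * (ch1 - ch2)) / dX
  s3 <- ahat * (F2 * sh1 * X1 - F1 * sh2 * X2) / dX
  t1 <- (G1 * G2 * (ch1 - ch2)) / dX
  t2 <- -(F1 * G2 * sh1 - F2 * G1 * sh2) / dX
  t3 <- ahat * (G2 * ch1 - G1 * ch2) / dX
  Xf <- w2 / cf^2 - k2
  if (is.complex(X1)) Xf <- as.complex(Xf)
  sincf <- .sincq(Xf, hf)
  cosf <- .cosq(Xf, hf)
  g <- .clip_zero(ga * k2 - w2)
  T1 <- grho * w2 * sincf * (s1 * t3 - s3 * t1)
  T2 <- cosf * (s1 * t2 - s2 * t1)
  num <- Re((T1 - T2) / g)
  den <- (Mod(T1) + Mod(T2)) / abs(g) + 1e-300
  num / den
}

# Christoffel roots: list(X1, X2, regime split); real where the discriminant
# allows, complex-conjugate pair otherwise.
.christoffel_roots <- function(al, be, de, ga, w2, k2) {
  A2 <- al * ga
  A1 <- al * (be * k2 - w2) + ga * (ga * k2 - w2) - (de + ga)^2 * k2
  A0 <- (ga * k2 - w2) * (be * k2 - w2)
  disc <- A1^2 - 4 * A2 * A0
  real <- disc >= 0
  out <- list(real = real)
  if (any(real)) {
    s <- sqrt(disc[real])
    out$X1r <- (-A1[real] + s) / (2 * A2)
    out$X2r <- (-A1[real] - s) / (2 * A2)
  }
  if (any(!real)) {
    s <- sqrt(as.complex(disc[!real]))
    out$X1c <- (-A1[!real] + s) / (2 * A2)
    out$X2c <- (-A1[!real] - s) / (2 * A2)
  }
  out
}

#' Free-plate characteristic function
#'
#' Real, scale-normalized residual whose zeros in the (f, k) plane are the
#' symmetric (S) or antisymmetric (A) Lamb modes of the traction-free
#' transverse-isotropic plate. Vectorized over `f` and `k` (recycled to a
#' common length).
#'
#' @param plate An [elastic_plate()].
#' @param f Frequency in MHz (> 0).
#' @param k Wavenumber in rad/mm (>= 0); the function is even in `k`.
#' @param family `"S"` for symmetric modes, `"A"` for antisymmetric.
#' @return Numeric vector of residuals in `[-1, 1]`.
#' @seealso [trace_plate_modes()]
#' @export
plate_characteristic <- function(plate, f, k, family = c("S", "A")) {
  stopifnot(inherits(plate, "elastic_plate"))
  family <- family[1L]
  if (!family %in% c("S", "A")) stop("family must be \"S\" or \"A\"")
  if (any(f <= 0)) stop("f must be positive")
  n <- max(length(f), length(k))
  f <- rep_len(f, n); k <- rep_len(k, n)
  al <- plate$VL1^2
  .plate_char_cpp(al, plate$VL3^2, plate$r13 * al, plate$VT^2,
                  plate$h_s / 2, f, k, family == "S")
}

#' Bilayer characteristic function
#'
#' Residual whose zeros are the guided modes of an ideal-fluid layer bonded to
#' a transverse-isotropic plate. The determinant couples six partial waves
#' (two in the fluid, four in the solid) through: zero pressure at the free
#' fluid surface, continuity of normal displacement and normal stress plus
#' zero shear stress at the interface (the fluid sustains no shear), and a
#' traction-free solid bottom. In the decoupled limit (`gamma -> 0`,
#' `tau -> 0`) its zero set converges to the free-plate modes.
#'
#' @param system A [bilayer_system()].
#' @inheritParams plate_characteristic
#' @return Numeric vector of residuals in `[-1, 1]`.
#' @seealso [trace_bilayer_modes()]
#' @export
bilayer_characteristic <- function(system, f, k) {
  stopifnot(inherits(system, "bilayer_system"))
  if (any(f <= 0)) stop("f must be positive")
  n <- max(length(f), length(k))
  f <- rep_len(f, n); k <- rep_len(k, n)
  plate <- system$plate
  al <- plate$VL1^2; be <- plate$VL3^2
  de <- plate$r13 * al; ga <- plate$VT^2
  w2 <- (2 * pi * f)^2; k2 <- k^2
  cr <- .christoffel_roots(al, be, de, ga, w2, k2)
  fl <- system$fluid
  grho <- fl$rho_f / system$rho_s
  out <- numeric(n)
  if (any(cr$real)) {
    i <- cr$real
    out[i] <- .bilayer_residual(cr$X1r, cr$X2r, k[i], k2[i], w2[i],
                                al, de, ga, plate$h_s,
                                fl$c_f, fl$h_f, grho)
  }
  if (any(!cr$real)) {
    i <- !cr$real
    out[i] <- .bilayer_residual(cr$X1c, cr$X2c, k[i], k2[i], w2[i],
                                al, de, ga, plate$h_s,
                                fl$c_f, fl$h_f, grho)
  }
  out
}
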