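# Synthetic data emulating axial-transmission guided-wave experiments:
# dispersion point clouds with extraction-like noise, and multichannel RF
# acquisitions for the full extraction chain.

#' Extraction noise model for synthetic dispersion clouds
#'
#' Statistical model of what dispersion-curve extraction does to the ideal
#' mode branches: Gaussian wavenumber scatter at the scale of the array
#' resolution pi/L, whole branches missing (weakly excited modes), per-point
#' dropout, and uniform outlier points (for instance soft-tissue arrivals at
#' low phase velocity).
#'
#' @param sigma_k Gaussian wavenumber noise standard deviation in rad/mm.
#'   Default pi/80, i.e. a quarter of the resolution pi/L of a 20 mm array.
#' @param p_drop_branch Probability that a branch is missing entirely.
#' @param p_drop_point Per-point dropout probability.
#' @param n_outliers Number of uniform outliers added over the window.
#' @param seed Integer seed; the generator is fully reproducible.
#' @return An object of class `extraction_noise_model`.
#' @export
extraction_noise_model <- function(sigma_k = pi / 80, p_drop_branch = 0,
                                   p_drop_point = 0, n_outliers = 0,
                                   seed = 1L) {
  stopifnot(sigma_k >= 0,
            p_drop_branch >= 0, p_drop_branch <= 1,
            p_drop_point >= 0, p_drop_point <= 1,
            n_outliers >= 0)
  structure(list(sigma_k = sigma_k, p_drop_branch = p_drop_branch,
                 p_drop_point = p_drop_point,
                 n_outliers = as.integer(n_outliers),
                 seed = as.integer(seed)),
            class = "extraction_noise_model")
}

#' Dispersion data point cloud
#'
#' Container for extracted or synthetic (f, k) pairs together with the window
#' and array metadata that the inversion normalizes by.
#'
#' @param points Data frame (or 2-column matrix) with columns `f` (MHz) and
#'   `k` (rad/mm).
#' @param f_max,k_max Window edges used for normalization.
#' @param L Receiver array length in mm (sets the resolution pi/L).
#' @return An object of class `dispersion_data` with fields `points`,
#'   `f_max`, `k_max`, `L`, `n`.
#' @export
dispersion_data <- function(points, f_max = 1.6, k_max = 6.28, L = 20) {
  points <- as.data.frame(points)
  if (!all(c("f", "k") %in% names(points))) {
    colnames(points)[1:2] <- c("f", "k")
  }
  points <- points[, c("f", "k")]
  if (nrow(points) < 1L) stop("dispersion data needs at least one point")
  if (any(points$f < 0 | points$f > f_max | points$k < 0 | points$k > k_max)) {
    stop("all points must lie inside [0, f_max] x [0, k_max]")
  }
  structure(list(points = points, f_max = f_max, k_max = k_max, L = L,
                 n = nrow(points)),
            class = "dispersion_data")
}

#' @export
print.dispersion_data <- function(x, ...) {
  cat(sprintf("Dispersion data: %d points, window [0, %.3g] MHz x [0, %.3g] rad/mm, L = %.3g mm\n",
              x$n, x$f_max, x$k_max, x$L))
  invisible(x)
}

#' Sample a noisy dispersion point cloud from mode branches
#'
#' Emulates the output of the dispersion-extraction chain for a waveguide
#' whose true branches are known: branch points at the grid frequencies are
#' perturbed in k, thinned, and polluted with uniform outliers.
#'
#' @param branches List of `mode_branch` objects (from [trace_plate_modes()]
#'   or [trace_bilayer_modes()]).
#' @param grid The [dispersion_grid()] defining the sampling window.
#' @param noise An [extraction_noise_model()].
#' @param L Array length in mm stored in the result (resolution metadata).
#' @param weights Optional list of per-point detection probabilities parallel
#'   to `branches` (see [detection_weights()]); each branch point is kept
#'   with its probability before the dropout thinning is applied.
#' @return A [dispersion_data()] object.
#' @export
sample_dispersion_points <- function(branches, grid,
                                     noise = extraction_noise_model(),
                                     L = 20, weights = NULL) {
  stopifnot(inherits(grid, "dispersion_grid"),
            inherits(noise, "extraction_noise_model"))
  if (!length(branches)) stop("no branches supplied")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(noise$seed)
  fs <- numeric(0); ks <- numeric(0)
  for (bi in seq_along(branches)) {
    b <- branches[[bi]]
    if (stats::runif(1) < noise$p_drop_branch) next
    f <- b$points[, "f"]; k <- b$points[, "k"]
    keep <- stats::runif(length(f)) >= noise$p_drop_point
    if (!is.null(weights)) {
      keep <- keep & (stats::runif(length(f)) < weights[[bi]])
    }
    f <- f[keep]; k <- k[keep]
    if (!length(f)) next
    k <- k + stats::rnorm(length(k), sd = noise$sigma_k)
    ok <- f <= grid$f_max & f >= 0 & k >= 0 & k <= grid$k_max
    fs <- c(fs, f[ok]); ks <- c(ks, k[ok])
  }
  if (noise$n_outliers > 0) {
    fs <- c(fs, stats::runif(noise$n_outliers, grid$f_min, grid$f_max))
    ks <- c(ks, stats::runif(noise$n_outliers, 0, grid$k_max))
  }
  if (!length(fs)) {
    stop("no branch intersects the sampling window: empty dispersion data")
  }
  dispersion_data(data.frame(f = fs, k = ks),
                  f_max = grid$f_max, k_max = grid$k_max, L = L)
}

# Save/restore .Random.seed so seeded generators do not disturb the caller's
# RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Axial-transmission probe geometry
#'
#' Geometry and acquisition settings of the multichannel probe: a receiving
#' array flanked by two emitter arrays, one per propagation direction.
#' Defaults describe a 24-receiver array spanning about 20 mm, two groups of
#' 5 emitters, wideband pulses centered at 1 MHz sampled at 20 MHz over 1024
#' samples.
#'
#' @param n_receivers,receiver_pitch Receiver count and spacing (mm).
#' @param n_emitters_per_side,emitter_pitch Emitters per side and spacing (mm).
#' @param emitter_gap Gap between the emitter array and the first receiver (mm).
#' @param fs Sampling rate in MHz.
#' @param n_samples Samples per trace.
#' @param f_center Pulse center frequency in MHz.
#' @param band Usable band in MHz (-6 dB span of the pulse spectrum).
#' @return An object of class `probe_geometry`; field `L` holds the receiver
#'   aperture `(n_receivers - 1) * receiver_pitch`.
#' @export
probe_geometry <- function(n_receivers = 24L, receiver_pitch = 0.87,
                           n_emitters_per_side = 5L, emitter_pitch = 1.0,
                           emitter_gap = 2.0, fs = 20, n_samples = 1024L,
                           f_center = 1.0, band = c(0.4, 1.6)) {
  stopifnot(n_receivers >= 2, receiver_pitch > 0, n_emitters_per_side >= 1,
            emitter_pitch > 0, emitter_gap >= 0, fs > 0, n_samples >= 16)
  if (fs / 2 <= band[2]) stop("sampling rate must satisfy fs/2 > band upper edge")
  structure(list(n_receivers = as.integer(n_receivers),
                 receiver_pitch = receiver_pitch,
                 n_emitters_per_side = as.integer(n_emitters_per_side),
                 emitter_pitch = emitter_pitch, emitter_gap = emitter_gap,
                 fs = fs, n_samples = as.integer(n_samples),
                 f_center = f_center, band = band,
                 L = (n_receivers - 1) * receiver_pitch),
            class = "probe_geometry")
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat(sprintf("Probe: %d receivers (pitch %.3g mm, L = %.3g mm), 2 x %d emitters\n",
              x$n_receivers, x$receiver_pitch, x$L, x$n_emitters_per_side))
  cat(sprintf("  fs = %.3g MHz, %d samples, pulse %.3g MHz, band [%.3g, %.3g] MHz\n",
              x$fs, x$n_samples, x$f_center, x$band[1], x$band[2]))
  invisible(x)
}

#' Simulate a bidirectional multichannel RF acquisition
#'
#' Synthesizes the per-emitter, per-receiver time series that the probe would
#' record for a waveguide with known dispersion branches. Every trace is the
#' inverse Fourier transform of a sum over branches of
#' `a_m(f) * G(f) * exp(i k_m(f) x)`, where `G` is the Gaussian pulse
#' spectrum, `k_m(f)` the branch wavenumber and `x` the emitter-receiver
#' distance. A probe inclination (tilt) rescales the apparent wavenumber by
#' `1 + tilt*1e-3` in one direction and `1 - tilt*1e-3` in the other, which
#' is the bias the bidirectional correction is designed to cancel. White
#' Gaussian noise is added at `noise_floor` times the signal RMS.
#'
#' @param branches List of `mode_branch` objects; each branch must be a
#'   single-valued function k(f) over its span.
#' @param probe A [probe_geometry()].
#' @param amplitudes Per-branch spectral weights (recycled); default 1.
#' @param noise_floor Additive white noise level relative to signal RMS.
#' @param tilt Probe inclination in mrad.
#' @param seed Integer seed for the noise.
#' @return List with elements `plus` and `minus`, each of class
#'   `rf_acquisition` with fields `signals` (emitter x receiver x sample
#'   array), `direction` and `geometry`.
#' @export
simulate_rf <- function(branches, probe = probe_geometry(), amplitudes = 1,
                        noise_floor = 0, tilt = 0, seed = 1L) {
  stopifnot(inherits(probe, "probe_geometry"))
  if (!length(branches)) stop("no branches supplied")
  kmax_br <- max(vapply(branches, function(b) max(b$points[, "k"]), 0))
  if (kmax_br * probe$receiver_pitch > pi) {
    stop(sprintf(paste0("branch wavenumbers reach %.3g rad/mm but the spatial ",
                        "Nyquist limit of the receiver pitch is pi/%.3g = %.3g rad/mm"),
                 kmax_br, probe$receiver_pitch, pi / probe$receiver_pitch))
  }
  amplitudes <- rep_len(amplitudes, length(branches))
  ns <- probe$n_samples
  freqs <- (0:(ns %/% 2)) * probe$fs / ns
  # -6 dB (amplitude 1/2) at the band edges
  half_bw <- (probe$band[2] - probe$band[1]) / 2
  sigma_f <- half_bw / sqrt(2 * log(2))
  G <- exp(-(freqs - probe$f_center)^2 / (2 * sigma_f^2))
  x_rec <- (seq_len(probe$n_receivers) - 1L) * probe$receiver_pitch
  x_emit <- probe$emitter_gap + (seq_len(probe$n_emitters_per_side) - 1L) *
    probe$emitter_pitch
  eps <- tilt * 1e-3
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # branch weights and interpolated wavenumbers on the FFT frequency bins
  nfreq <- length(freqs)
  weights <- matrix(0, nfreq, length(branches))
  kf_mat <- matrix(0, nfreq, length(branches))
  for (m in seq_along(branches)) {
    b <- branches[[m]]$points
    inside <- freqs >= min(b[, "f"]) & freqs <= max(b[, "f"])
    kf_mat[inside, m] <- stats::approx(b[, "f"], b[, "k"],
                                       xout = freqs[inside])$y
    weights[inside, m] <- amplitudes[m] * G[inside]
  }
  # emitter-receiver distances, one column per (emitter, receiver) pair
  dist <- as.vector(outer(x_rec, x_emit, "+"))           # receiver fastest
  make_dir <- function(direction) {
    kfac <- if (direction == "+") 1 + eps else 1 - eps
    spec <- matrix(0 + 0i, nfreq, length(dist))
    for (m in seq_along(branches)) {
      spec <- spec + weights[, m] *
        exp(-1i * kfac * outer(kf_mat[, m], dist))
    }
    # hermitian completion and inverse FFT, trace by trace
    sig <- array(0, dim = c(probe$n_emitters_per_side, probe$n_receivers, ns))
    for (j in seq_along(dist)) {
      full <- c(spec[, j], Conj(rev(spec[seq(2, nfreq - 1L), j])))
      tr <- Re(stats::fft(full, inverse = TRUE)) / ns
      e <- (j - 1L) %/% probe$n_receivers + 1L
      r <- (j - 1L) %% probe$n_receivers + 1L
      sig[e, r, ] <- tr
    }
    if (noise_floor > 0) {
      rms <- sqrt(mean(sig^2))
      sig <- sig + array(stats::rnorm(length(sig), sd = noise_floor * rms),
                         dim = dim(sig))
    }
    structure(list(direction = direction, signals = sig, geometry = probe),
              class = "rf_acquisition")
  }
  list(plus = make_dir("+"), minus = make_dir("-"))
}
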