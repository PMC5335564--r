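# Dispersion-curve extraction from multichannel RF acquisitions:
# time FFT -> per-frequency response matrix -> SVD signal subspace ->
# Norm function -> peak picking -> bidirectional correction ->
# repetition denoising -> direction merging.

#' Build the per-frequency response matrix
#'
#' Fourier transforms every emitter-receiver trace with respect to time and
#' collects, for each frequency bin inside the probe band, the complex
#' receivers x emitters matrix.
#'
#' @param rf An `rf_acquisition` (see [simulate_rf()]).
#' @return An object of class `response_matrix`: list with `freqs` (MHz) and
#'   `R` (list of complex matrices, receivers x emitters).
#' @export
build_response_matrix <- function(rf) {
  stopifnot(inherits(rf, "rf_acquisition"))
  probe <- rf$geometry
  ns <- probe$n_samples
  if (probe$fs / 2 <= probe$band[2]) {
    stop("band upper edge exceeds the temporal Nyquist frequency")
  }
  freqs <- (0:(ns - 1)) * probe$fs / ns
  sel <- which(freqs >= probe$band[1] & freqs <= probe$band[2])
  ne <- probe$n_emitters_per_side
  nr <- probe$n_receivers
  # FFT along time for all traces: reshape to (ne*nr) x ns
  flat <- matrix(rf$signals, nrow = ne * nr, ncol = ns)
  spec <- t(stats::mvfft(t(flat)))          # rows: traces, cols: bins
  R <- lapply(sel, function(b) {
    matrix(spec[, b], nrow = nr, ncol = ne, byrow = TRUE)
  })
  # flat row index runs emitter fastest (array dim 1), so byrow = TRUE above
  # places receivers in rows
  structure(list(freqs = freqs[sel], R = R, geometry = probe),
            class = "response_matrix")
}

#' Per-frequency singular basis of the response matrix
#'
#' Applies a singular value decomposition to the response matrix at each
#' frequency and keeps the `n_keep` left singular vectors (receiver space)
#' associated with the largest singular values. Dropping the weakest singular
#' directions removes spatially incoherent noise.
#'
#' @param R A `response_matrix`.
#' @param n_keep Number of singular vectors kept (1 to number of emitters).
#' @return Object of class `singular_basis`: list with `freqs` and `U` (list
#'   of receivers x n_keep orthonormal matrices; `NULL` entries for
#'   degenerate all-zero matrices, with a warning).
#' @export
svd_denoise <- function(R, n_keep = 3L) {
  stopifnot(inherits(R, "response_matrix"))
  ne <- ncol(R$R[[1]])
  if (n_keep < 1 || n_keep > ne) stop("n_keep must be in 1..n_emitters")
  degenerate <- FALSE
  U <- lapply(R$R, function(m) {
    if (all(m == 0)) { degenerate <<- TRUE; return(NULL) }
    s <- svd(m, nu = n_keep, nv = 0)
    s$u
  })
  if (degenerate) warning("all-zero response matrix at some frequencies; empty basis there")
  structure(list(freqs = R$freqs, U = U, geometry = R$geometry,
                 n_keep = n_keep),
            class = "singular_basis")
}

#' Norm function of the singular basis
#'
#' Projects a unit-normalized testing vector -- an attenuated spatial plane
#' wave `exp((i k - alpha) x_r)` over the receiver positions -- onto the kept
#' singular subspace at every frequency. The squared projection norm lies in
#' `[0, 1]`; its maxima over k locate the modal wavenumbers.
#'
#' @param basis A `singular_basis`.
#' @param k_grid Wavenumbers in rad/mm at which to evaluate (must stay below
#'   the spatial Nyquist limit pi/receiver_pitch).
#' @param alpha Spatial attenuation of the testing vector in 1/mm.
#' @return Object of class `norm_surface`: list with `freqs`, `k_grid`,
#'   `values` (frequency x wavenumber matrix in `[0, 1]`) and `alpha`.
#' @export
norm_function <- function(basis, k_grid, alpha = 0.05) {
  stopifnot(inherits(basis, "singular_basis"))
  probe <- basis$geometry
  if (max(k_grid) * probe$receiver_pitch > pi) {
    stop(sprintf("k grid exceeds the spatial Nyquist limit pi/%.3g = %.3g rad/mm",
                 probe$receiver_pitch, pi / probe$receiver_pitch))
  }
  x <- (seq_len(probe$n_receivers) - 1L) * probe$receiver_pitch
  # testing vectors, one column per k, unit-normalized; the propagating field
  # carries exp(-i k x) under the e^{i(w t - k x)} convention used throughout
  TV <- exp(outer(x, -1i * k_grid)) * exp(-alpha * x)
  TV <- sweep(TV, 2, sqrt(colSums(Mod(TV)^2)), "/")
  vals <- matrix(0, length(basis$freqs), length(k_grid))
  for (i in seq_along(basis$freqs)) {
    U <- basis$U[[i]]
    if (is.null(U)) next
    proj <- Conj(t(U)) %*% TV
    vals[i, ] <- colSums(Mod(proj)^2)
  }
  structure(list(freqs = basis$freqs, k_grid = k_grid, values = vals,
                 alpha = alpha),
            class = "norm_surface")
}

#' Peak extraction from a Norm surface
#'
#' A dilation-style picker: a grid point survives iff it equals the maximum
#' of its wavenumber neighborhood of `radius` bins and exceeds `floor`. On a
#' flat plateau the leftmost (lowest-k) bin is kept.
#'
#' @param surface A `norm_surface`.
#' @param radius Neighborhood half-width in k bins.
#' @param floor Minimum Norm value for a peak.
#' @return Data frame with columns `f`, `k`, `value`.
#' @export
extract_peaks <- function(surface, radius = 3L, floor = 0.5) {
  stopifnot(inherits(surface, "norm_surface"))
  v <- surface$values
  nk <- ncol(v)
  out_f <- numeric(0); out_k <- numeric(0); out_v <- numeric(0)
  for (i in seq_len(nrow(v))) {
    row <- v[i, ]
    is_peak <- logical(nk)
    for (j in seq_len(nk)) {
      lo <- max(1L, j - radius); hi <- min(nk, j + radius)
      # leftmost bin of a plateau represents it (tie-break)
      is_peak[j] <- row[j] > floor && row[j] >= max(row[lo:hi]) &&
        (j == 1L || row[j - 1L] < row[j])
    }
    idx <- which(is_peak)
    out_f <- c(out_f, rep(surface$freqs[i], length(idx)))
    out_k <- c(out_k, surface$k_grid[idx])
    out_v <- c(out_v, row[idx])
  }
  data.frame(f = out_f, k = out_k, value = out_v)
}

#' Bidirectional correction of peak wavenumbers
#'
#' Combines peaks measured along the two propagation directions. A probe
#' inclination biases the apparent wavenumber by opposite relative amounts in
#' the two directions (`k (1 +/- eps)`); the harmonic mean
#' `2 k+ k- / (k+ + k-)` cancels the bias to first order. Peaks are matched
#' per frequency bin, nearest in k within `pi/L`, greedily from the highest
#' Norm value; unmatched peaks pass through flagged.
#'
#' @param peaks_plus,peaks_minus Data frames from [extract_peaks()].
#' @param L Receiver aperture in mm (sets the matching window pi/L).
#' @return Data frame `f`, `k`, `value`, `matched` (logical).
#' @export
bidirectional_correct <- function(peaks_plus, peaks_minus, L = 20) {
  if (nrow(peaks_plus) == 0L || nrow(peaks_minus) == 0L) {
    warning("one direction has no peaks; passing the other through uncorrected")
    out <- rbind(peaks_plus, peaks_minus)
    out$matched <- logical(nrow(out))
    return(out)
  }
  tol <- pi / L
  out_f <- numeric(0); out_k <- numeric(0); out_v <- numeric(0)
  out_m <- logical(0)
  for (f0 in sort(unique(c(peaks_plus$f, peaks_minus$f)))) {
    pp <- peaks_plus[peaks_plus$f == f0, , drop = FALSE]
    pm <- peaks_minus[peaks_minus$f == f0, , drop = FALSE]
    used_m <- logical(nrow(pm))
    ord <- order(-pp$value)
    for (i in ord) {
      if (nrow(pm) == 0L) break
      d <- abs(pm$k - pp$k[i])
      d[used_m] <- Inf
      j <- which.min(d)
      if (length(j) && is.finite(d[j]) && d[j] <= tol) {
        used_m[j] <- TRUE
        kh <- 2 * pp$k[i] * pm$k[j] / (pp$k[i] + pm$k[j])
        out_f <- c(out_f, f0); out_k <- c(out_k, kh)
        out_v <- c(out_v, (pp$value[i] + pm$value[j]) / 2)
        out_m <- c(out_m, TRUE)
      } else {
        out_f <- c(out_f, f0); out_k <- c(out_k, pp$k[i])
        out_v <- c(out_v, pp$value[i]); out_m <- c(out_m, FALSE)
      }
    }
    if (any(!used_m)) {
      out_f <- c(out_f, pm$f[!used_m]); out_k <- c(out_k, pm$k[!used_m])
      out_v <- c(out_v, pm$value[!used_m])
      out_m <- c(out_m, rep(FALSE, sum(!used_m)))
    }
  }
  data.frame(f = out_f, k = out_k, value = out_v, matched = out_m)
}

#' Statistical denoising over measurement repetitions
#'
#' A (f, k) point survives iff at least `min_votes` repetitions contain a
#' point at the same frequency bin within `tol_k`; survivors are averaged
#' over their matches. This is the step that removes spurious peaks that do
#' not repeat from acquisition to acquisition.
#'
#' @param reps List (length >= 2) of peak data frames (`f`, `k` columns).
#' @param min_votes Minimum number of repetitions supporting a point.
#' @param tol_k Wavenumber matching tolerance in rad/mm (default pi/(2 L)
#'   with L = 20 mm).
#' @param f_max,k_max,L Window metadata for the returned [dispersion_data()].
#' @return A [dispersion_data()] with the surviving averaged points.
#' @export
denoise_repetitions <- function(reps, min_votes = 5L, tol_k = pi / 40,
                                f_max = 1.6, k_max = 6.28, L = 20) {
  if (length(reps) < 2L) stop("need at least 2 repetitions")
  if (min_votes > length(reps)) stop("min_votes cannot exceed the number of repetitions")
  all_f <- sort(unique(unlist(lapply(reps, function(p) p$f))))
  out_f <- numeric(0); out_k <- numeric(0)
  for (f0 in all_f) {
    ks <- lapply(reps, function(p) p$k[p$f == f0])
    rep_id <- rep(seq_along(ks), vapply(ks, length, 0L))
    kv <- unlist(ks)
    if (!length(kv)) next
    ord <- order(kv)
    kv <- kv[ord]; rep_id <- rep_id[ord]
    # greedy clustering along k
    start <- 1L
    for (i in seq_along(kv)) {
      if (i == length(kv) || kv[i + 1L] - kv[i] > tol_k) {
        members <- start:i
        votes <- length(unique(rep_id[members]))
        if (votes >= min_votes) {
          out_f <- c(out_f, f0)
          out_k <- c(out_k, mean(kv[members]))
        }
        start <- i + 1L
      }
    }
  }
  if (!length(out_f)) stop("no point survived the repetition vote")
  dispersion_data(data.frame(f = out_f, k = out_k),
                  f_max = f_max, k_max = k_max, L = L)
}

#' Full extraction chain on repeated bidirectional acquisitions
#'
#' Convenience wrapper running the whole pipeline: for every repetition,
#' response matrices and Norm surfaces for both directions, peak extraction,
#' bidirectional correction; then repetition denoising and direction merging
#' into a single dispersion point cloud.
#'
#' @param acquisitions List of repetitions, each a list with elements `plus`
#'   and `minus` as returned by [simulate_rf()].
#' @param k_grid Wavenumber grid for the Norm function.
#' @param n_keep Singular vectors kept per frequency.
#' @param alpha Testing-vector attenuation in 1/mm.
#' @param radius,floor Peak-picker parameters (see [extract_peaks()]).
#' @param min_votes,tol_k Denoising parameters; defaults 5 votes, pi/(2L).
#' @return A [dispersion_data()].
#' @export
extract_dispersion <- function(acquisitions, k_grid = NULL, n_keep = 3L,
                               alpha = 0.05, radius = 3L, floor = 0.5,
                               min_votes = NULL, tol_k = NULL) {
  if (!length(acquisitions)) stop("no acquisitions supplied")
  probe <- acquisitions[[1]]$plus$geometry
  if (is.null(k_grid)) {
    k_grid <- seq(0.05, pi / probe$receiver_pitch * 0.999, by = pi / (4 * probe$L))
  }
  if (is.null(min_votes)) min_votes <- max(1L, ceiling(length(acquisitions) / 2))
  if (length(acquisitions) == 1L) min_votes <- 1L
  if (is.null(tol_k)) tol_k <- pi / (2 * probe$L)
  per_rep <- lapply(acquisitions, function(acq) {
    pk <- lapply(c("plus", "minus"), function(d) {
      extract_peaks(norm_function(svd_denoise(build_response_matrix(acq[[d]]),
                                              n_keep = n_keep),
                                  k_grid, alpha = alpha),
                    radius = radius, floor = floor)
    })
    bidirectional_correct(pk[[1]], pk[[2]], L = probe$L)
  })
  if (length(per_rep) == 1L) {
    pts <- per_rep[[1]]
    return(dispersion_data(pts[, c("f", "k")], f_max = probe$band[2],
                           k_max = max(k_grid), L = probe$L))
  }
  denoise_repetitions(per_rep, min_votes = min_votes, tol_k = tol_k,
                      f_max = probe$band[2], k_max = max(k_grid), L = probe$L)
}
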