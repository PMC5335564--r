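# Aperture-limited synthetic extraction: from exact bilayer branches to the
# point cloud a finite receiver array resting on the coating would deliver.

#' Simulate an extracted dispersion cloud for a coated plate
#'
#' Produces the synthetic analog of the dispersion data that the extraction
#' chain recovers from an axial-transmission measurement of a fluid-coated
#' plate. Three physical effects shape the cloud:
#'
#' * the guided modes are those of the bilayer, not of the free plate;
#' * the array aperture `L` cannot separate wavenumbers closer than `pi/L`:
#'   at each frequency, neighboring bilayer roots merge into a single
#'   detected wavenumber at their detectability-weighted centroid (in
#'   particular, the narrow avoided crossings between solid-guided and
#'   fluid-layer branches are not resolved, so the detected trajectory runs
#'   smoothly through them);
#' * detection favors the modes carried by the solid: per frequency only
#'   the `n_detect` merged roots of largest solid energy share fit into the
#'   kept singular subspace of the response matrix, and each survivor is
#'   then detected through a steep logistic gate on that share
#'   ([solid_energy_fraction()]), emulating the hard thresholds of the real
#'   chain (Norm floor, repetition vote). Solid-guided trajectories are
#'   recovered almost everywhere, hybrid segments sporadically, and fluid
#'   resonances appear only as scattered low-phase-velocity points.
#'
#' Wavenumber noise, dropout and uniform outliers are then applied as in
#' [sample_dispersion_points()].
#'
#' @param system A [bilayer_system()].
#' @param grid A [dispersion_grid()].
#' @param noise An [extraction_noise_model()].
#' @param L Receiver aperture in mm (merging scale `pi/L`).
#' @param midpoint,scale Logistic detection gate on the solid energy share.
#' @param n_detect Maximum number of modes detectable per frequency. The
#'   response matrix of a probe with five emitters has rank at most five and
#'   the extraction keeps about three singular directions, so only the few
#'   strongest modes at each frequency can be recovered.
#' @param detect `"bernoulli"` keeps each merged point with the gate
#'   probability (repetition-to-repetition variability of weak peaks);
#'   `"threshold"` keeps exactly the points whose share reaches `midpoint`,
#'   so that the only randomness left is the noise model.
#' @param branches Optional pre-traced bilayer branches (avoids re-tracing).
#' @return A [dispersion_data()].
#' @export
simulate_extracted_cloud <- function(system, grid,
                                     noise = extraction_noise_model(),
                                     L = 20, midpoint = 0.65, scale = 0.1,
                                     n_detect = 4L,
                                     detect = c("bernoulli", "threshold"),
                                     branches = NULL) {
  detect <- match.arg(detect)
  stopifnot(inherits(system, "bilayer_system"),
            inherits(grid, "dispersion_grid"))
  if (is.null(branches)) branches <- trace_bilayer_modes(system, grid)
  if (!length(branches)) stop("no bilayer mode crosses the window")
  Dw <- lapply(branches, function(b) {
    solid_energy_fraction(system, b$points[, "f"], b$points[, "k"])
  })
  f_all <- unlist(lapply(branches, function(b) b$points[, "f"]))
  k_all <- unlist(lapply(branches, function(b) b$points[, "k"]))
  d_all <- unlist(Dw)
  tol <- pi / L
  out_f <- numeric(0); out_k <- numeric(0); out_d <- numeric(0)
  for (f0 in unique(f_all)) {
    sel <- which(f_all == f0)
    ord <- sel[order(k_all[sel])]
    kv <- k_all[ord]; dv <- d_all[ord]
    cl_k <- numeric(0); cl_d <- numeric(0)
    start <- 1L
    for (i in seq_along(kv)) {
      if (i == length(kv) || kv[i + 1L] - kv[i] > tol) {
        mem <- start:i
        wsum <- sum(dv[mem]) + 1e-300
        cl_k <- c(cl_k, sum(kv[mem] * dv[mem]) / wsum)
        cl_d <- c(cl_d, max(dv[mem]))
        start <- i + 1L
      }
    }
    # rank-limited detection: only the strongest modes fit into the kept
    # singular subspace of the (receivers x emitters) response matrix
    if (length(cl_k) > n_detect) {
      keep <- order(cl_d, decreasing = TRUE)[seq_len(n_detect)]
      cl_k <- cl_k[keep]; cl_d <- cl_d[keep]
    }
    out_f <- c(out_f, rep(f0, length(cl_k)))
    out_k <- c(out_k, cl_k)
    out_d <- c(out_d, cl_d)
  }
  if (detect == "threshold") {
    keep <- out_d >= midpoint
    if (!any(keep)) stop("no merged root reaches the detection threshold")
    merged <- .mode_branch("merged", "n", 1L, out_f[keep], out_k[keep])
    sample_dispersion_points(list(merged), grid, noise, L = L)
  } else {
    merged <- .mode_branch("merged", "n", 1L, out_f, out_k)
    p_detect <- stats::plogis((out_d - midpoint) / scale)
    sample_dispersion_points(list(merged), grid, noise, L = L,
                             weights = list(p_detect))
  }
}
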