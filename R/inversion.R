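# The occupancy-rate objective: normalized distances, inlier assignment and
# the mode-activation rule that scores a candidate waveguide model against a
# dispersion point cloud.

#' Objective configuration
#'
#' @param d0 Dimensionless inlier threshold on the normalized distance.
#'   The default 0.025 corresponds to the normalized wavenumber resolution
#'   `(pi/L)/k_max` of a 20 mm array observed up to 6.28 rad/mm.
#' @param alpha_active Mode-activation fraction. A selected mode contributes
#'   to the objective only if (i) its inliers occupy a contiguous stretch of
#'   the predicted branch covering at least `alpha_active` of its
#'   theoretical points (isolated gaps up to `gap_tol` vertices are
#'   bridged), and (ii) at least `alpha_active` of the data points assigned
#'   to the mode are its inliers. Together these encode that experimental
#'   data only count when they form a trajectory along a predicted mode: a
#'   model whose branches merely criss-cross dense data picks up scattered
#'   matches with short runs and poor precision and gains nothing, which
#'   removes the incentive to overfit with a dense mode fan.
#' @param gap_tol Number of consecutive unoccupied theoretical vertices that
#'   may interrupt a trajectory without breaking it (dropout tolerance).
#' @param M_max Number of candidate Lamb modes (ordered A0, S0, A1, S1, ...)
#'   the pairing vector ranges over.
#' @return An object of class `objective_config`.
#' @export
objective_config <- function(d0 = 0.025, alpha_active = 1/3, M_max = 10L,
                             gap_tol = 2L) {
  stopifnot(d0 > 0, alpha_active >= 0, alpha_active <= 1, M_max >= 1,
            gap_tol >= 0)
  structure(list(d0 = d0, alpha_active = alpha_active,
                 M_max = as.integer(M_max), gap_tol = as.integer(gap_tol)),
            class = "objective_config")
}

#' Model parameter bounds
#'
#' Box bounds for the five free-plate parameters. Defaults encompass both
#' bone-mimicking phantoms and cortical bone.
#'
#' @param h_s,r13,r33,VL3,VT Two-element vectors `c(low, high)`.
#' @return An object of class `parameter_bounds`.
#' @export
parameter_bounds <- function(h_s = c(0.5, 4), r13 = c(0.2, 0.7),
                             r33 = c(1.1, 2.5), VL3 = c(1.63, 7),
                             VT = c(1.0, 2.0)) {
  b <- list(h_s = h_s, r13 = r13, r33 = r33, VL3 = VL3, VT = VT)
  for (nm in names(b)) {
    if (length(b[[nm]]) != 2L || b[[nm]][1] >= b[[nm]][2]) {
      stop(sprintf("bound for %s must be c(low, high) with low < high", nm))
    }
  }
  structure(b, class = "parameter_bounds")
}

# Minimum normalized distance from each point to a branch polyline,
# vectorized over points. Coordinates are (f/f_max, k/k_max).
.branch_distances <- function(pf, pk, branch, f_max, k_max) {
  bp <- branch$points
  u <- bp[, "f"] / f_max; v <- bp[, "k"] / k_max
  px <- pf / f_max; py <- pk / k_max
  m <- length(u)
  if (m == 1L) {
    return(sqrt((px - u)^2 + (py - v)^2))
  }
  ax <- u[-m]; ay <- v[-m]
  dx <- diff(u); dy <- diff(v)
  len2 <- dx^2 + dy^2
  len2[len2 == 0] <- 1e-300
  # t[i, j]: projection parameter of point j on segment i, clamped to [0,1]
  t <- (outer(dx / len2, px) + outer(dy / len2, py) -
          (dx * ax + dy * ay) / len2)
  t[t < 0] <- 0; t[t > 1] <- 1
  ex <- ax + t * dx - rep(px, each = m - 1L)
  ey <- ay + t * dy - rep(py, each = m - 1L)
  sqrt(.colMins(ex^2 + ey^2))
}

.colMins <- function(m) {
  if (is.null(dim(m))) return(m)
  do.call(pmin, lapply(seq_len(nrow(m)), function(i) m[i, ]))
}

#' Normalized distance of a point to a mode branch
#'
#' Euclidean distance in the normalized plane `(f/f_max, k/k_max)` between a
#' data point and the branch polyline. A point is an inlier of the mode when
#' this distance does not exceed the threshold `d0`.
#'
#' @param point Numeric vector `c(f, k)` (MHz, rad/mm).
#' @param branch A `mode_branch`.
#' @param f_max,k_max Normalization constants of the observation window.
#' @return The minimum normalized distance (scalar); `Inf` for an empty
#'   branch.
#' @export
normalized_distance <- function(point, branch, f_max, k_max) {
  if (is.null(branch) || nrow(branch$points) == 0L) return(Inf)
  .branch_distances(point[1], point[2], branch, f_max, k_max)
}

#' Assign data points to their nearest mode branches
#'
#' Each point is assigned to the nearest branch in normalized distance; it is
#' an inlier when that distance is at most `cfg$d0`. Each point counts for a
#' single mode; equidistant ties go to the earlier branch in the list (for
#' the canonical ordering A0, S0, A1, S1, ... this means the lower mode
#' order, antisymmetric first).
#'
#' @param data A [dispersion_data()].
#' @param branches List of `mode_branch` objects (may contain `NULL` slots
#'   for modes absent from the window).
#' @param cfg An [objective_config()].
#' @return List with `mode` (index into `branches`, `NA` when no branch
#'   exists), `distance`, and `inlier` (logical), each of length `data$n`.
#' @export
assign_inliers <- function(data, branches, cfg = objective_config()) {
  stopifnot(inherits(data, "dispersion_data"))
  pf <- data$points$f; pk <- data$points$k
  n <- data$n
  live <- which(!vapply(branches, is.null, TRUE))
  if (!length(live)) {
    return(list(mode = rep(NA_integer_, n), distance = rep(Inf, n),
                inlier = rep(FALSE, n)))
  }
  d <- matrix(Inf, n, length(branches))
  for (i in live) {
    d[, i] <- .branch_distances(pf, pk, branches[[i]], data$f_max, data$k_max)
  }
  mode <- max.col(-d, ties.method = "first")   # first index wins ties
  dist <- d[cbind(seq_len(n), mode)]
  list(mode = mode, distance = dist, inlier = dist <= cfg$d0)
}

#' Candidate Lamb modes in canonical order
#'
#' Traces the plate modes on the grid and arranges them in the canonical
#' pairing order A0, S0, A1, S1, ... up to `M_max` slots. Slots whose mode
#' does not enter the window are `NULL`.
#'
#' @param plate An [elastic_plate()].
#' @param grid A [dispersion_grid()].
#' @param M_max Number of slots.
#' @param rtol Root refinement tolerance passed to [trace_plate_modes()].
#' @return List of length `M_max` of `mode_branch` or `NULL`.
#' @export
candidate_lamb_modes <- function(plate, grid, M_max = 10L, rtol = 1e-9) {
  br <- trace_plate_modes(plate, grid, rtol = rtol)
  slots <- vector("list", M_max)
  for (b in br) {
    i <- 2L * b$order + if (b$family == "A") 1L else 2L
    if (i <= M_max) slots[[i]] <- b
  }
  # total theoretical point count of every mode the model places in the
  # window (including orders beyond the pairing slots): the parsimony
  # denominator of the fitness
  attr(slots, "n_th_total") <- sum(vapply(br, function(b) nrow(b$points), 0L))
  slots
}

#' Occupancy rate of the Lamb modes
#'
#' The objective function of the inversion: the fraction of experimental
#' points that are inliers of the modes selected by the pairing vector,
#' subject to the activation rule of [objective_config()]. A mode whose
#' inlier count is too small relative to its own theoretical point count is
#' deemed not observed and contributes nothing.
#'
#' @param plate An [elastic_plate()] candidate.
#' @param pairing Logical (or 0/1) vector of length `cfg$M_max` selecting
#'   candidate modes in the order A0, S0, A1, S1, ...
#' @param data A [dispersion_data()].
#' @param cfg An [objective_config()].
#' @param grid Optional [dispersion_grid()]; defaults to the data window with
#'   a 0.025 MHz tracing step.
#' @param modes Optional precomputed [candidate_lamb_modes()] list.
#' @param detail If `TRUE`, also return the mean normalized distance of the
#'   inliers of active modes and the per-mode counts.
#' @return Scalar occupancy rate in `[0, 1]`, or a list when `detail = TRUE`.
#' @export
occupancy_rate <- function(plate, pairing, data, cfg = objective_config(),
                           grid = NULL, modes = NULL, detail = FALSE) {
  stopifnot(inherits(data, "dispersion_data"))
  if (data$n == 0L) stop("empty dispersion data")
  pairing <- as.logical(rep_len(pairing, cfg$M_max))
  empty <- list(F = 0, F_kernel = 0, mean_inlier_distance = cfg$d0,
                parsimony = 0)
  if (!any(pairing)) return(if (detail) empty else 0)
  if (is.null(modes)) {
    if (is.null(grid)) grid <- .default_inversion_grid(data)
    modes <- candidate_lamb_modes(plate, grid, cfg$M_max)
  }
  sel <- which(pairing & !vapply(modes, is.null, TRUE))
  if (!length(sel)) return(if (detail) empty else 0)
  asg <- assign_inliers(data, modes[sel], cfg)
  n_exp <- tabulate(asg$mode, nbins = length(sel))
  n_in <- tabulate(asg$mode[asg$inlier], nbins = length(sel))
  n_th <- vapply(modes[sel], function(b) nrow(b$points), 0L)
  run <- vapply(seq_along(sel), function(i) {
    pts <- which(asg$inlier & asg$mode == i)
    if (!length(pts)) return(0L)
    .longest_run(.nearest_vertices(data$points$f[pts], data$points$k[pts],
                                   modes[[sel[i]]], data$f_max, data$k_max),
                 cfg$gap_tol)
  }, 0L)
  # a mode is observed when (i) its inliers form a trajectory along a
  # sufficient contiguous span of the predicted branch and (ii) the data
  # assigned to it are predominantly explained by it, not merely nearby
  active <- run >= cfg$alpha_active * n_th &
    n_in >= cfg$alpha_active * n_exp
  F <- sum(n_in[active]) / data$n
  if (!detail) return(F)
  keep <- asg$inlier & active[asg$mode]
  md <- if (any(keep)) mean(asg$distance[keep]) else cfg$d0
  n_th_total <- attr(modes, "n_th_total")
  if (is.null(n_th_total)) n_th_total <- sum(n_th)
  E <- if (n_th_total > 0) sum(n_th[active]) / n_th_total else 0
  # kernel-weighted coverage: inliers discounted by how far inside the
  # tolerance tube they sit (Epanechnikov weight), so that modes riding the
  # data exactly outscore modes merely passing through the tube
  Fk <- if (any(keep)) {
    sum(1 - (asg$distance[keep] / cfg$d0)^2) / data$n
  } else 0
  list(F = F, F_kernel = Fk, mean_inlier_distance = md,
       n_in = n_in, n_th = n_th,
       run = run, active = active, sel = sel, parsimony = E)
}

# Index of the nearest branch vertex for each point (normalized metric).
.nearest_vertices <- function(pf, pk, branch, f_max, k_max) {
  u <- branch$points[, "f"] / f_max; v <- branch$points[, "k"] / k_max
  px <- pf / f_max; py <- pk / k_max
  d2 <- outer(u, px, "-")^2 + outer(v, py, "-")^2   # vertices x points
  max.col(-t(d2), ties.method = "first")
}

# Length (in vertices, gaps included) of the longest stretch of occupied
# vertices where unoccupied holes of at most gap_tol vertices are bridged.
.longest_run <- function(vertex_idx, gap_tol) {
  idx <- sort(unique(vertex_idx))
  if (!length(idx)) return(0L)
  brk <- which(diff(idx) > gap_tol + 1L)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(idx))
  max(idx[ends] - idx[starts] + 1L)
}

.default_inversion_grid <- function(data, f_step = 0.02, k_step = 0.03) {
  f_lo <- max(0.05, min(data$points$f) - f_step)
  dispersion_grid(f_min = f_lo, f_max = data$f_max, f_step = f_step,
                  k_max = data$k_max, k_step = k_step)
}

# Validity of a candidate parameter vector beyond the box bounds.
.plate_valid <- function(h_s, r13, r33, VL3, VT) {
  r13^2 < r33 && VL3 / sqrt(r33) > VT
}
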