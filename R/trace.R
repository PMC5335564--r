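# Tracing guided-mode branches on a frequency-wavenumber grid.
#
# At each grid frequency the characteristic function is scanned in k with
# step k_step, sign changes are bracketed and refined (Illinois-type regula
# falsi), and the per-frequency roots are linked into branches by
# slope-predicted nearest-neighbor continuity. Branches spanning fewer than
# `min_points` frequencies are discarded as numerical chatter.

# Vectorized bracketed root refinement (Illinois variant of regula falsi,
# falling back on bisection steps): fn(f, k) must accept equal-length
# vectors. `rtol` is relative to `k_scale`.
.refine_roots <- function(fn, f, lo, hi, k_scale, rtol = 1e-9) {
  if (length(lo) == 0L) return(numeric(0))
  flo <- fn(f, lo); fhi <- fn(f, hi)
  tol <- rtol * k_scale
  for (i in seq_len(60L)) {
    wid <- hi - lo
    if (max(wid) <= tol) break
    mid <- (lo * fhi - hi * flo) / (fhi - flo)    # secant point
    # keep the step well inside the bracket; otherwise bisect
    bad <- !is.finite(mid) | mid <= lo + 0.01 * wid | mid >= hi - 0.01 * wid
    mid[bad] <- (lo[bad] + hi[bad]) / 2
    fmid <- fn(f, mid)
    same_lo <- flo * fmid > 0      # root lies in (mid, hi)
    # move one endpoint to mid; halve the value kept at the stagnant
    # endpoint (Illinois) so the secant keeps converging
    lo[same_lo] <- mid[same_lo]
    flo[same_lo] <- fmid[same_lo]
    fhi[same_lo] <- fhi[same_lo] / 2
    hi[!same_lo] <- mid[!same_lo]
    fhi[!same_lo] <- fmid[!same_lo]
    flo[!same_lo] <- flo[!same_lo] / 2
  }
  (lo + hi) / 2
}

# Roots along k for every frequency of the grid, for one or several
# characteristic functions sharing the same grid. `fns` is a named list of
# vectorized fn(f, k); returns list(fs, roots = list per fn of per-frequency
# root vectors).
.scan_roots_multi <- function(fns, grid, rtol = 1e-9) {
  fs <- seq(grid$f_min, grid$f_max, by = grid$f_step)
  ks <- seq(grid$k_step, grid$k_max, by = grid$k_step)
  nf <- length(fs); nk <- length(ks)
  fgrid <- rep(fs, times = nk); kgrid <- rep(ks, each = nf)
  out <- vector("list", length(fns))
  for (j in seq_along(fns)) {
    fn <- fns[[j]]
    vals <- matrix(fn(fgrid, kgrid), nrow = nf)
    sgn <- vals[, -1L, drop = FALSE] * vals[, -nk, drop = FALSE]
    idx <- which(sgn < 0 & is.finite(sgn), arr.ind = TRUE)
    roots <- rep(list(numeric(0)), nf)
    if (nrow(idx) > 0) {
      r <- .refine_roots(fn, fs[idx[, 1L]], ks[idx[, 2L]], ks[idx[, 2L] + 1L],
                         grid$k_max, rtol)
      roots_by_f <- split(r, idx[, 1L])
      for (nm in names(roots_by_f)) {
        roots[[as.integer(nm)]] <- sort(roots_by_f[[nm]])
      }
    }
    out[[j]] <- roots
  }
  names(out) <- names(fns)
  list(fs = fs, roots = out)
}

# Link per-frequency roots into branches by nearest-neighbor continuity.
# Each open branch predicts its next wavenumber by linear continuation of
# its last two points; a root within `max_jump` of the prediction may extend
# the branch (closest pairs first). A branch with a single point has no
# slope yet, so its first extension is granted a wider window.
.link_branches <- function(fs, roots, max_jump, min_points) {
  open_f <- list(); open_k <- list()
  closed <- list()
  for (i in seq_along(fs)) {
    rk <- roots[[i]]
    nb <- length(open_k); nr <- length(rk)
    matched_branch <- rep(FALSE, nb)
    matched_root <- rep(FALSE, nr)
    if (nb && nr) {
      pred <- numeric(nb); win <- numeric(nb)
      for (b in seq_len(nb)) {
        kk <- open_k[[b]]; n <- length(kk)
        pred[b] <- if (n >= 2L) 2 * kk[n] - kk[n - 1L] else kk[n]
        win[b] <- if (n >= 2L) max_jump else 5 * max_jump
      }
      d <- abs(outer(pred, rk, "-"))
      ord <- order(d)
      for (ii in ord) {
        bi <- (ii - 1L) %% nb + 1L
        ri <- (ii - 1L) %/% nb + 1L
        if (d[[ii]] > win[bi]) next
        if (matched_branch[bi] || matched_root[ri]) next
        matched_branch[bi] <- TRUE
        matched_root[ri] <- TRUE
        open_f[[bi]] <- c(open_f[[bi]], fs[i])
        open_k[[bi]] <- c(open_k[[bi]], rk[ri])
      }
    }
    if (nb) {
      closing <- which(!matched_branch)
      for (b in closing) {
        closed[[length(closed) + 1L]] <- list(f = open_f[[b]], k = open_k[[b]])
      }
      keep <- which(matched_branch)
      open_f <- open_f[keep]; open_k <- open_k[keep]
    }
    for (ri in which(!matched_root)) {
      open_f[[length(open_f) + 1L]] <- fs[i]
      open_k[[length(open_k) + 1L]] <- rk[ri]
    }
  }
  for (b in seq_along(open_f)) {
    closed[[length(closed) + 1L]] <- list(f = open_f[[b]], k = open_k[[b]])
  }
  closed[vapply(closed, function(b) length(b$f), 0L) >= min_points]
}

.mode_branch <- function(label, family, order, f, k) {
  structure(list(label = label, family = family, order = order,
                 points = cbind(f = f, k = k)),
            class = "mode_branch")
}

#' @export
print.mode_branch <- function(x, ...) {
  rng <- range(x$points[, "f"])
  cat(sprintf("Mode %s: %d points, f in [%.3g, %.3g] MHz, k in [%.3g, %.3g] rad/mm\n",
              x$label, nrow(x$points), rng[1], rng[2],
              min(x$points[, "k"]), max(x$points[, "k"])))
  invisible(x)
}

# Order branches of one plate family by mode order. Within a family branches
# do not cross, so at any common frequency descending k means ascending mode
# order (the fundamental is the slowest). Without a common frequency the
# branch living at lower frequencies comes first (higher orders cut on
# later).
.order_family <- function(branches) {
  if (length(branches) <= 1L) return(branches)
  higher <- function(a, b) { # TRUE if a is higher-order than b
    fa <- a$f; fb <- b$f
    common <- intersect(round(fa / 1e-6), round(fb / 1e-6))
    if (length(common)) {
      fc <- common[1] * 1e-6
      ka <- a$k[which.min(abs(fa - fc))]
      kb <- b$k[which.min(abs(fb - fc))]
      ka < kb
    } else {
      min(fa) > min(fb)
    }
  }
  n <- length(branches)
  ord <- seq_len(n)
  for (i in seq_len(n - 1L)) {        # insertion sort with the comparator
    j <- i + 1L
    while (j > 1L && higher(branches[[ord[j - 1L]]], branches[[ord[j]]])) {
      tmp <- ord[j]; ord[j] <- ord[j - 1L]; ord[j - 1L] <- tmp
      j <- j - 1L
    }
  }
  branches[ord]
}

#' Trace free-plate Lamb mode branches
#'
#' Scans the symmetric and antisymmetric characteristic functions over the
#' grid, refines every root, and links the roots into labeled branches
#' `A0, A1, ...` and `S0, S1, ...` (within each family the fundamental is
#' the branch of largest wavenumber).
#'
#' @param plate An [elastic_plate()].
#' @param grid A [dispersion_grid()].
#' @param families Which families to trace (default both).
#' @param min_points Branches spanning fewer grid frequencies are dropped.
#' @param rtol Relative root refinement tolerance (of `k_max`).
#' @return List of `mode_branch` objects, sorted by ascending k at the top
#'   of the band; empty list when no mode crosses the window.
#' @export
trace_plate_modes <- function(plate, grid, families = c("A", "S"),
                              min_points = 5L, rtol = 1e-9) {
  stopifnot(inherits(plate, "elastic_plate"), inherits(grid, "dispersion_grid"))
  fns <- lapply(families, function(fam) {
    force(fam)
    function(f, k) plate_characteristic(plate, f, k, fam)
  })
  names(fns) <- families
  sc <- .scan_roots_multi(fns, grid, rtol)
  out <- list()
  for (fam in families) {
    raw <- .link_branches(sc$fs, sc$roots[[fam]], 3 * grid$k_step, min_points)
    raw <- .order_family(raw)
    for (i in seq_along(raw)) {
      b <- raw[[i]]
      out[[length(out) + 1L]] <- .mode_branch(
        label = paste0(fam, i - 1L), family = fam,
        order = i - 1L, f = b$f, k = b$k)
    }
  }
  # sort by ascending k at the highest frequency each branch reaches
  if (length(out)) {
    key <- vapply(out, function(b) {
      b$points[nrow(b$points), "k"] - 100 * max(b$points[, "f"])
    }, 0)
    out <- out[order(key)]
  }
  out
}

#' Trace bilayer guided-mode branches
#'
#' As [trace_plate_modes()], for the fluid-solid bilayer. Bilayer modes are
#' not Lamb modes, so branches carry ordinal labels `1, 2, ...` assigned by
#' ascending wavenumber at the highest frequency common to the branches.
#'
#' @param system A [bilayer_system()].
#' @inheritParams trace_plate_modes
#' @return List of `mode_branch` objects with integer labels.
#' @export
trace_bilayer_modes <- function(system, grid, min_points = 5L, rtol = 1e-9) {
  stopifnot(inherits(system, "bilayer_system"),
            inherits(grid, "dispersion_grid"))
  fn <- function(f, k) bilayer_characteristic(system, f, k)
  sc <- .scan_roots_multi(list(n = fn), grid, rtol)
  raw <- .link_branches(sc$fs, sc$roots[["n"]], 3 * grid$k_step, min_points)
  if (!length(raw)) return(list())
  f_top <- max(vapply(raw, function(b) max(b$f), 0))
  key <- vapply(raw, function(b) {
    # k at the branch's top frequency; branches absent from the common top
    # frequency are ranked after, by how far below it they stop
    penalty <- (f_top - max(b$f)) * 1e3
    b$k[length(b$k)] + penalty
  }, 0)
  raw <- raw[order(key)]
  lapply(seq_along(raw), function(i) {
    b <- raw[[i]]
    .mode_branch(label = as.character(i), family = "n", order = i,
                 f = b$f, k = b$k)
  })
}

#' Export branches as delimited text
#'
#' Writes one TSV with columns `mode_label`, `f_MHz`, `k_rad_per_mm`;
#' `#`-prefixed header lines carry the parameter set used.
#'
#' @param branches List of `mode_branch` objects.
#' @param file Output path.
#' @param params Optional named list echoed into the header comments.
#' @export
export_branches <- function(branches, file, params = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(params)) {
    for (nm in names(params)) {
      writeLines(sprintf("# %s = %s", nm, format(params[[nm]])), con)
    }
  }
  writeLines("mode_label\tf_MHz\tk_rad_per_mm", con)
  for (b in branches) {
    utils::write.table(
      data.frame(b$label, b$points[, "f"], b$points[, "k"]),
      con, sep = "\t", col.names = FALSE, row.names = FALSE, quote = FALSE)
  }
  invisible(file)
}
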