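# Two-step workflow: invert with the free plate model, then insert the
# estimates into the bilayer forward model and check how much more of the
# data it explains; plus a benchmark driver over solid/coating combinations.

#' Reference material properties
#'
#' Material constants used by the benchmark drivers and examples: the
#' bone-mimicking composite (short glass fibers in epoxy, transverse
#' isotropic) characterized by resonant ultrasound spectroscopy, the
#' literature range for human cortical bone, and the two soft-tissue-mimicking
#' polymers plus water-like soft tissue.
#'
#' @return Nested list with elements `bone_mimic` (c11, c33, c13, c55 in GPa,
#'   rho_s in g/cm3), `cortical_range` (two-element ranges), `zerdine`,
#'   `urethane`, `soft_tissue` (c_f, rho_f).
#' @export
reference_materials <- function() {
  list(
    bone_mimic = list(c11 = 14.7, c33 = 22.1, c13 = 7.6, c55 = 4.6,
                      rho_s = 1.65),
    cortical_range = list(c11 = c(13.1, 21.5), c33 = c(24.8, 32.4),
                          c55 = c(4.7, 6.4), rho_s = c(1.83, 2.01)),
    zerdine = list(c_f = 1.54, rho_f = 1.03),
    urethane = list(c_f = 1.43, rho_f = 1.00),
    soft_tissue = list(c_f = 1.54, rho_f = 1.00)
  )
}

#' Bone-mimicking plate of given thickness
#'
#' Convenience constructor building an [elastic_plate()] from the reference
#' stiffness of the bone-mimicking composite.
#'
#' @param h_s Thickness in mm.
#' @return An [elastic_plate()].
#' @export
bone_mimic_plate <- function(h_s) {
  m <- reference_materials()$bone_mimic
  plate_from_stiffness(m$c11, m$c33, m$c13, m$c55, m$rho_s, h_s)
}

#' Two-step validation of a free-plate inversion
#'
#' Implements the second step of the workflow: the optimal plate parameters
#' are inserted into the bilayer model (which additionally needs the solid
#' density and the fluid-layer properties), the bilayer modes are traced on
#' the same window, and the inlier assignment is re-run on all data points
#' with the same threshold. The report compares the share of data explained
#' by the two models and counts the plate-stage outliers that the bilayer
#' explains.
#'
#' @param result An `inversion_result` from [invert_dispersion()].
#' @param data The same [dispersion_data()] the inversion used.
#' @param rho_s Solid mass density in g/cm3 (required by the bilayer model).
#' @param fluid A [fluid_layer()] describing the coating.
#' @param cfg An [objective_config()]; defaults to the one used in the
#'   inversion.
#' @param grid Optional tracing grid; defaults to the inversion's grid.
#' @return An object of class `validation_report`: plate and bilayer inlier
#'   percentages, the count of newly explained points, and the parameters.
#' @export
two_step_validate <- function(result, data, rho_s, fluid, cfg = NULL,
                              grid = NULL) {
  stopifnot(inherits(result, "inversion_result"),
            inherits(data, "dispersion_data"))
  if (missing(rho_s) || is.null(rho_s)) {
    stop("the bilayer model requires the solid mass density rho_s explicitly")
  }
  if (is.null(cfg)) cfg <- result$cfg
  if (is.null(grid)) grid <- result$grid
  system <- bilayer_system(result$theta, rho_s, fluid)
  bil <- trace_bilayer_modes(system, grid)
  if (!length(bil)) stop("no bilayer mode crosses the window")
  plate_in <- result$assignments$inlier
  asg <- assign_inliers(data, bil, cfg)
  structure(list(
    plate_inlier_percent = 100 * sum(plate_in) / data$n,
    bilayer_inlier_percent = 100 * sum(asg$inlier) / data$n,
    newly_explained = sum(asg$inlier & !plate_in),
    n = data$n,
    theta = result$theta, rho_s = rho_s, fluid = fluid,
    bilayer_assignments = data.frame(mode = asg$mode,
                                     distance = asg$distance,
                                     inlier = asg$inlier),
    n_bilayer_modes = length(bil)),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Two-step validation\n")
  cat(sprintf("  free plate : %5.1f%% inliers\n", x$plate_inlier_percent))
  cat(sprintf("  bilayer    : %5.1f%% inliers (%d modes)\n",
              x$bilayer_inlier_percent, x$n_bilayer_modes))
  cat(sprintf("  outliers newly explained by the bilayer: %d of %d points\n",
              x$newly_explained, x$n))
  invisible(x)
}

#' Benchmark cases for coated bone-mimicking plates
#'
#' Builds the default synthetic benchmark: bone-mimicking plates of the given
#' thicknesses, each under a set of soft-tissue-mimicking coatings.
#'
#' @param h_s Plate thicknesses in mm.
#' @param coatings Data frame with columns `material`, `c_f`, `rho_f`, `h_f`;
#'   default the four-coating series Urethane 2 mm, Zerdine 4 mm, Urethane
#'   6 mm, Zerdine 8 mm.
#' @return Data frame with one row per (plate, coating) combination.
#' @export
benchmark_cases <- function(h_s = c(1.25, 2.34, 3.48), coatings = NULL) {
  m <- reference_materials()
  if (is.null(coatings)) {
    coatings <- data.frame(
      material = c("urethane", "zerdine", "urethane", "zerdine"),
      c_f = c(m$urethane$c_f, m$zerdine$c_f, m$urethane$c_f, m$zerdine$c_f),
      rho_f = c(m$urethane$rho_f, m$zerdine$rho_f, m$urethane$rho_f,
                m$zerdine$rho_f),
      h_f = c(2, 4, 6, 8))
  }
  out <- merge(data.frame(h_s = h_s), coatings)
  out[order(out$h_s, out$h_f), ]
}

#' Synthetic benchmark of the free-plate inversion on coated plates
#'
#' For every (solid, coating) combination: traces the bilayer modes, samples
#' a noisy dispersion cloud, inverts it with the free plate model, and
#' reports the estimates with their relative errors against the known truth.
#' Per plate thickness, the spread of the estimates across its coatings is
#' summarized as half-range divided by median.
#'
#' @param cases Data frame as from [benchmark_cases()].
#' @param bounds,ga,cfg Inversion settings ([parameter_bounds()],
#'   [ga_config()], [objective_config()]); the GA seed is combined with the
#'   case index so each case is independently seeded yet reproducible.
#' @param noise An [extraction_noise_model()]; its seed is offset per case.
#' @param grid Window for data generation (default [dispersion_grid()]).
#' @return Object of class `benchmark_result`: `estimates` (one row per
#'   case: truth, estimates, relative errors in percent) and `variability`
#'   (per thickness: half-range/median of each parameter, in percent).
#' @export
benchmark_suite <- function(cases = benchmark_cases(),
                            bounds = parameter_bounds(), ga,
                            cfg = objective_config(),
                            noise = extraction_noise_model(
                              sigma_k = pi / 80, p_drop_point = 0.1,
                              n_outliers = 20),
                            grid = dispersion_grid()) {
  stopifnot(inherits(ga, "ga_config"))
  ref <- reference_materials()$bone_mimic
  rows <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    plate <- bone_mimic_plate(cs$h_s)
    system <- bilayer_system(plate, ref$rho_s,
                             fluid_layer(cs$c_f, cs$rho_f, cs$h_f))
    noise_i <- noise; noise_i$seed <- noise$seed + i
    data <- simulate_extracted_cloud(system, grid, noise_i)
    ga_i <- ga; ga_i$seed <- ga$seed + i
    res <- invert_dispersion(data, bounds, ga_i, cfg)
    th <- res$theta
    rows[[i]] <- data.frame(
      h_s_true = cs$h_s, material = cs$material, h_f = cs$h_f,
      n_points = data$n,
      h_s = th$h_s, VL3 = th$VL3, VL1 = th$VL1, VT = th$VT,
      err_h_s = 100 * abs(th$h_s - cs$h_s) / cs$h_s,
      err_VL3 = 100 * abs(th$VL3 - plate$VL3) / plate$VL3,
      err_VL1 = 100 * abs(th$VL1 - plate$VL1) / plate$VL1,
      err_VT = 100 * abs(th$VT - plate$VT) / plate$VT,
      F_opt = res$F_opt, inlier_percent = res$inlier_percent)
  }
  est <- do.call(rbind, rows)
  half_range_median <- function(x) 100 * (max(x) - min(x)) / 2 / stats::median(x)
  var_rows <- lapply(split(est, est$h_s_true), function(g) {
    data.frame(h_s_true = g$h_s_true[1], n_coatings = nrow(g),
               var_h_s = half_range_median(g$h_s),
               var_VL3 = half_range_median(g$VL3),
               var_VL1 = half_range_median(g$VL1),
               var_VT = half_range_median(g$VT))
  })
  structure(list(estimates = est,
                 variability = do.call(rbind, var_rows)),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("Free-plate inversion benchmark on coated plates\n")
  print(x$estimates[, c("h_s_true", "material", "h_f", "h_s", "err_h_s",
                        "VL3", "err_VL3", "VT", "err_VT", "F_opt")],
        row.names = FALSE, digits = 3)
  cat("\nVariability across coatings (half-range / median, %):\n")
  print(x$variability, row.names = FALSE, digits = 2)
  invisible(x)
}
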