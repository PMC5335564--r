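# Waveguide material and geometry descriptions.
#
# Unit system used throughout the package (self-consistent):
#   length mm, time us, frequency MHz, wavenumber rad/mm,
#   stiffness GPa, mass density g/cm3, velocity mm/us.
# In this system sqrt(GPa / (g/cm3)) = mm/us exactly.

#' Bulk wave velocities of a transverse-isotropic solid
#'
#' Converts stiffness coefficients and mass density into the three bulk wave
#' velocities that parametrize the plate model: the longitudinal velocities
#' normal to and along the symmetry axis, and the transverse velocity.
#'
#' @param c11,c33,c55 Stiffness coefficients in GPa. `c11` acts normal to the
#'   symmetry (fiber/bone) axis, `c33` along it, `c55` in shear.
#' @param rho_s Mass density in g/cm3.
#' @return Named numeric vector `c(VL1, VL3, VT)` in mm/us, with
#'   `VL1 = sqrt(c11/rho_s)`, `VL3 = sqrt(c33/rho_s)`, `VT = sqrt(c55/rho_s)`.
#' @examples
#' bulk_velocities(14.7, 22.1, 4.6, 1.65) # c(2.98, 3.66, 1.67) at 2 decimals
#' @export
bulk_velocities <- function(c11, c33, c55, rho_s) {
  if (any(!is.finite(c(c11, c33, c55, rho_s))) ||
      any(c(c11, c33, c55, rho_s) <= 0)) {
    stop("stiffness coefficients and density must be positive and finite")
  }
  c(VL1 = sqrt(c11 / rho_s), VL3 = sqrt(c33 / rho_s), VT = sqrt(c55 / rho_s))
}

#' Transverse-isotropic free plate
#'
#' A free plate waveguide described by its thickness and four stiffness-derived
#' parameters: two stiffness ratios and two bulk wave velocities. The mass
#' density is embedded in the velocities, so the free-plate dispersion
#' relation does not require it.
#'
#' @param h_s Plate thickness in mm.
#' @param r13 Stiffness ratio c13/c11 (dimensionless).
#' @param r33 Stiffness ratio c33/c11, the anisotropy ratio (dimensionless).
#' @param VL3 Longitudinal bulk wave velocity along the symmetry axis,
#'   `sqrt(c33/rho_s)`, in mm/us.
#' @param VT Transverse bulk wave velocity `sqrt(c55/rho_s)` in mm/us.
#' @return An object of class `elastic_plate` with derived field
#'   `VL1 = VL3/sqrt(r33)`.
#' @details Thermodynamic stability of the stiffness tensor requires
#'   `r13^2 < r33` (equivalently `c13^2 < c11 * c33`); the constructor
#'   enforces it, along with `VL1 > VT`.
#' @seealso [plate_from_stiffness()], [trace_plate_modes()]
#' @export
elastic_plate <- function(h_s, r13, r33, VL3, VT) {
  vals <- c(h_s = h_s, r13 = r13, r33 = r33, VL3 = VL3, VT = VT)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all plate parameters must be positive and finite")
  }
  if (r13^2 >= r33) {
    stop("thermodynamic stability requires r13^2 < r33 (c13^2 < c11*c33)")
  }
  VL1 <- VL3 / sqrt(r33)
  if (VL1 <= VT) {
    stop("longitudinal velocity VL1 = VL3/sqrt(r33) must exceed VT")
  }
  structure(list(h_s = h_s, r13 = r13, r33 = r33, VL3 = VL3, VT = VT,
                 VL1 = VL1),
            class = "elastic_plate")
}

#' Build a plate from stiffness coefficients and density
#'
#' @param c11,c33,c13,c55 Stiffness coefficients in GPa.
#' @param rho_s Mass density in g/cm3.
#' @param h_s Plate thickness in mm.
#' @return An [elastic_plate()] object.
#' @export
plate_from_stiffness <- function(c11, c33, c13, c55, rho_s, h_s) {
  v <- bulk_velocities(c11, c33, c55, rho_s)
  if (c13 <= 0) stop("c13 must be positive")
  elastic_plate(h_s = h_s, r13 = c13 / c11, r33 = c33 / c11,
                VL3 = v[["VL3"]], VT = v[["VT"]])
}

#' @export
print.elastic_plate <- function(x, ...) {
  cat("Transverse-isotropic free plate\n")
  cat(sprintf("  h_s = %.4g mm, c13/c11 = %.4g, c33/c11 = %.4g\n",
              x$h_s, x$r13, x$r33))
  cat(sprintf("  VL3 = %.4g, VL1 = %.4g, VT = %.4g mm/us\n",
              x$VL3, x$VL1, x$VT))
  invisible(x)
}

#' Fluid layer (soft-tissue mimic)
#'
#' @param c_f Compressional wave velocity in mm/us. Values outside
#'   `[1.3, 1.7]` trigger a warning, since soft tissue and its mimics lie in
#'   that band; the value is accepted.
#' @param rho_f Mass density in g/cm3.
#' @param h_f Layer thickness in mm.
#' @return An object of class `fluid_layer`.
#' @export
fluid_layer <- function(c_f, rho_f, h_f) {
  vals <- c(c_f = c_f, rho_f = rho_f, h_f = h_f)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all fluid layer parameters must be positive and finite")
  }
  if (c_f < 1.3 || c_f > 1.7) {
    warning("fluid velocity outside the soft-tissue band [1.3, 1.7] mm/us")
  }
  structure(as.list(vals), class = "fluid_layer")
}

#' @export
print.fluid_layer <- function(x, ...) {
  cat(sprintf("Fluid layer: c_f = %.4g mm/us, rho_f = %.4g g/cm3, h_f = %.4g mm\n",
              x$c_f, x$rho_f, x$h_f))
  invisible(x)
}

#' Fluid-solid bilayer waveguide
#'
#' A fluid layer resting on a transverse-isotropic plate. Unlike the free
#' plate, the bilayer dispersion relation requires the solid mass density
#' explicitly: it enters through the density ratio `gamma = rho_f/rho_s`
#' coupling the two subsystems.
#'
#' @param plate An [elastic_plate()].
#' @param rho_s Solid mass density in g/cm3 (required; cannot be folded into
#'   the velocity parameters).
#' @param fluid A [fluid_layer()].
#' @return An object of class `bilayer_system`.
#' @seealso [nondim_params()], [trace_bilayer_modes()]
#' @export
bilayer_system <- function(plate, rho_s, fluid) {
  if (!inherits(plate, "elastic_plate")) stop("`plate` must be an elastic_plate")
  if (!inherits(fluid, "fluid_layer")) stop("`fluid` must be a fluid_layer")
  if (missing(rho_s) || is.null(rho_s)) {
    stop("the bilayer model requires the solid mass density rho_s explicitly")
  }
  if (!is.finite(rho_s) || rho_s <= 0) stop("rho_s must be positive and finite")
  structure(list(plate = plate, rho_s = rho_s, fluid = fluid),
            class = "bilayer_system")
}

#' Nondimensional bilayer parameters
#'
#' @param system A [bilayer_system()].
#' @return Named vector `c(kappa_f, tau, gamma)`: the fluid-to-shear velocity
#'   ratio `c_f/VT`, the thickness ratio `h_f/h_s` and the density ratio
#'   `rho_f/rho_s`.
#' @export
nondim_params <- function(system) {
  stopifnot(inherits(system, "bilayer_system"))
  c(kappa_f = system$fluid$c_f / system$plate$VT,
    tau = system$fluid$h_f / system$plate$h_s,
    gamma = system$fluid$rho_f / system$rho_s)
}

#' @export
print.bilayer_system <- function(x, ...) {
  nd <- nondim_params(x)
  cat("Fluid-solid bilayer waveguide\n")
  print(x$plate)
  print(x$fluid)
  cat(sprintf("  rho_s = %.4g g/cm3; kappa_f = %.3g, tau = %.3g, gamma = %.3g\n",
              x$rho_s, nd[["kappa_f"]], nd[["tau"]], nd[["gamma"]]))
  invisible(x)
}

#' Dispersion computation grid
#'
#' Rectangular frequency-wavenumber window on which guided-mode branches are
#' traced. Defaults match a 1 MHz axial-transmission acquisition whose usable
#' band spans 0.4 to 1.6 MHz.
#'
#' @param f_min,f_max Band edges in MHz.
#' @param f_step Frequency step in MHz.
#' @param k_max Largest wavenumber in rad/mm.
#' @param k_step Wavenumber scan step in rad/mm; root refinement is much finer.
#' @return An object of class `dispersion_grid`.
#' @export
dispersion_grid <- function(f_min = 0.4, f_max = 1.6, f_step = 0.02,
                            k_max = 6.28, k_step = 0.02) {
  if (!(f_min > 0 && f_max > f_min)) stop("need 0 < f_min < f_max")
  if (f_step <= 0 || k_step <= 0 || k_max <= k_step) {
    stop("steps must be positive and k_max > k_step")
  }
  structure(list(f_min = f_min, f_max = f_max, f_step = f_step,
                 k_max = k_max, k_step = k_step),
            class = "dispersion_grid")
}

#' @export
print.dispersion_grid <- function(x, ...) {
  cat(sprintf("Grid: f in [%.3g, %.3g] MHz step %.3g; k up to %.3g rad/mm step %.3g\n",
              x$f_min, x$f_max, x$f_step, x$k_max, x$k_step))
  invisible(x)
}
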