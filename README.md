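# gwbone

Model-based analysis of ultrasonic guided waves in cortical-bone-like
waveguides.

Long bones guide ultrasound: in an axial-transmission measurement a linear
probe records several guided modes whose frequency–wavenumber relation
(the dispersion curves) encodes the cortical thickness and stiffness. This
package implements the full model-based chain for estimating those
properties, for researchers in bone quantitative ultrasound and guided-wave
NDE:

* **Forward solvers** — dispersion branches of a transverse-isotropic free
  plate (Lamb modes, parametrized by thickness `h_s`, stiffness ratios
  `c13/c11`, `c33/c11` and bulk velocities `VL3 = sqrt(c33/ρ)`,
  `VT = sqrt(c55/ρ)`) and of a fluid–solid bilayer (a soft-tissue-like
  layer on the plate, with explicit solid density and the nondimensional
  couplings `κ_f = c_f/VT`, `τ = h_f/h_s`, `γ = ρ_f/ρ_s`).
* **Synthetic data** — multichannel RF acquisitions of a 24-receiver /
  2×5-emitter probe and extracted dispersion point clouds with realistic
  statistics (wavenumber noise at the array resolution `π/L`, missing
  branches/segments, soft-tissue outliers, aperture-limited merging of
  close modes, energy-based detectability of coated-plate modes).
* **Extraction chain** — time FFT → per-frequency response matrix → SVD
  signal subspace → Norm-function projection of an attenuated plane-wave
  testing vector → dilation peak picking → bidirectional (tilt) correction
  by harmonic mean → repetition denoising → direction merging.
* **Inversion** — genetic-algorithm maximization of the *occupancy rate*
  `F(θ) = Σ N_in^i / N`: the fraction of measured points that are inliers
  (normalized distance ≤ `d0 = 0.025`) of the Lamb modes selected by a
  binary pairing vector, with activation rules that demand inliers form
  contiguous trajectories. A two-step check re-scores the data against the
  bilayer model built from the plate estimates.

## Worked example

Estimate thickness and stiffness of a coated bone-mimicking plate from a
synthetic extracted cloud:

```r
library(gwbone)

plate <- bone_mimic_plate(2.34)               # reference composite, 2.34 mm
system <- bilayer_system(plate, rho_s = 1.65,
                         fluid = fluid_layer(1.54, 1.03, 4))  # 4 mm Zerdine

cloud <- simulate_extracted_cloud(
  system, dispersion_grid(),
  extraction_noise_model(sigma_k = pi / 80, p_drop_point = 0.1,
                         n_outliers = 20, seed = 103))
cloud
#> Dispersion data: 156 points, window [0, 1.6] MHz x [0, 6.28] rad/mm, L = 20 mm

fit <- invert_dispersion(cloud, parameter_bounds(),
                         ga_config(population = 40, generations = 20,
                                   seed = 103))
fit
#> Free-plate inversion result
#>   F = 0.801 (inliers 85.3%)
#>   h_s = 2.307 mm, c13/c11 = 0.294, c33/c11 = 2.500, VL3 = 3.521, VT = 1.673
#>   pairing: A0 S0 A1 S1 A2 S2 A3 S3 A4 S4
#>  mode N_exp N_in N_th
#>    A0    15    7   59
#>    S0    43   42   60
#>    A1    29   27   62
#>    S1    29   28   57
#>    A2    14   12   33
#>    S2    19   16   44
#>    A3     6    0   26
#>    S3     0    0   11
#>    S4     1    1    8
```

The true values are `h_s = 2.34` mm, `VL3 = 3.66`, `VT = 1.67` mm/µs: the
thickness comes back within 1.4 %, the transverse velocity within 0.2 % and
the axial longitudinal velocity within 4 %. The occupancy rate F = 0.80
says that 80 % of the cloud lies on active free-plate modes; the per-mode
table shows which trajectories carry the estimate (S0, A1, S1 here — the
weakly solid A0 of the coated plate is mostly undetected, as in real
coated-phantom measurements). The stiffness *ratios* are only loosely
constrained by a single cloud; thickness and bulk velocities are the robust
outputs. Inserting the estimates into the bilayer forward model explains
part of what the free plate left over:

```r
two_step_validate(fit, cloud, rho_s = 1.65,
                  fluid = fluid_layer(1.54, 1.03, 4))
#> Two-step validation
#>   free plate :  85.3% inliers
#>   bilayer    :  90.4% inliers (17 modes)
#>   outliers newly explained by the bilayer: 13 of 156 points
```

`benchmark_suite()` runs the full grid of plate thicknesses × coatings and
summarizes recovery errors and the across-coating variability
(half-range/median). A thin command-line front end for the main verbs
(`simulate-points`, `invert`, `benchmark`) is in `inst/cli/gwbone.R`.

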