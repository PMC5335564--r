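test_that("two-step validation explains bilayer data fully with the truth", {
  p <- bone_plate(1.25)
  fl <- fluid_layer(1.43, 1.0, 4)
  bs <- bilayer_system(p, bone_ref$rho, fl)
  g <- dispersion_grid()
  bb <- trace_bilayer_modes(bs, g)
  dd <- sample_dispersion_points(bb, g, extraction_noise_model(sigma_k = 0,
                                                               seed = 2))
  # fabricate an inversion result holding the true plate
  res <- structure(list(theta = p,
                        assignments = data.frame(
                          mode = NA_integer_, distance = Inf,
                          inlier = rep(FALSE, dd$n)),
                        cfg = objective_config(),
                        grid = g),
                   class = "inversion_result")
  rep1 <- two_step_validate(res, dd, rho_s = bone_ref$rho, fluid = fl)
  expect_equal(rep1$bilayer_inlier_percent, 100)
  expect_equal(rep1$newly_explained, dd$n)
  expect_error(two_step_validate(res, dd, rho_s = NULL, fluid = fl), "rho_s")
})

test_that("with a vanishing coating the bilayer explains plate data like the plate", {
  p <- bone_plate(2)
  g <- dispersion_grid()
  br <- trace_plate_modes(p, g)
  dd <- sample_dispersion_points(br, g, extraction_noise_model(sigma_k = 0,
                                                               seed = 4))
  asg_p <- assign_inliers(dd, br)
  res <- structure(list(theta = p,
                        assignments = data.frame(mode = asg_p$mode,
                                                 distance = asg_p$distance,
                                                 inlier = asg_p$inlier),
                        cfg = objective_config(), grid = g),
                   class = "inversion_result")
  fl <- suppressWarnings(fluid_layer(1.5, 1e-6 * 1e6 * 1.65, 1e-6))
  rep1 <- two_step_validate(res, dd, rho_s = 1e6, fluid = fl)
  expect_equal(rep1$plate_inlier_percent, rep1$bilayer_inlier_percent,
               tolerance = 0.02)
})

test_that("variability statistic is half-range over median", {
  x <- c(1.28, 1.28, 1.31, 1.25)
  expect_equal(100 * (max(x) - min(x)) / 2 / median(x), 2.34, tolerance = 1e-2)
})

test_that("benchmark case table pairs plates with coatings", {
  cs <- benchmark_cases()
  expect_equal(nrow(cs), 12L)
  expect_setequal(unique(cs$h_s), c(1.25, 2.34, 3.48))
  expect_setequal(unique(cs$h_f), c(2, 4, 6, 8))
  m <- reference_materials()
  expect_equal(m$soft_tissue$c_f, 1.54)
  expect_equal(m$soft_tissue$rho_f, 1.00)
})

test_that("dispersion data round-trips through TSV", {
  dd <- dispersion_data(data.frame(f = c(0.5, 1.0), k = c(1.2, 2.4)),
                        f_max = 1.6, k_max = 6.28, L = 20)
  tf <- tempfile(fileext = ".tsv")
  write_dispersion(dd, tf)
  dd2 <- read_dispersion(tf)
  expect_equal(dd2$points, dd$points, tolerance = 1e-9)
  expect_equal(dd2$f_max, 1.6)
  expect_equal(dd2$L, 20)
})

test_that("branch export writes labeled rows with parameter headers", {
  p <- bone_plate(2)
  br <- trace_plate_modes(p, dispersion_grid(f_min = 0.8, f_max = 1.0,
                                             k_max = 3, k_step = 0.02))
  tf <- tempfile(fileext = ".tsv")
  export_branches(br, tf, params = list(h_s = 2))
  lines <- readLines(tf)
  expect_true(any(grepl("^# h_s = 2", lines)))
  tab <- utils::read.table(tf, header = TRUE, sep = "\t", comment.char = "#")
  expect_named(tab, c("mode_label", "f_MHz", "k_rad_per_mm"))
  expect_gt(nrow(tab), 0)
})
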