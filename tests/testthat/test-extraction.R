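test_that("response matrix keeps the signal energy (Parseval) and shape", {
  sim <- two_mode_rf()
  R <- build_response_matrix(sim$rf$plus)
  expect_equal(dim(R$R[[1]]), c(24L, 5L))
  tr <- sim$rf$plus$signals[1, 1, ]
  sp <- stats::fft(tr)
  expect_equal(sum(tr^2), sum(Mod(sp)^2) / length(sp), tolerance = 1e-10)
  rf0 <- sim$rf$plus; rf0$signals[] <- 0
  expect_true(all(vapply(build_response_matrix(rf0)$R,
                         function(m) all(m == 0), TRUE)))
})

test_that("svd keeps an orthonormal basis and flags rank", {
  sim <- two_mode_rf(noise_floor = 0)
  R <- build_response_matrix(sim$rf$plus)
  B <- svd_denoise(R, 3)
  U <- B$U[[30]]
  expect_equal(Conj(t(U)) %*% U, diag(3) + 0i, tolerance = 1e-10)
  # two clean modes: exactly two significant singular values
  d <- svd(R$R[[30]])$d
  expect_lt(d[3] / d[1], 1e-8)
  expect_error(svd_denoise(R, 9), "n_keep")
})

test_that("norm function peaks at the true wavenumbers and stays in [0,1]", {
  sim <- two_mode_rf(noise_floor = 0)
  R <- build_response_matrix(sim$rf$plus)
  B <- svd_denoise(R, 3)
  kg <- seq(0.05, 3.5, by = 0.01)
  NS <- norm_function(B, kg, alpha = 0.05)
  expect_true(all(NS$values >= 0 & NS$values <= 1 + 1e-12))
  i <- which.min(abs(NS$freqs - 1.0))
  pk <- extract_peaks(NS, radius = 3, floor = 0.5)
  pk1 <- pk[pk$f == NS$freqs[i], ]
  kt <- vapply(sim$branches, function(b) {
    stats::approx(b$points[, "f"], b$points[, "k"], xout = NS$freqs[i])$y
  }, 0)
  for (k0 in kt) {
    expect_lt(min(abs(pk1$k - k0)), 2 * pi / 20)
  }
  expect_error(norm_function(B, seq(0.1, 5, 0.1)), "Nyquist")
})

test_that("norm surface is invariant to overall RF amplitude", {
  sim <- two_mode_rf()
  rf2 <- sim$rf$plus; rf2$signals <- rf2$signals * 37
  kg <- seq(0.05, 3.5, by = 0.02)
  n1 <- norm_function(svd_denoise(build_response_matrix(sim$rf$plus), 3), kg)
  n2 <- norm_function(svd_denoise(build_response_matrix(rf2), 3), kg)
  expect_equal(n1$values, n2$values, tolerance = 1e-8)
})

test_that("peak picker implements the dilation rule with leftmost ties", {
  surf <- structure(list(freqs = 1, k_grid = seq_len(9) / 10,
                         values = matrix(c(0.1, 0.2, 0.8, 0.8, 0.8, 0.2,
                                           0.1, 0.9, 0.3), nrow = 1),
                         alpha = 0), class = "norm_surface")
  pk <- extract_peaks(surf, radius = 2, floor = 0.5)
  expect_equal(pk$k, c(0.3, 0.8))   # plateau keeps its leftmost bin
  pk2 <- extract_peaks(surf, radius = 2, floor = 0.95)
  expect_equal(nrow(pk2), 0)
})

test_that("bidirectional correction is the harmonic mean of matched peaks", {
  pp <- data.frame(f = 1, k = 2.0, value = 0.9)
  pm <- data.frame(f = 1, k = 2.2, value = 0.8)
  out <- bidirectional_correct(pp, pm, L = 15)  # matching window pi/L > 0.2
  expect_equal(out$k, 2 * 2.0 * 2.2 / (2.0 + 2.2), tolerance = 1e-12)
  expect_true(out$matched)
  # symmetric inputs pass through unchanged
  out2 <- bidirectional_correct(pp, pp, L = 15)
  expect_equal(out2$k, 2.0)
  expect_warning(bidirectional_correct(pp, pp[0, ], L = 20), "no peaks")
})

test_that("repetition vote keeps repeated points and averages jitter", {
  base <- data.frame(f = 1, k = 2.0, value = 1)
  reps <- lapply(1:10, function(i) {
    if (i <= 8) data.frame(f = 1, k = 2.0 + 0.01 * (i - 4), value = 1)
    else data.frame(f = 1, k = 4.5, value = 1)
  })
  dd <- denoise_repetitions(reps, min_votes = 5, tol_k = pi / 40)
  expect_equal(dd$n, 1L)
  expect_equal(dd$points$k, mean(2.0 + 0.01 * ((1:8) - 4)), tolerance = 1e-9)
  expect_error(denoise_repetitions(reps, min_votes = 11), "min_votes")
})

test_that("end-to-end extraction recovers the branches within pi/L", {
  sim <- lapply(1:6, function(s) two_mode_rf(seed = s)$rf)
  branches <- two_mode_rf(seed = 1)$branches
  dd <- extract_dispersion(sim, min_votes = 3)
  err <- truth_error(dd, branches)
  expect_gt(mean(err < pi / 20), 0.9)
})

test_that("bidirectional correction cancels the tilt bias", {
  tilted <- lapply(1:3, function(s) two_mode_rf(seed = s, tilt = 5)$rf)
  branches <- two_mode_rf(seed = 1)$branches
  dd <- extract_dispersion(tilted, min_votes = 2)
  err_corr <- stats::median(truth_error(dd, branches))
  # single-direction extraction at the same tilt
  one_dir <- lapply(tilted, function(acq) list(plus = acq$plus,
                                               minus = acq$plus))
  dd1 <- extract_dispersion(one_dir, min_votes = 2)
  err_raw <- stats::median(truth_error(dd1, branches))
  expect_lt(err_corr, err_raw)
})
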