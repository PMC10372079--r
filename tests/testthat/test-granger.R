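var_150 <- function() {
  # x has an AR(2) resonance at 150 Hz (fs 1000); x drives y
  A <- array(0, c(2, 2, 2))
  r <- 0.9
  A[1, 1, 1] <- 2 * r * cos(2 * pi * 0.15); A[1, 1, 2] <- -r^2
  A[2, 2, 1] <- 0.5
  A[2, 1, 1] <- 0.4
  A
}

test_that("VAR coefficients are recovered from window-pooled least squares", {
  A <- var_150()
  sim <- simulate_var(A, diag(2), 1e5, fs = 1000, seed = 30)
  vf <- fit_var_windows(sim$x, sim$y, 1000, window_s = 0.5, order = 2)
  expect_equal(vf$A[1, 1, 1], A[1, 1, 1], tolerance = 0.02)
  expect_equal(vf$A[1, 1, 2], A[1, 1, 2], tolerance = 0.02)
  expect_equal(vf$A[2, 1, 1], A[2, 1, 1], tolerance = 0.02)
  expect_equal(vf$A[1, 2, 1], 0, tolerance = 0.02)
  expect_equal(vf$Sigma, diag(2), tolerance = 0.05)

  set.seed(31)
  wn <- matrix(rnorm(2e4), ncol = 2)
  vf0 <- fit_var_windows(wn[, 1], wn[, 2], 1000, order = 2)
  expect_lt(max(abs(vf0$A[1, 2, ]), abs(vf0$A[2, 1, ])), 0.05)

  x <- sin(2 * pi * 10 * (1:20000) / 1000)
  expect_error(fit_var_windows(x, x, 1000), "singular|ill-conditioned")
  expect_error(fit_var_windows(wn[1:3000, 1], wn[1:3000, 2], 1000),
               "at least 20 windows")
})

test_that("Geweke spectra find the coupling peak with the right direction", {
  A <- var_150()
  sim <- simulate_var(A, diag(2), 6e4, fs = 1000, seed = 32)
  gc <- gc_spectrum(fit_var_windows(sim$x, sim$y, 1000))
  pk <- gc_peak(gc, "xy")
  expect_equal(pk$freq, 150, tolerance = 3)
  expect_lt(max(gc$gc_yx), 0.1 * pk$height)

  # analytic oracle from the true coefficients
  vf_true <- structure(list(A = A, Sigma = diag(2), fs = 1000, order = 2),
                       class = "var_fit")
  gct <- gc_spectrum(vf_true)
  pkt <- gc_peak(gct, "xy")
  expect_equal(pk$height, pkt$height, tolerance = 0.05 * pkt$height)
  expect_equal(pk$freq, pkt$freq, tolerance = 2)

  # independent channels: causality below 0.01 everywhere
  sim0 <- simulate_var(array(0, c(2, 2, 1)), diag(2), 6e4, fs = 1000,
                       seed = 33)
  gc0 <- gc_spectrum(fit_var_windows(sim0$x, sim0$y, 1000))
  expect_lt(max(gc0$gc_xy, gc0$gc_yx), 0.01)

  # swapping inputs swaps directions exactly
  vfa <- fit_var_windows(sim$x, sim$y, 1000, order = 2)
  vfb <- fit_var_windows(sim$y, sim$x, 1000, order = 2)
  ga <- gc_spectrum(vfa); gb <- gc_spectrum(vfb)
  expect_equal(ga$gc_xy, gb$gc_yx, tolerance = 1e-9)
  expect_equal(ga$gc_yx, gb$gc_xy, tolerance = 1e-9)

  # unstable VAR is refused
  Au <- array(0, c(2, 2, 1)); Au[1, 1, 1] <- 1.01; Au[2, 2, 1] <- 0.5
  vfu <- structure(list(A = Au, Sigma = diag(2), fs = 1000, order = 1),
                   class = "var_fit")
  expect_gt(var_spectral_radius(vfu), 1)
  expect_error(gc_spectrum(vfu), "unstable")
})

test_that("the VAR-analytic spectrum matches the data spectrum at the fitted order", {
  A <- var_150()
  sim <- simulate_var(A, diag(2), 1e5, fs = 1000, seed = 34)
  vf <- fit_var_windows(sim$x, sim$y, 1000, order = 2)
  # analytic S_xx(f) from the fitted VAR vs averaged periodogram
  fs <- 1000
  freqs <- c(50, 100, 150, 200)
  Sxx_var <- vapply(freqs, function(f) {
    Af <- diag(2) + 0i
    for (k in 1:2) Af <- Af - vf$A[, , k] * exp(-2i * pi * f * k / fs)
    H <- solve(Af)
    Re((H %*% vf$Sigma %*% Conj(t(H)))[1, 1]) * 2 / fs
  }, numeric(1))
  n_seg <- 100; nn <- 1000
  acc <- 0
  for (k in seq_len(n_seg)) {
    seg <- sim$x[((k - 1) * nn + 1):(k * nn)]
    seg <- (seg - mean(seg))
    acc <- acc + 2 * Mod(fft(seg))^2 / (fs * nn)
  }
  Sxx_data <- (acc / n_seg)[freqs + 1]
  expect_equal(Sxx_var, Sxx_data, tolerance = 0.1)
})

test_that("band summaries retain qualifying peaks and mark missing directed pairs", {
  A <- var_150()
  sim <- simulate_var(A, diag(2), 6e4, fs = 1000, seed = 35)
  gc <- gc_spectrum(fit_var_windows(sim$x, sim$y, 1000))
  bs <- band_summary(list(list(gc = gc, structure_x = "vStr",
                               structure_y = "mPFC")), hfo_freq = 150)
  fwd <- bs$summary[bs$summary$from == "vStr", ]
  rev <- bs$summary[bs$summary$from == "mPFC", ]
  expect_false(is.na(fwd$median_peak))
  expect_true(is.na(rev$median_peak))      # reverse peak below 0.2: missing
  expect_gte(fwd$median_peak, 5 * max(gc$gc_yx))
  expect_equal(bs$peak_freqs, gc_peak(gc, "xy")$freq, tolerance = 1e-9)
  # mean HFO-band causality dwarfs the gamma band for 150 Hz coupling
  row_fwd <- bs$pairs[bs$pairs$from == "vStr", ]
  expect_gt(row_fwd$mean_gc_hfo, row_fwd$mean_gc_gamma)
})
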