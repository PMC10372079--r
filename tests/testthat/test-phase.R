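test_that("narrowband filter passes f0, rejects out-of-band tones, zero phase", {
  fs <- 1000
  t <- (0:19999) / fs
  mid <- 5000:15000
  s0 <- sin(2 * pi * 150 * t)
  y0 <- narrowband(s0, fs, 150)
  expect_gt(sd(y0[mid]) / sd(s0[mid]), 0.99)
  expect_lt(sd(y0[mid]) / sd(s0[mid]), 1.01)

  s40 <- sin(2 * pi * 190 * t)
  expect_lt(20 * log10(sd(narrowband(s40, fs, 150)[mid]) / sd(s40[mid])), -20)

  imp <- numeric(2001); imp[1001] <- 1
  yi <- narrowband(imp, fs, 150)
  expect_equal(yi, rev(yi), tolerance = 1e-10)  # symmetric = zero phase
  expect_equal(which.max(abs(yi)), 1001)

  expect_error(narrowband(s0, fs, 499, halfwidth = 5), "Nyquist")
  expect_error(narrowband(s0, fs, 3, halfwidth = 5), "Nyquist")
})

test_that("analytic series implements the trough-at-zero convention", {
  fs <- 2000
  t <- (0:39999) / fs
  x <- 3.5 * cos(2 * pi * 127 * t)
  a <- analytic(x, 127, fs)
  mid <- 4000:36000
  expect_equal(median(a$amplitude[mid]), 3.5, tolerance = 0.01)
  # phase equals the closed form wrap(2*pi*f0*t + pi): trough -> 0, peak -> pi
  expected <- wrap_angle(2 * pi * 127 * t + pi)
  err <- wrap_angle(a$phase[mid] - expected[mid])
  expect_lt(max(abs(err)), 0.02)
  # frequency consistency of the unwrapped slope
  dphi <- wrap_angle(diff(a$phase[mid]))
  expect_equal(mean(dphi) * fs / (2 * pi), 127, tolerance = 0.5)

  a0 <- analytic(numeric(100))
  expect_false(a0$defined)
  expect_true(all(is.na(a0$phase)))
})

test_that("a Gaussian spindle envelope is recovered without broadening at 2 kHz", {
  fs <- 2000
  t <- (0:19999) / fs
  sig <- 0.050 / 2.355           # 50 ms FWHM bump
  env <- 40 * exp(-(t - 5)^2 / (2 * sig^2))
  a <- analytic(narrowband(env * cos(2 * pi * 127 * t), fs, 127), 127, fs)
  half <- max(a$amplitude) / 2
  fwhm_ms <- diff(range(t[a$amplitude > half])) * 1000
  expect_equal(fwhm_ms, 50, tolerance = 0.1)  # 50 +- 5 ms
})

test_that("amplitude autocorrelation: white noise is delta-like, theta modulation shows side peaks", {
  set.seed(12)
  fs <- 1000
  amp <- abs(rnorm(fs * 120, mean = 20, sd = 3))
  ac <- amplitude_autocorr(amp, fs, min_median_uV = 0)
  expect_lt(max(abs(ac$acf[-1])), 0.05)  # delta at lag 0

  tt <- (0:(fs * 120 - 1)) / fs
  amp_theta <- 20 + 5 * sin(2 * pi * 7 * tt) + rnorm(fs * 120, 0, 0.5)
  act <- amplitude_autocorr(amp_theta, fs, min_median_uV = 0)
  side <- act$lags >= 0.120 & act$lags <= 0.165
  i_side <- which(side)[which.max(act$acf[side])]
  expect_equal(act$lags[i_side], 1 / 7, tolerance = 0.01)

  low <- amplitude_autocorr(rep(1, fs * 60), fs, min_median_uV = 15)
  expect_true(low$excluded)
})

test_that("amplitude cross-correlation separates identical, correlated and independent envelopes", {
  set.seed(13)
  fs <- 1000
  smooth <- function(x) as.numeric(stats::filter(x, rep(1 / 50, 50),
                                                 circular = TRUE))
  e1 <- 20 + 5 * smooth(rnorm(fs * 120))
  e2 <- 20 + 5 * smooth(rnorm(fs * 120))
  cc_same <- amplitude_crosscorr(e1, e1, fs)
  expect_equal(cc_same$peak, 1, tolerance = 1e-6)
  expect_equal(cc_same$lag_s, 0)
  cc_ind <- amplitude_crosscorr(e1, e2, fs)
  expect_lt(abs(cc_ind$peak), 0.1)
  expect_true(amplitude_crosscorr(e1 * 0 + 1, e2, fs)$excluded)
})

test_that("phase-pair statistics: antisymmetry, swap-invariant inversion, jittered lag recovery", {
  set.seed(14)
  n <- 60000
  phi <- wrap_angle(cumsum(rep(2 * pi * 127 / 1000, n)))
  jit <- rvonmises(n, 0, 5)
  phi_j <- wrap_angle(phi - 0.3 + jit)
  amp <- rep(10, n)
  p_ij <- phase_pair(phi, phi_j, amp, amp, fs = 1000, gate = FALSE)
  expect_lt(abs(p_ij$dphi - 0.30), 0.03)
  p_ji <- phase_pair(phi_j, phi, amp, amp, fs = 1000, gate = FALSE)
  expect_equal(p_ji$dphi, -p_ij$dphi, tolerance = 1e-9)
  expect_identical(p_ij$inverted, p_ji$inverted)

  p_same <- phase_pair(phi, phi, fs = 1000)
  expect_equal(p_same$dphi, 0)
  expect_equal(p_same$r, 1)
  expect_false(p_same$inverted)

  p_inv <- phase_pair(phi, wrap_angle(phi - pi + 0.3 * jit / 5), fs = 1000)
  expect_true(abs(p_inv$dphi) > 3 * pi / 4 && p_inv$kappa > 1)
  expect_true(p_inv$inverted)
})

test_that("structure phase map orients lags as structure-leads-reference and screens r", {
  set.seed(15)
  n <- 20000
  phi_ref <- wrap_angle(cumsum(rep(2 * pi * 0.127, n)))
  mk_ana <- function(lag, noisy = FALSE) {
    ph <- if (noisy) runif(n, -pi, pi) else wrap_angle(phi_ref + lag)
    structure(list(phase = ph, amplitude = rep(10, n), f0 = 127, fs = 1000,
                   defined = TRUE), class = "analytic_series")
  }
  channels <- data.frame(channel_id = 1:5,
                         structure = c("OB", "OB", "vStr", "vStr", "mPFC"),
                         hemisphere = "left", electrode_group = 1L)
  ana <- list("1" = mk_ana(0), "2" = mk_ana(0), "3" = mk_ana(0.2),
              "4" = mk_ana(0.2), "5" = mk_ana(0, noisy = TRUE))
  pairs <- phase_pair_table(ana, channels, gate = FALSE)
  expect_warning(mp <- structure_phase_map(pairs, "OB"), "mPFC")
  vstr <- mp$map[mp$map$structure == "vStr", ]
  expect_lt(abs(vstr$median_lag - 0.2), 1e-6)            # vStr leads OB
  expect_equal(vstr$n_pairs, 4)                          # 2x2 cross pairs
  expect_false("mPFC" %in% mp$map$structure)             # r screen dropped it
})
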