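test_that("rate standardisation matches Poisson moments", {
  set.seed(16)
  inj <- 3600
  # null: equal rate in both epochs
  st_null <- cumsum(rexp(4 * 3600 * 2, 2))
  zr <- standardize_rates(st_null, inj)
  expect_false(zr$excluded)
  expect_lt(abs(zr$mean_z_drug), 0.3)
  zb <- zr$z$z[zr$z$epoch == "baseline"]
  expect_equal(mean(zb), 0, tolerance = 1e-9)
  expect_equal(sd(zb), 1, tolerance = 1e-9)

  # rate doubling 2 -> 4 Hz: z per 10-s bin = (40 - 20) / sqrt(20)
  st_up <- c(cumsum(rexp(2 * 3600 * 2, 2)))
  st_up <- st_up[st_up < inj]
  st_up <- c(st_up, inj + cumsum(rexp(4 * 3600 * 2, 4)))
  zr_up <- standardize_rates(st_up, inj)
  expect_lt(abs(zr_up$mean_z_drug - 20 / sqrt(20)), 0.7)

  # silent baseline is excluded with a reason
  ze <- standardize_rates(c(inj + 100, inj + 200), inj)
  expect_true(ze$excluded)
  expect_match(ze$reason, "zero baseline SD")
})

test_that("unit modulation classifies strong rate changes and reports the tail test", {
  set.seed(17)
  inj <- 3600
  st <- c(cumsum(rexp(1 * 3600 * 2, 1)))
  st <- c(st[st < inj], inj + cumsum(rexp(3 * 3600 * 2, 3)))
  um <- unit_modulation(st, inj)
  expect_equal(um$class, "up")
  expect_lt(um$p, 1e-10)

  # 40 of 100 units modulated in one direction at alpha = 0.01
  expect_lt(population_modulation_test(40, 100, alpha = 0.01), 1e-10)
  expect_gt(population_modulation_test(1, 100, alpha = 0.01), 0.05)
  expect_error(unit_modulation(c(1, 2, 3), 50,
                               baseline = epoch("baseline", -50, -20),
                               drug = epoch("drug", 10, 40)),
               "at least 10 bins")
})

test_that("waveform features use interpolated FWHM and scale equivariantly", {
  wf_fs <- 32000
  t <- seq(0, 0.003, by = 1 / wf_fs)
  sig <- 0.0001                                  # 0.1 ms Gaussian valley
  w <- -80 * exp(-(t - 0.001)^2 / (2 * sig^2)) +
    30 * exp(-(t - 0.0016)^2 / (2 * 0.0002^2))
  ft <- waveform_features(w, wf_fs)
  expect_true(ft$reliable)
  expect_equal(ft$valley_width, 2.355 * 0.1, tolerance = 0.02)
  expect_equal(ft$peak_to_valley, 0.6, tolerance = 0.04)

  # time-stretching doubles all three features
  w2 <- -80 * exp(-(t - 0.001)^2 / (2 * (2 * sig)^2)) +
    30 * exp(-(t - 0.0022)^2 / (2 * 0.0004^2))
  ft2 <- waveform_features(w2, wf_fs)
  expect_equal(ft2$valley_width / ft$valley_width, 2, tolerance = 0.05)
  expect_equal(ft2$peak_to_valley, 1.2, tolerance = 0.05)

  mono <- -80 * exp(-(t - 0.002)^2 / (2 * sig^2))
  expect_false(waveform_features(mono, wf_fs)$reliable)
})

test_that("fuzzy classification separates narrow from broad spiking and abstains when symmetric", {
  set.seed(18)
  feats <- do.call(rbind, lapply(1:60, function(i) {
    ct <- if (i <= 30) "PC" else "IN"
    as.data.frame(unclass(
      waveform_features(hfosync:::.gen_waveform(ct, 32000), 32000))[1:3])
  }))
  cl <- classify_cells(feats)
  truth <- rep(c("PC", "IN"), each = 30)
  agree <- mean(cl$labels == truth)
  expect_gte(agree, 0.95)
  expect_lt(mean(cl$labels == "X"), 0.10)
  # IN cluster must be the narrow-spiking one
  expect_lt(mean(feats$peak_to_valley[cl$labels == "IN"]),
            mean(feats$peak_to_valley[cl$labels == "PC"]))

  # single tight cluster duplicated: no real structure, so abstention
  # rises sharply relative to the separated case (z-scoring inflates the
  # jitter, so points near the arbitrary split still get confident labels)
  one <- feats[1:30, ] + matrix(rnorm(90, 0, 1e-3), 30)
  cl1 <- classify_cells(rbind(one, one))
  expect_gt(mean(cl1$labels == "X"), 0.25)

  degen <- feats; degen$valley_width <- 1
  expect_error(classify_cells(degen), "zero variance")
})

test_that("spike entrainment excludes the unit's own electrode and recovers the preferred phase", {
  set.seed(19)
  fs <- 1000; n <- 300000
  phi <- wrap_angle(cumsum(rep(2 * pi * 127 / fs, n)))
  mk <- function(ph) structure(list(phase = ph, amplitude = rep(10, n),
                                    f0 = 127, fs = fs, defined = TRUE),
                               class = "analytic_series")
  channels <- data.frame(channel_id = 1:3, structure = "vStr",
                         hemisphere = "left", electrode_group = 1L)
  ana <- list("1" = mk(wrap_angle(phi + 2)),   # the unit's own electrode: corrupted
              "2" = mk(phi), "3" = mk(phi))
  # spikes at phase -2: sample times where phi ~ -2
  cand <- which(abs(wrap_angle(phi + 2)) < 0.05)
  st <- (sort(sample(cand, min(3000, length(cand)))) - 1) / fs
  u <- spike_unit("u1", st, electrode = 1)
  er <- spike_entrainment(u, ana, channels)
  expect_false(er$skipped)
  expect_lt(abs(er$mu - -2), 0.05)
  expect_lt(er$rayleigh_p, 1e-10)
  expect_true(er$entrained)
  expect_true(er$includable)

  # uniform spiking: not entrained
  st_u <- sort(runif(2000, 0, n / fs))
  er_u <- spike_entrainment(spike_unit("u2", st_u, 1), ana, channels)
  expect_gt(er_u$rayleigh_p, 0.001)

  # no eligible channel
  ch1 <- channels[1, ]
  er_skip <- spike_entrainment(u, ana["1"], ch1)
  expect_true(er_skip$skipped)
  er_few <- spike_entrainment(spike_unit("u3", st[1:10], 1), ana, channels)
  expect_true(er_few$skipped)
})

test_that("Bhattacharyya distance matches closed forms and is symmetric and affine-invariant", {
  set.seed(20)
  a <- matrix(rnorm(300), 100, 3)
  expect_equal(bhattacharyya(a, a), 0, tolerance = 1e-12)

  skip_if_not_installed("MASS")
  x <- MASS::mvrnorm(2000, c(0, 0), diag(2), empirical = TRUE)
  y <- MASS::mvrnorm(2000, c(2, 0), diag(2), empirical = TRUE)
  expect_equal(bhattacharyya(x, y), 0.5, tolerance = 1e-9)
  y2 <- MASS::mvrnorm(2000, c(0, 0), 4 * diag(2), empirical = TRUE)
  expect_equal(bhattacharyya(x, y2), log(2.5 / 2), tolerance = 1e-9)

  expect_equal(bhattacharyya(x, y), bhattacharyya(y, x), tolerance = 1e-12)
  A <- matrix(c(2, 0.5, -1, 3), 2); b <- c(5, -7)
  xt <- sweep(x %*% t(A), 2, b, "+")
  yt <- sweep(y %*% t(A), 2, b, "+")
  expect_equal(bhattacharyya(xt, yt), bhattacharyya(x, y), tolerance = 1e-9)

  sing <- cbind(1:50, (1:50) * 2)
  expect_error(bhattacharyya(sing, sing + 1), "singular")
})
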