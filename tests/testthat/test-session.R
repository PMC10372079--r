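make_mini_session <- function(with_accel = TRUE, with_units = TRUE) {
  set.seed(3)
  fs <- 200
  lfp <- matrix(rnorm(4 * fs * 30), 4, fs * 30)
  channels <- data.frame(channel_id = 1:4,
                         structure = c("vStr", "vStr", "OB", "OB"),
                         hemisphere = c("left", "left", "right", "right"),
                         electrode_group = c(1L, 1L, 2L, 2L),
                         ap = 1.2, ml = -2.0, dv = 6.5)
  units <- if (with_units) list(
    spike_unit("u1", sort(runif(40, 0, 30)), electrode = 2,
               waveform = rnorm(96), wf_fs = 32000, cell_type = "PC")) else list()
  accel <- if (with_accel) matrix(rnorm(3 * 100 * 30, sd = 0.1), 3) else NULL
  session(lfp, fs, channels, units = units, accel = accel,
          fs_accel = if (with_accel) 100 else NULL,
          injection_time = 15, drug = "LSD", drug_class = "5HT2A")
}

test_that("session container round-trips losslessly", {
  s <- make_mini_session()
  p <- file.path(tempdir(), "sess_rt")
  write_session(s, p)
  s2 <- read_session(p)
  expect_equal(s2$lfp, s$lfp, tolerance = 1e-9)
  expect_equal(s2$channels$structure, s$channels$structure)
  expect_equal(s2$fs_lfp, s$fs_lfp)
  expect_equal(s2$units[[1]]$spike_times, s$units[[1]]$spike_times,
               tolerance = 1e-12)
  expect_equal(s2$units[[1]]$waveform, s$units[[1]]$waveform,
               tolerance = 1e-12)
  expect_equal(s2$accel, s$accel, tolerance = 1e-9)
  expect_equal(s2$injection_time, 15)
  expect_equal(s2$drug, "LSD")
  unlink(p, recursive = TRUE)
})

test_that("optional blocks are tolerated and malformed containers are named errors", {
  s <- make_mini_session(with_accel = FALSE, with_units = FALSE)
  p <- file.path(tempdir(), "sess_noacc")
  write_session(s, p)
  s2 <- read_session(p)
  expect_null(s2$accel)
  expect_length(s2$units, 0)

  file.remove(file.path(p, "lfp.csv"))
  expect_error(read_session(p), "lfp.csv")
  unlink(p, recursive = TRUE)
})

test_that("session validation catches shape and unit-time violations", {
  s <- make_mini_session()
  bad <- s; bad$lfp <- bad$lfp[1:3, ]
  expect_error(validate_session(bad), "3 rows.*4 channels")
  bad2 <- s; bad2$units[[1]]$spike_times <- c(1, 99)  # beyond 30 s recording
  expect_error(validate_session(bad2), "outside the recording")
  expect_error(session(s$lfp, -1, s$channels), "positive")
})

test_that("bipolar derivation pairs same-structure channels and rejects common mode", {
  set.seed(4)
  fs <- 100
  common <- rnorm(fs * 10)
  local1 <- sin(2 * pi * 7 * (1:(fs * 10)) / fs)
  lfp <- rbind(common + local1, common, common - local1, common + 2)
  channels <- data.frame(channel_id = 1:4, structure = "vStr",
                         hemisphere = "left", electrode_group = 1L,
                         ap = 0, ml = 0, dv = 0)
  s <- session(lfp, fs, channels)
  bp <- make_bipolar(s, "vStr")
  expect_length(bp, choose(4, 2))
  # pair (1,2): common mode cancels, local signal survives
  b12 <- bp[[1]]
  expect_equal(b12$pair, c(1, 2))
  expect_equal(b12$series, local1, tolerance = 1e-12)
  # sign-inverted common oscillation doubles: channels 1 and 3
  b13 <- Filter(function(b) all(b$pair == c(1, 3)), bp)[[1]]
  expect_equal(sd(b13$series), 2 * sd(local1), tolerance = 1e-6)
  expect_length(make_bipolar(s, "OB"), 0)
})

test_that("epoch slicing respects boundaries, warns on no overlap, and is idempotent", {
  # spikes at -40, -10, +45 min relative to a 60-min injection
  inj <- 60 * 60
  spikes <- inj + c(-40, -10, 45) * 60
  kept <- slice_epoch(spikes, inj, epoch("baseline"))
  expect_equal(kept, inj - 10 * 60)
  expect_equal(slice_epoch(kept, inj, epoch("baseline")), kept)

  # 120-min recording, injection at 60 min: drug epoch is a 30-min slice
  fs <- 10
  x <- rnorm(fs * 120 * 60)
  sl <- slice_epoch(x, inj, epoch("drug"), fs = fs)
  expect_equal(length(sl), 30 * 60 * fs)
  expect_equal(attr(sl, "t0"), inj + 30 * 60)
  sl2 <- slice_epoch(sl, inj, epoch("drug"), fs = fs)
  expect_equal(as.numeric(sl2), as.numeric(sl))

  expect_warning(slice_epoch(x[1:100], inj, epoch("drug"), fs = fs),
                 "no overlap")
  expect_warning(out <- slice_epoch(spikes, inj + 1e6, epoch("baseline")),
                 "no overlap")
  expect_length(out, 0)
})
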