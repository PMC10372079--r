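# Synthetic sessions with full ground truth: 1/f^beta fractal background,
# band-limited gamma, spindle-modulated HFO carriers with controlled
# inter-channel phase lags/inversions and amplitude co-modulation, Poisson
# spike trains with von Mises phase preference, and accelerometer traces with
# injected 8-32 Hz twitch bursts.

#' Configuration for synthetic sessions
#'
#' Returns the full parameter block for [gen_session()], with defaults chosen
#' to emulate the recording conditions of chronic multi-structure rodent
#' sessions: 1 kHz LFP, 60 min baseline followed by 60 min on drug, ~150 Hz
#' spindle-modulated HFOs (~50 ms envelope FWHM) that are sporadic during
#' baseline and persistent after injection, 1/f^2 fractal background, and
#' entrained spiking. Presets set the HFO carrier to the class-typical
#' frequency: 127 Hz for 5-HT2A agonists, 143 Hz for NMDA antagonists;
#' the amphetamine preset boosts gamma without HFOs.
#'
#' @param preset one of "5HT2A", "NMDA", "amphetamine", "baseline".
#' @param ... named overrides of any top-level or nested field (nested blocks
#'   are merged with [utils::modifyList()]).
#' @return nested list of class `synth_config`.
#' @export
synth_config <- function(preset = c("5HT2A", "NMDA", "amphetamine", "baseline"),
                         ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    fs = 2000,
    duration = 7200,
    injection_time = 3600,
    structures = c(OB = 2L, OC = 2L, vStr = 2L, OFC = 2L, mPFC = 2L),
    fractal = list(beta = 2, scale = 5000),       # uV^2/Hz at 1 Hz
    gamma = list(band = c(30, 80), rms = 3),      # uV
    hfo = list(
      carrier_freq = 150, carrier_sd = 3, carrier_tau = 2,
      spindle_rate = 12, envelope_fwhm = 0.050, amplitude = 80,
      structure_lags = NULL,       # named rad; NULL = all zero
      inverted_channels = integer(0),
      rho = 0.8,                   # between-structure envelope co-modulation
      baseline_frac = 0.05,        # spindle-rate fraction before injection
      channel_gain_range = c(0.6, 1.4)  # per-electrode dipole coupling
    ),
    spikes = list(
      n_per_structure = 2L, base_rate = 5, kappa = 0.3,
      preferred_phase = -2.0, frac_entrained = 1, wf_fs = 32000
    ),
    rate_modulation = c(PC = 1, IN = 1, X = 1),
    htr = list(event_times = NULL, rate_per_min = 1, burst_freq = 15,
               burst_dur = 0.300, burst_amp = 0.8, noise_sd = 0.1,
               fs_accel = 1000),
    seed = 1L
  )
  if (preset == "5HT2A") {
    cfg$hfo$carrier_freq <- 127
    cfg$drug <- "LSD"; cfg$drug_class <- "5HT2A"
  } else if (preset == "NMDA") {
    cfg$hfo$carrier_freq <- 143
    cfg$drug <- "ketamine"; cfg$drug_class <- "NMDA"
    cfg$rate_modulation <- c(PC = 0.6, IN = 1.6, X = 1)
    cfg$htr$rate_per_min <- 0
  } else if (preset == "amphetamine") {
    cfg$hfo$amplitude <- 0
    cfg$gamma$rms <- 8
    cfg$drug <- "amphetamine"; cfg$drug_class <- "amphetamine"
    cfg$htr$rate_per_min <- 0
  } else {
    cfg$hfo$baseline_frac <- 0.05
    cfg$hfo$amplitude <- 0
    cfg$drug <- "none"; cfg$drug_class <- "baseline-only"
    cfg$injection_time <- NA_real_
    cfg$htr$rate_per_min <- 0
  }
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  stopifnot(cfg$hfo$rho >= 0, cfg$hfo$rho <= 1,
            cfg$hfo$amplitude >= 0, cfg$fractal$beta >= 0)
  class(cfg) <- "synth_config"
  cfg
}

# centered linear convolution via FFT, same length as x
.fftconv <- function(x, kernel) {
  n <- length(x); m <- length(kernel)
  L <- stats::nextn(n + m - 1, 2)
  X <- stats::fft(c(x, numeric(L - n)))
  K <- stats::fft(c(kernel, numeric(L - m)))
  y <- Re(stats::fft(X * K, inverse = TRUE)) / L
  shift <- (m - 1) %/% 2
  y[(1 + shift):(n + shift)]
}

#' Generate 1/f^beta fractal noise
#'
#' Spectral shaping of Gaussian white noise in the frequency domain, giving
#' exact slope control: the one-sided PSD is `scale * f^-beta` uV^2/Hz (within
#' estimation error) over the analysis band. Power below 0.1 Hz is flattened
#' to keep the variance finite.
#'
#' @param beta spectral slope in \[0, 3\].
#' @param scale PSD at 1 Hz, uV^2/Hz.
#' @param fs sampling rate, Hz.
#' @param duration length, seconds; `fs * duration` must be at least 4096.
#' @param seed optional RNG seed for reproducibility.
#' @return numeric vector of `fs * duration` samples.
#' @export
gen_fractal_noise <- function(beta, scale, fs, duration, seed = NULL) {
  stopifnot(beta >= 0, beta <= 3, scale >= 0)
  n <- round(fs * duration)
  if (n < 4096)
    stop("gen_fractal_noise: need at least 4096 samples for spectral shaping")
  if (!is.null(seed)) set.seed(seed)
  w <- stats::rnorm(n)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) * fs / n
  g <- sqrt(scale * fs / 2) * pmax(f, 0.1)^(-beta / 2)
  g[1] <- 0
  x <- Re(stats::fft(stats::fft(w) * g, inverse = TRUE)) / n
  x
}

# Spindle envelope: Gaussian bumps at Poisson onsets. `fwhm` is the spindle
# length in its operational sense -- the FWHM of the envelope's normalized
# autocorrelation -- so the bump SD is fwhm / (2.355 * sqrt(2)) (the
# autocorrelation of a Gaussian of SD s is a Gaussian of SD s*sqrt(2)).
# onset_keep_prob: function(times)->prob, used for epoch gating.
.gen_envelope <- function(rate, fwhm, amp, fs, duration,
                          onset_keep_prob = NULL) {
  n <- round(fs * duration)
  n_on <- stats::rpois(1, rate * duration)
  t_on <- sort(stats::runif(n_on, 0, duration))
  if (!is.null(onset_keep_prob) && length(t_on)) {
    keep <- stats::runif(length(t_on)) < onset_keep_prob(t_on)
    t_on <- t_on[keep]
  }
  env <- numeric(n)
  if (length(t_on)) {
    idx <- pmin(pmax(round(t_on * fs) + 1, 1), n)
    imp <- numeric(n)
    amps <- stats::runif(length(idx), 0.5, 1.5) * amp
    for (k in seq_along(idx)) imp[idx[k]] <- imp[idx[k]] + amps[k]
    sigma <- fwhm / (2 * sqrt(2 * log(2))) / sqrt(2)
    hw <- max(1L, round(4 * sigma * fs))
    kern <- exp(-((-hw:hw) / fs)^2 / (2 * sigma^2))
    env <- .fftconv(imp, kern)
    env[env < 0] <- 0
  }
  env
}

#' Generate a multichannel spindle-modulated HFO component
#'
#' Each channel is `envelope(t) * cos(theta(t) + lag_ch)`, where the carrier
#' phase `theta` is shared across channels and its instantaneous frequency
#' wanders around `carrier_freq` as an Ornstein--Uhlenbeck process (SD
#' `carrier_sd`, correlation time `carrier_tau`), reproducing cross-structure
#' frequency co-modulation by construction. The envelope is a train of
#' Gaussian bumps with Poisson onsets at `spindle_rate`; `envelope_fwhm` is
#' the spindle length in its operational sense -- the FWHM of the envelope
#' autocorrelation -- so the bump itself is narrower by sqrt(2).
#' Channels in the same group share the envelope exactly; envelopes of
#' different groups are mixed with a shared component so their correlation is
#' `rho`. Channels listed in `inverted_channels` get an extra pi phase lag.
#'
#' @param hfo list as in [synth_config()]`$hfo`, plus optional `phase_lag`
#'   (numeric vector, one lag per channel, radians).
#' @param n_channels number of channels.
#' @param fs sampling rate, Hz.
#' @param duration seconds.
#' @param seed optional RNG seed.
#' @param groups integer vector (length `n_channels`): envelope-sharing
#'   groups; default all channels share one envelope.
#' @param onset_keep_prob optional function(times)->prob for gating spindle
#'   onsets (used to make baseline HFOs sporadic).
#' @return list with `signal` (n_channels x samples), and `truth`: carrier
#'   phase `theta` (radians, unwrapped), per-channel `lags` (inversion
#'   included), `envelopes` (n_channels x samples), `trough_phase`
#'   (n_channels x samples not stored; derive as `wrap_angle(theta + lag + pi)`).
#' @export
gen_hfo_component <- function(hfo, n_channels, fs, duration, seed = NULL,
                              groups = rep(1L, n_channels),
                              onset_keep_prob = NULL) {
  if (hfo$carrier_freq >= fs / 2)
    stop("gen_hfo_component: carrier frequency must be below Nyquist")
  if (!is.null(seed)) set.seed(seed)
  n <- round(fs * duration)
  # OU frequency wander, shared across channels
  tau <- if (is.null(hfo$carrier_tau)) 2 else hfo$carrier_tau
  a <- exp(-1 / (fs * tau))
  innov <- stats::rnorm(n, sd = hfo$carrier_sd * sqrt(1 - a^2))
  drift <- stats::filter(innov, a, method = "recursive")
  f_inst <- hfo$carrier_freq + as.numeric(drift)
  theta <- 2 * pi * cumsum(f_inst) / fs

  lags <- hfo$phase_lag
  if (is.null(lags)) lags <- numeric(n_channels)
  stopifnot(length(lags) == n_channels)
  lags[seq_len(n_channels) %in% hfo$inverted_channels] <-
    lags[seq_len(n_channels) %in% hfo$inverted_channels] + pi

  ug <- unique(groups)
  rho <- if (is.null(hfo$rho)) 1 else hfo$rho
  shared <- .gen_envelope(hfo$spindle_rate, hfo$envelope_fwhm, hfo$amplitude,
                          fs, duration, onset_keep_prob)
  env_by_group <- list()
  for (g in ug) {
    env_by_group[[as.character(g)]] <-
      if (length(ug) == 1L || rho >= 1) {
        shared
      } else {
        priv <- .gen_envelope(hfo$spindle_rate, hfo$envelope_fwhm,
                              hfo$amplitude, fs, duration, onset_keep_prob)
        sqrt(rho) * shared + sqrt(1 - rho) * priv
      }
  }
  # per-electrode coupling gain: electrodes sample the local dipole at
  # distinct depths, so same-structure channels see systematically different
  # amplitudes and the bipolar derivative retains the local HFO. Gains are
  # spread evenly across the range within each envelope-sharing group, which
  # guarantees a non-degenerate bipolar contrast.
  gr_rng <- hfo$channel_gain_range
  gains <- rep(1, n_channels)
  if (!is.null(gr_rng)) {
    for (g in ug) {
      idx <- which(groups == g)
      if (length(idx) > 1)
        gains[idx] <- seq(gr_rng[1], gr_rng[2], length.out = length(idx))
    }
  }
  sig <- matrix(0, n_channels, n)
  envs <- matrix(0, n_channels, n)
  for (ch in seq_len(n_channels)) {
    e <- gains[ch] * env_by_group[[as.character(groups[ch])]]
    envs[ch, ] <- e
    sig[ch, ] <- e * cos(theta + lags[ch])
  }
  list(signal = sig,
       truth = list(theta = theta, lags = wrap_angle(lags), envelopes = envs,
                    gains = gains))
}

# band-limited Gaussian noise with given RMS, by spectral masking
.gen_gamma <- function(band, rms, fs, duration) {
  n <- round(fs * duration)
  w <- stats::rnorm(n)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) * fs / n
  mask <- as.numeric(f >= band[1] & f <= band[2])
  x <- Re(stats::fft(stats::fft(w) * mask, inverse = TRUE)) / n
  if (stats::sd(x) > 0) x <- x * rms / stats::sd(x)
  x
}

# extracellular waveform template (negative-first): valley then peak.
# Returns the mean waveform in uV on the wf_fs grid (3 ms span).
.gen_waveform <- function(cell_type, wf_fs, jitter = 0.05) {
  t <- seq(0, 0.003, by = 1 / wf_fs)            # seconds
  j <- function(x) x * (1 + stats::rnorm(1, 0, jitter))
  if (cell_type == "IN") {
    tv <- j(0.0010); sv <- j(0.000064); tp <- tv + j(0.00030); sp <- j(0.00017)
    A <- j(80); B <- j(30)
  } else {                                      # PC: broad spiking
    tv <- j(0.0010); sv <- j(0.00013); tp <- tv + j(0.00060); sp <- j(0.00035)
    A <- j(90); B <- j(40)
  }
  -A * exp(-((t - tv) / sv)^2 / 2) + B * exp(-((t - tp) / sp)^2 / 2)
}

# inhomogeneous Poisson spikes by thinning, with a 1 ms dead time.
# rate_fun indexes a per-sample rate vector (Hz).
.gen_spikes <- function(rate_t, fs, duration) {
  lam_max <- max(rate_t)
  if (lam_max <= 0) return(numeric(0))
  n_cand <- stats::rpois(1, lam_max * duration * 1.05)
  tc <- sort(stats::runif(n_cand, 0, duration))
  idx <- pmin(pmax(round(tc * fs) + 1, 1), length(rate_t))
  acc <- stats::runif(length(tc)) < rate_t[idx] / lam_max
  st <- tc[acc]
  if (length(st) > 1L) {
    keep <- c(TRUE, diff(st) > 0.001)
    st <- st[keep]
  }
  st
}

#' Generate a synthetic session with ground truth
#'
#' Composes per-channel LFP as fractal background + gamma + spindle-modulated
#' HFO (HFO spindles sporadic before the injection, persistent after), spike
#' trains thinned from a Poisson process with a von Mises phase gain against
#' the channel's true HFO trough phase (gated by the HFO envelope, so
#' entrained firing happens when the oscillation is present), and a 3-axis
#' accelerometer trace with 8-32 Hz twitch bursts on the mediolateral axis.
#'
#' @param config a [synth_config()].
#' @return list with `session` (an [session()] object) and `truth`: carrier
#'   phase, per-channel lags/envelopes, per-unit true `(mu, kappa)` and
#'   entrainment flag, per-class rate factors, twitch times.
#' @export
gen_session <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  fs <- cfg$fs; dur <- cfg$duration; n <- round(fs * dur)
  inj <- cfg$injection_time
  structs <- names(cfg$structures)
  n_ch <- sum(cfg$structures)
  ch_struct <- rep(structs, times = cfg$structures)
  channels <- data.frame(
    channel_id = seq_len(n_ch),
    structure = ch_struct,
    hemisphere = rep_len(c("left", "right"), n_ch),
    electrode_group = as.integer(factor(ch_struct, levels = structs)),
    ap = 0, ml = 0, dv = 0
  )

  # ---- LFP ----
  lfp <- matrix(0, n_ch, n)
  for (ch in seq_len(n_ch)) {
    lfp[ch, ] <- gen_fractal_noise(cfg$fractal$beta, cfg$fractal$scale, fs, dur) +
      .gen_gamma(cfg$gamma$band, cfg$gamma$rms, fs, dur)
  }
  lags <- numeric(n_ch)
  if (!is.null(cfg$hfo$structure_lags)) {
    for (sname in names(cfg$hfo$structure_lags))
      lags[ch_struct == sname] <- cfg$hfo$structure_lags[[sname]]
  }
  gate <- if (is.na(inj)) {
    local({bf <- cfg$hfo$baseline_frac; function(tt) rep(bf, length(tt))})
  } else {
    local({bf <- cfg$hfo$baseline_frac; ij <- inj
           function(tt) ifelse(tt < ij, bf, 1)})
  }
  hfo_cfg <- cfg$hfo
  hfo_cfg$phase_lag <- lags
  hfo <- gen_hfo_component(hfo_cfg, n_ch, fs, dur,
                           groups = channels$electrode_group,
                           onset_keep_prob = gate)
  lfp <- lfp + hfo$signal

  # ---- spikes ----
  units <- list()
  unit_truth <- list()
  kmods <- cfg$rate_modulation
  uid <- 0L
  for (sname in structs) {
    ch_ids <- channels$channel_id[channels$structure == sname]
    for (k in seq_len(cfg$spikes$n_per_structure)) {
      uid <- uid + 1L
      ctype <- if (k %% 2L == 1L) "PC" else "IN"
      electrode <- ch_ids[(k - 1L) %% length(ch_ids) + 1L]
      entrained <- stats::runif(1) < cfg$spikes$frac_entrained
      kap <- if (entrained) cfg$spikes$kappa else 0
      mu <- cfg$spikes$preferred_phase
      # true trough-zero phase of the unit's structure
      phi <- wrap_angle(hfo$truth$theta + lags[electrode] + pi)
      gain <- if (kap > 0) {
        exp(kap * cos(phi - mu)) / besselI(kap, 0)
      } else rep(1, n)
      env <- hfo$truth$envelopes[electrode, ]
      me <- mean(env)
      egate <- if (me > 0) env / me else rep(1, n)
      mod_t <- rep(1, n)
      if (!is.na(inj)) {
        fac <- unname(kmods[ctype]); if (is.na(fac)) fac <- 1
        mod_t[seq_len(n) > inj * fs] <- fac
      }
      rate_t <- cfg$spikes$base_rate * mod_t *
        (if (kap > 0 && me > 0) egate * gain else rep(1, n))
      st <- .gen_spikes(rate_t, fs, dur)
      wf <- .gen_waveform(ctype, cfg$spikes$wf_fs)
      units[[uid]] <- spike_unit(sprintf("u%02d", uid), st, electrode,
                                 waveform = wf, wf_fs = cfg$spikes$wf_fs,
                                 cell_type = "unset")
      unit_truth[[uid]] <- list(unit_id = sprintf("u%02d", uid),
                                structure = sname, electrode = electrode,
                                cell_type = ctype, mu = mu, kappa = kap,
                                entrained = entrained,
                                rate_factor = if (is.na(inj)) 1
                                              else unname(kmods[ctype]))
    }
  }

  # ---- accelerometer ----
  fsa <- cfg$htr$fs_accel
  na <- round(fsa * dur)
  accel <- matrix(0, 3, na)
  for (ax in 1:3)
    accel[ax, ] <- {
      x <- gen_fractal_noise(1, 1, fsa, dur)
      x * cfg$htr$noise_sd / stats::sd(x)
    }
  tw <- cfg$htr$event_times
  if (is.null(tw)) {
    tw <- numeric(0)
    if (!is.na(inj) && cfg$htr$rate_per_min > 0) {
      n_ev <- round(cfg$htr$rate_per_min * (dur - inj) / 60)
      if (n_ev > 0) {
        cand <- sort(stats::runif(n_ev * 3, inj + 5, dur - 5))
        for (tt in cand) {
          if (!length(tw) || tt - tw[length(tw)] > 2) tw <- c(tw, tt)
          if (length(tw) >= n_ev) break
        }
      }
    }
  }
  if (length(tw)) {
    nb <- round(cfg$htr$burst_dur * fsa)
    win <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = nb)))   # Hanning
    tb <- seq_len(nb) / fsa
    burst <- cfg$htr$burst_amp * win * sin(2 * pi * cfg$htr$burst_freq * tb)
    for (tt in tw) {
      i0 <- round((tt - cfg$htr$burst_dur / 2) * fsa)
      ii <- i0 + seq_len(nb)
      ok <- ii >= 1 & ii <= na
      accel[2, ii[ok]] <- accel[2, ii[ok]] + burst[ok]
    }
  }

  sess <- session(lfp, fs, channels, units = units, accel = accel,
                  fs_accel = fsa, injection_time = inj,
                  drug = cfg$drug, drug_class = cfg$drug_class)
  truth <- list(theta = hfo$truth$theta, lags = hfo$truth$lags,
                envelopes = hfo$truth$envelopes, units = unit_truth,
                twitch_times = tw, config = cfg)
  list(session = sess, truth = truth)
}
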