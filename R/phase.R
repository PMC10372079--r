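# Instantaneous HFO phase/amplitude, amplitude co-modulation, pairwise phase
# differences, inversion classification, structure-level phase-lag maps.

#' Zero-phase narrowband filter
#'
#' 64th-order Hamming-windowed FIR bandpass at `f0 +/- halfwidth`, applied
#' forwards and backwards (`signal::filtfilt`) so the group delay is zero.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param f0 centre frequency, Hz.
#' @param halfwidth half bandwidth, Hz (default 5; note that at this filter
#'   order the transition band, not the design band, sets the effective
#'   bandwidth).
#' @param order FIR order.
#' @return filtered signal, same length.
#' @export
narrowband <- function(x, fs, f0, halfwidth = 5, order = 64) {
  lo <- f0 - halfwidth; hi <- f0 + halfwidth
  if (lo <= 0 || hi >= fs / 2)
    stop("narrowband: band outside (0, Nyquist)")
  b <- signal::fir1(order, c(lo, hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(b, x))
}

# analytic signal by FFT (Hilbert construction)
.analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase and amplitude of a narrowband signal
#'
#' Hilbert-transforms the filtered signal into its complex analytic form
#' `z(t)`; amplitude is `|z|` and phase is `arg z` shifted by pi so that the
#' oscillation *trough* maps to phase 0 (a cosine peak maps to pi).
#'
#' @param filtered narrowband signal (microvolts).
#' @param f0 nominal centre frequency, Hz (stored for reference).
#' @param fs sampling rate, Hz.
#' @return object of class `analytic_series`: `phase` (radians, (-pi, pi],
#'   trough = 0), `amplitude` (uV), `f0`, `fs`, `defined` (FALSE for an
#'   all-zero input).
#' @export
analytic <- function(filtered, f0 = NA_real_, fs = NA_real_) {
  z <- .analytic_signal(filtered)
  amp <- Mod(z)
  defined <- any(amp > 0)
  ph <- if (defined) wrap_angle(Arg(z) + pi) else rep(NA_real_, length(z))
  structure(list(phase = ph, amplitude = amp, f0 = f0, fs = fs,
                 defined = defined),
            class = "analytic_series")
}

# normalized autocorrelation of a (mean-subtracted) series up to max_lag
.acf_norm <- function(x, max_lag) {
  a <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  a
}

#' Amplitude autocorrelation and spindle-length estimate
#'
#' Normalised autocorrelation of the mean-subtracted instantaneous amplitude,
#' computed in 60-s windows and averaged; the full width at half maximum of
#' the central peak estimates the typical spindle length. Channels whose
#' median amplitude is below `min_median_uV` are flagged excluded.
#'
#' @param amp instantaneous amplitude series, uV.
#' @param fs sampling rate, Hz.
#' @param window_s window length, seconds.
#' @param min_median_uV inclusion threshold on the median amplitude.
#' @param max_lag_s maximum lag, seconds.
#' @return list: `lags` (s), `acf`, `peak_fwhm_ms` (NA when the half-max
#'   level is never crossed), `excluded`, `median_amplitude`.
#' @export
amplitude_autocorr <- function(amp, fs, window_s = 60, min_median_uV = 15,
                               max_lag_s = 0.5) {
  med <- stats::median(amp)
  if (med < min_median_uV) {
    return(list(lags = NULL, acf = NULL, peak_fwhm_ms = NA_real_,
                excluded = TRUE, median_amplitude = med))
  }
  nw <- round(window_s * fs)
  if (length(amp) < nw) stop("amplitude_autocorr: series shorter than one window")
  max_lag <- round(max_lag_s * fs)
  starts <- seq(1L, length(amp) - nw + 1L, by = nw)
  acfs <- vapply(starts, function(s0)
    .acf_norm(amp[s0:(s0 + nw - 1L)], max_lag), numeric(max_lag + 1L))
  a <- rowMeans(acfs)
  lags <- (0:max_lag) / fs
  # FWHM of the central peak: first downward crossing of 0.5, interpolated;
  # peak is symmetric, so FWHM = 2 * crossing lag
  below <- which(a < 0.5)
  fwhm <- NA_real_
  if (length(below)) {
    i <- below[1]
    if (i > 1) {
      x0 <- lags[i - 1] + (0.5 - a[i - 1]) * (lags[i] - lags[i - 1]) /
        (a[i] - a[i - 1])
      fwhm <- 2 * x0 * 1000
    }
  }
  list(lags = lags, acf = a, peak_fwhm_ms = fwhm, excluded = FALSE,
       median_amplitude = med)
}

#' Peak amplitude cross-correlation between two channels
#'
#' Normalised cross-correlation of the instantaneous amplitudes, computed in
#' 60-s windows, averaged, and summarised by its peak value within
#' `max_lag_s`. Pairs where either channel's median amplitude is below the
#' threshold are excluded.
#'
#' @param amp_i,amp_j amplitude series, uV (same length and rate).
#' @param fs sampling rate, Hz.
#' @param window_s window length, seconds.
#' @param min_median_uV inclusion threshold.
#' @param max_lag_s lag range for the peak search, seconds.
#' @return list: `peak` (correlation at the best lag), `lag_s`, `excluded`.
#' @export
amplitude_crosscorr <- function(amp_i, amp_j, fs, window_s = 60,
                                min_median_uV = 15, max_lag_s = 0.5) {
  stopifnot(length(amp_i) == length(amp_j))
  if (stats::median(amp_i) < min_median_uV ||
      stats::median(amp_j) < min_median_uV) {
    return(list(peak = NA_real_, lag_s = NA_real_, excluded = TRUE))
  }
  nw <- round(window_s * fs)
  if (length(amp_i) < nw) stop("amplitude_crosscorr: series shorter than one window")
  max_lag <- round(max_lag_s * fs)
  starts <- seq(1L, length(amp_i) - nw + 1L, by = nw)
  ccs <- vapply(starts, function(s0) {
    sel <- s0:(s0 + nw - 1L)
    stats::ccf(amp_i[sel], amp_j[sel], lag.max = max_lag, plot = FALSE,
               demean = TRUE)$acf[, 1, 1]
  }, numeric(2L * max_lag + 1L))
  cc <- rowMeans(ccs)
  i <- which.max(cc)
  list(peak = cc[i], lag_s = (i - 1L - max_lag) / fs, excluded = FALSE)
}

#' Pairwise phase-difference statistics and inversion call
#'
#' Circular summary of the sample-wise phase difference `phi_i - phi_j`,
#' optionally gated to samples where both amplitudes exceed their own median
#' (suppresses noise-phase samples; `gate = FALSE` uses the whole period).
#' The pair is called phase inverted when `|dphi| > 3*pi/4` and `kappa > 1`.
#'
#' @param phi_i,phi_j phase series, radians (simultaneous samples).
#' @param amp_i,amp_j optional amplitude series for gating.
#' @param fs sampling rate, Hz (used to flag pairs with under 1 s of gated
#'   samples as unstable).
#' @param gate logical; apply the amplitude gate?
#' @return object of class `phase_pair_stats`: `dphi`, `r`, `kappa`,
#'   `inverted`, `n_samples`, `unstable`.
#' @export
phase_pair <- function(phi_i, phi_j, amp_i = NULL, amp_j = NULL,
                       fs = NA_real_, gate = TRUE) {
  stopifnot(length(phi_i) == length(phi_j))
  keep <- rep(TRUE, length(phi_i))
  if (gate && !is.null(amp_i) && !is.null(amp_j)) {
    keep <- amp_i > stats::median(amp_i) & amp_j > stats::median(amp_j)
  }
  d <- wrap_angle(phi_i[keep] - phi_j[keep])
  s <- circ_summary(d)
  inverted <- isTRUE(abs(s$mu) > 3 * pi / 4 && s$kappa > 1)
  unstable <- is.finite(fs) && s$n < fs
  structure(list(dphi = s$mu, r = s$r, kappa = s$kappa, inverted = inverted,
                 n_samples = s$n, unstable = unstable),
            class = "phase_pair_stats")
}

#' Per-channel analytic HFO series for a session
#'
#' Filters every monopolar channel at `f0 +/- halfwidth` and Hilbert
#' transforms it, optionally restricted to an epoch.
#'
#' @param s an [session()] object.
#' @param f0 narrowband centre, Hz (e.g. [median_hfo_frequency()]).
#' @param ep optional [epoch()] (uses the session's injection time).
#' @param halfwidth half bandwidth, Hz.
#' @return named list (by channel id) of `analytic_series`.
#' @export
session_analytic <- function(s, f0, ep = NULL, halfwidth = 5) {
  out <- list()
  for (k in seq_len(nrow(s$channels))) {
    x <- s$lfp[k, ]
    if (!is.null(ep)) x <- slice_epoch(x, s$injection_time, ep, fs = s$fs_lfp)
    out[[as.character(s$channels$channel_id[k])]] <-
      analytic(narrowband(x, s$fs_lfp, f0, halfwidth), f0 = f0, fs = s$fs_lfp)
  }
  out
}

#' Phase-difference table for all channel pairs
#'
#' @param ana named list from [session_analytic()].
#' @param channels session channel table.
#' @param gate logical; amplitude gating as in [phase_pair()].
#' @return data.frame, one row per unordered channel pair: ids, structures,
#'   `dphi`, `r`, `kappa`, `inverted`, `n_samples`.
#' @export
phase_pair_table <- function(ana, channels, gate = TRUE) {
  ids <- channels$channel_id
  prs <- utils::combn(seq_along(ids), 2)
  rows <- lapply(seq_len(ncol(prs)), function(k) {
    i <- prs[1, k]; j <- prs[2, k]
    ai <- ana[[as.character(ids[i])]]; aj <- ana[[as.character(ids[j])]]
    ps <- phase_pair(ai$phase, aj$phase, ai$amplitude, aj$amplitude,
                     fs = ai$fs, gate = gate)
    data.frame(channel_i = ids[i], channel_j = ids[j],
               structure_i = channels$structure[i],
               structure_j = channels$structure[j],
               dphi = ps$dphi, r = ps$r, kappa = ps$kappa,
               inverted = ps$inverted, n_samples = ps$n_samples)
  })
  do.call(rbind, rows)
}

#' Structure-level phase-lag map relative to a reference structure
#'
#' For every structure, takes all channel pairs linking it to the reference
#' structure (dropping pairs with resultant length below `r_min`, which marks
#' unstable phase estimates), orients the lag so that positive means the
#' structure *leads* the reference, and reports the median lag with a
#' Wilcoxon signed-rank p-value against zero median.
#'
#' @param pairs data.frame from [phase_pair_table()].
#' @param reference_structure label of the reference (e.g. "OB").
#' @param r_min minimum resultant length for inclusion.
#' @return list: `map` (data.frame structure, median_lag, n_pairs, p_wilcox)
#'   and `pairs` (the retained oriented pair table). Structures with no
#'   retained pairs are omitted with a warning.
#' @export
structure_phase_map <- function(pairs, reference_structure, r_min = 0.5) {
  sel <- (pairs$structure_i == reference_structure) !=
         (pairs$structure_j == reference_structure)   # exactly one end is ref
  tab <- pairs[sel & pairs$r >= r_min, , drop = FALSE]
  # orient: dphi = phi_struct - phi_ref  (positive = structure leads)
  flip <- tab$structure_i == reference_structure
  tab$lag <- ifelse(flip, -tab$dphi, tab$dphi)
  tab$lag <- wrap_angle(tab$lag)
  tab$structure <- ifelse(flip, tab$structure_j, tab$structure_i)
  all_structs <- setdiff(unique(c(pairs$structure_i, pairs$structure_j)),
                         reference_structure)
  rows <- list()
  for (st in all_structs) {
    lg <- tab$lag[tab$structure == st]
    if (!length(lg)) {
      warning(sprintf("structure_phase_map: no retained pairs for %s", st))
      next
    }
    p <- if (length(lg) >= 2 && stats::sd(lg) > 0)
      stats::wilcox.test(lg, mu = 0, exact = FALSE)$p.value else NA_real_
    rows[[st]] <- data.frame(structure = st, median_lag = stats::median(lg),
                             n_pairs = length(lg), p_wilcox = p)
  }
  list(map = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       pairs = tab)
}
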