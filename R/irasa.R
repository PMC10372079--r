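# Fractal/oscillatory spectral separation by irregular resampling (IRASA) and
# the fractal-normalised rhythmicity spectrum S_dB = 10*log10(S / S_fractal).

# one-sided PSD of a mean-detrended, Hanning-tapered segment.
# sum(S) * df ~= var(x) (Parseval, within taper loss correction U).
.periodogram <- function(x, fs) {
  n <- length(x)
  x <- x - mean(x)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  U <- mean(w^2)
  X <- stats::fft(x * w)
  kmax <- floor(n / 2)
  S <- 2 * Mod(X[2:(kmax + 1)])^2 / (fs * n * U)
  list(freqs = (1:kmax) * fs / n, S = S)
}

# resample by factor h (> 0): returns x evaluated on a grid with spacing
# h/fs (h > 1 compresses, i.e. plays the signal faster). Exact band-limited
# (sinc) resampling in the frequency domain: spectrum truncation is an ideal
# anti-alias filter, zero-padding an ideal interpolator. X = fft(x) may be
# passed precomputed.
.resample_by <- function(x, h, X = NULL) {
  n <- length(x)
  if (is.null(X)) X <- stats::fft(x)
  m <- max(16L, round(n / h))
  K <- min((m - 1L) %/% 2L, (n - 1L) %/% 2L)
  Y <- complex(m)
  Y[1] <- X[1]
  Y[2:(K + 1)] <- X[2:(K + 1)]
  Y[m - (1:K) + 1] <- X[n - (1:K) + 1]
  Re(stats::fft(Y, inverse = TRUE)) / n
}

# centered running mean with edge replication (bins odd)
.smooth_run_mean <- function(s, bins) {
  if (bins <= 1L) return(s)
  n <- length(s)
  pad <- bins %/% 2L
  sp <- c(rep(s[1], pad), s, rep(s[n], pad))
  as.numeric(stats::filter(sp, rep(1 / bins, bins), sides = 2))[(pad + 1L):(pad + n)]
}

#' IRASA spectral decomposition of a signal
#'
#' Splits the signal into 50%-overlapping windows (8 s by default) and, per
#' window, estimates the total PSD `S` with a Hanning-tapered periodogram and
#' the arrhythmic fractal component `S_fractal` as the median over the
#' resampling factors `hset` of the geometric mean of the PSDs of the
#' h-resampled and 1/h-resampled signal. Rhythmic excess is expressed as
#' `S_dB = 10*log10(S / S_fractal)` ("dB_fractal"): 0 dB means no rhythm
#' above the fractal background.
#'
#' @param x numeric signal (microvolts); an optional `t0` attribute gives the
#'   absolute time of the first sample (seconds), default 0.
#' @param fs sampling rate, Hz.
#' @param window_s window length, seconds (8 s gives a 0.125 Hz grid).
#' @param overlap fractional window overlap (0.5 = 50%).
#' @param hset resampling factors; default `seq(1.1, 1.9, by = 0.05)`.
#' @param f_range analysis band, Hz; upper bound is additionally capped at
#'   `fs / (2 * max(hset))` so all resampled spectra are defined.
#' @param smooth_bw bandwidth (Hz) of the running-mean smoother applied to
#'   the resampled PSDs before the geometric mean. The fractal component is
#'   smooth by construction, and smoothing removes the small-sample downward
#'   bias of the square root of noisy periodogram products; set 0 to
#'   disable.
#' @return list of `spectral_frame` objects, each with `freqs`, `S`,
#'   `S_fractal`, `S_dB` and the window centre time `t_center` (seconds).
#' @export
irasa <- function(x, fs, window_s = 8, overlap = 0.5,
                  hset = seq(1.1, 1.9, by = 0.05), f_range = c(1, 250),
                  smooth_bw = 1) {
  n_win <- round(window_s * fs)
  if (length(x) < n_win)
    stop("irasa: signal shorter than one window")
  t0 <- attr(x, "t0"); if (is.null(t0)) t0 <- 0
  step <- max(1L, round(n_win * (1 - overlap)))
  starts <- seq(1L, length(x) - n_win + 1L, by = step)
  f_hi <- min(f_range[2], fs / (2 * max(hset)))
  frames <- vector("list", length(starts))
  for (w in seq_along(starts)) {
    seg <- x[starts[w]:(starts[w] + n_win - 1L)]
    seg <- seg - mean(seg)
    X <- stats::fft(seg)
    pg <- .periodogram(seg, fs)
    keep <- pg$freqs >= f_range[1] & pg$freqs <= f_hi
    freqs <- pg$freqs[keep]
    S <- pg$S[keep]
    Sh <- matrix(NA_real_, length(hset), length(freqs))
    for (i in seq_along(hset)) {
      h <- hset[i]
      p_up <- .periodogram(.resample_by(seg, 1 / h, X), fs)
      p_dn <- .periodogram(.resample_by(seg, h, X), fs)
      su <- stats::approx(p_up$freqs, p_up$S, xout = freqs, rule = 2)$y
      sd_ <- stats::approx(p_dn$freqs, p_dn$S, xout = freqs, rule = 2)$y
      if (smooth_bw > 0) {
        bins <- max(1L, round(smooth_bw * window_s))
        if (bins %% 2L == 0L) bins <- bins + 1L
        su <- .smooth_run_mean(su, bins)
        sd_ <- .smooth_run_mean(sd_, bins)
      }
      Sh[i, ] <- sqrt(pmax(su, 1e-20) * pmax(sd_, 1e-20))
    }
    S_fractal <- apply(Sh, 2, stats::median)
    S_fractal <- pmax(S_fractal, 1e-20)
    frames[[w]] <- structure(
      list(freqs = freqs, S = S, S_fractal = S_fractal,
           S_dB = 10 * log10(pmax(S, 1e-20) / S_fractal),
           t_center = t0 + (starts[w] - 1 + n_win / 2) / fs),
      class = "spectral_frame")
  }
  frames
}

#' Average spectral frames (optionally within an epoch)
#'
#' Averages `S` and `S_fractal` in the linear power domain across the
#' selected windows and recomputes `S_dB` from the means. Epoch membership is
#' decided by each window's centre time.
#'
#' @param frames list of `spectral_frame` objects from [irasa()].
#' @param ep optional [epoch()]; requires `injection_time`.
#' @param injection_time injection time, seconds from recording start.
#' @return a single `spectral_frame`.
#' @export
average_spectrum <- function(frames, ep = NULL, injection_time = NULL) {
  if (!is.null(ep)) {
    stopifnot(!is.null(injection_time), !is.na(injection_time))
    tc <- vapply(frames, function(f) f$t_center, numeric(1))
    frames <- frames[tc >= injection_time + ep$start &
                     tc < injection_time + ep$end]
  }
  if (!length(frames)) stop("average_spectrum: no frames in epoch")
  S <- rowMeans(vapply(frames, function(f) f$S, frames[[1]]$S))
  Sf <- rowMeans(vapply(frames, function(f) f$S_fractal, frames[[1]]$S_fractal))
  structure(
    list(freqs = frames[[1]]$freqs, S = S, S_fractal = pmax(Sf, 1e-20),
         S_dB = 10 * log10(pmax(S, 1e-20) / pmax(Sf, 1e-20)),
         t_center = mean(vapply(frames, function(f) f$t_center, numeric(1)))),
    class = "spectral_frame")
}
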