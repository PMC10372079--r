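# Bivariate spectral Granger causality between bipolar LFPs: short-window
# VAR fitting (windows pooled as trials), Geweke's frequency-domain measure,
# peak analysis and band summaries.

# remove a linear trend
.detrend <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  stats::lm.fit(cbind(1, t), x)$residuals
}

#' Fit a bivariate VAR on short windows pooled as trials
#'
#' Splits the pair of signals into non-overlapping windows (500 ms by
#' default), detrends each window linearly, and fits one VAR(order) by least
#' squares pooling all windows as trials -- regressors never cross a window
#' boundary. The residual covariance is estimated from the pooled residuals.
#'
#' @param x,y numeric signals (same length).
#' @param fs sampling rate, Hz.
#' @param window_s window length, seconds.
#' @param order VAR model order.
#' @return object of class `var_fit`: `A` (2 x 2 x order lag matrices,
#'   `A[i, j, k]` = effect of series j at lag k on series i; series 1 = x),
#'   `Sigma` (2 x 2 residual covariance), `fs`, `order`, `n_windows`.
#' @export
fit_var_windows <- function(x, y, fs, window_s = 0.5, order = 5) {
  stopifnot(length(x) == length(y))
  nw <- round(window_s * fs)
  n_win <- floor(length(x) / nw)
  if (n_win < 20) stop("fit_var_windows: need at least 20 windows")
  rows_per_win <- nw - order
  N <- n_win * rows_per_win
  X <- matrix(0, N, 2 * order)
  Y <- matrix(0, N, 2)
  r0 <- 0L
  for (w in seq_len(n_win)) {
    sel <- ((w - 1) * nw + 1):(w * nw)
    xa <- .detrend(x[sel]); ya <- .detrend(y[sel])
    tt <- (order + 1):nw
    Y[r0 + seq_len(rows_per_win), ] <- cbind(xa[tt], ya[tt])
    for (k in seq_len(order)) {
      X[r0 + seq_len(rows_per_win), 2 * k - 1] <- xa[tt - k]
      X[r0 + seq_len(rows_per_win), 2 * k]     <- ya[tt - k]
    }
    r0 <- r0 + rows_per_win
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("fit_var_windows: ill-conditioned regression (rank-deficient); consider downsampling")
  B <- qr.coef(qrX, Y)              # (2*order) x 2
  res <- Y - X %*% B
  Sigma <- crossprod(res) / (N - 2 * order)
  if (!is.finite(det(Sigma)) || det(Sigma) <= 1e-300)
    stop("fit_var_windows: singular residual covariance (degenerate input)")
  A <- array(0, c(2, 2, order))
  for (k in seq_len(order)) {
    # Y[, i] ~ sum_j B[2(k-1)+j, i] * lag_k of series j
    A[1, 1, k] <- B[2 * k - 1, 1]; A[1, 2, k] <- B[2 * k, 1]
    A[2, 1, k] <- B[2 * k - 1, 2]; A[2, 2, k] <- B[2 * k, 2]
  }
  structure(list(A = A, Sigma = Sigma, fs = fs, order = order,
                 n_windows = n_win),
            class = "var_fit")
}

#' Check VAR stability (spectral radius of the companion matrix)
#' @param var_fit a `var_fit`.
#' @return spectral radius (< 1 means stable).
#' @export
var_spectral_radius <- function(var_fit) {
  p <- var_fit$order
  comp <- matrix(0, 2 * p, 2 * p)
  for (k in seq_len(p)) comp[1:2, (2 * k - 1):(2 * k)] <- var_fit$A[, , k]
  if (p > 1) comp[3:(2 * p), 1:(2 * (p - 1))] <- diag(2 * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Geweke spectral Granger causality from a fitted VAR
#'
#' Computes the bivariate frequency-domain measure in both directions from
#' the VAR transfer function `H(f) = (I - sum_k A_k e^(-2 pi i f k / fs))^-1`
#' and residual covariance `Sigma`:
#' `f_{x->y}(f) = ln(S_yy / (S_yy - (Sigma_xx - Sigma_xy^2 / Sigma_yy)
#' |H_yx|^2))`, with `S = H Sigma H*`.
#'
#' @param var_fit a `var_fit` (from [fit_var_windows()] or built from known
#'   coefficients).
#' @param freq_grid frequencies, Hz; default 1 Hz grid up to Nyquist.
#' @return object of class `gc_spectrum`: `freqs`, `gc_xy` (x driving y),
#'   `gc_yx`, `fs`, `order`.
#' @export
gc_spectrum <- function(var_fit, freq_grid = NULL) {
  if (var_spectral_radius(var_fit) >= 1)
    stop("gc_spectrum: unstable VAR (spectral radius >= 1)")
  fs <- var_fit$fs
  if (is.null(freq_grid)) freq_grid <- seq(1, floor(fs / 2) - 1, by = 1)
  S <- var_fit$Sigma
  p <- var_fit$order
  gxy <- gyx <- numeric(length(freq_grid))
  for (i in seq_along(freq_grid)) {
    f <- freq_grid[i]
    Af <- diag(2) + 0i
    for (k in seq_len(p))
      Af <- Af - var_fit$A[, , k] * exp(-2i * pi * f * k / fs)
    H <- solve(Af)
    Sp <- H %*% S %*% Conj(t(H))
    s11 <- Re(Sp[1, 1]); s22 <- Re(Sp[2, 2])
    num_xy <- S[1, 1] - S[1, 2]^2 / S[2, 2]
    num_yx <- S[2, 2] - S[1, 2]^2 / S[1, 1]
    gxy[i] <- log(s22 / max(s22 - num_xy * Mod(H[2, 1])^2, 1e-300))
    gyx[i] <- log(s11 / max(s11 - num_yx * Mod(H[1, 2])^2, 1e-300))
  }
  structure(list(freqs = freq_grid, gc_xy = pmax(gxy, 0),
                 gc_yx = pmax(gyx, 0), fs = fs, order = p),
            class = "gc_spectrum")
}

#' Simulate from a bivariate VAR
#'
#' @param A 2 x 2 x order array of lag matrices.
#' @param Sigma 2 x 2 innovation covariance.
#' @param n samples to return (after a 500-sample burn-in).
#' @param fs sampling rate (stored only).
#' @param seed optional RNG seed.
#' @return list with `x`, `y`.
#' @export
simulate_var <- function(A, Sigma, n, fs = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- dim(A)[3]
  burn <- 500
  ntot <- n + burn
  L <- chol(Sigma)
  E <- matrix(stats::rnorm(2 * ntot), ntot, 2) %*% L
  Z <- matrix(0, ntot, 2)
  for (t in (p + 1):ntot) {
    acc <- E[t, ]
    for (k in seq_len(p)) acc <- acc + as.numeric(A[, , k] %*% Z[t - k, ])
    Z[t, ] <- acc
  }
  list(x = Z[(burn + 1):ntot, 1], y = Z[(burn + 1):ntot, 2], fs = fs)
}

# indices of strict local maxima
.local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n], FALSE))
}

#' Highest Granger-causality peak of a spectrum
#'
#' Local maxima on the analytic spectrum grid; only the highest is analysed.
#'
#' @param gc a `gc_spectrum`.
#' @param direction "xy" or "yx".
#' @param range analysed frequency range, Hz.
#' @return list `freq`, `height` (NA when no local maximum in range).
#' @export
gc_peak <- function(gc, direction = c("xy", "yx"), range = c(10, 250)) {
  direction <- match.arg(direction)
  v <- if (direction == "xy") gc$gc_xy else gc$gc_yx
  keep <- gc$freqs >= range[1] & gc$freqs <= range[2]
  f <- gc$freqs[keep]; v <- v[keep]
  im <- .local_maxima(v)
  if (!length(im)) return(list(freq = NA_real_, height = NA_real_))
  i <- im[which.max(v[im])]
  list(freq = f[i], height = v[i])
}

#' Band summaries of Granger causality across structure pairs
#'
#' For each pair spectrum and direction: the highest peak (retained when its
#' height reaches `peak_min`), the mean causality in the HFO band
#' (`hfo_freq +/- 10` Hz) and in the gamma band (25-75 Hz). Aggregates the
#' median peak height per directed structure pair; directed pairs with no
#' qualifying peak are marked missing.
#'
#' @param gc_entries list of entries: `list(gc = <gc_spectrum>, structure_x,
#'   structure_y)`.
#' @param hfo_freq HFO centre frequency, Hz.
#' @param peak_min minimum qualifying peak height.
#' @param gamma_band gamma band, Hz.
#' @param range peak-analysis range, Hz.
#' @return list: `pairs` (per-entry, per-direction data.frame with peak and
#'   band means), `summary` (median peak height per directed structure pair,
#'   `NA` = missing), `peak_freqs` (vector of qualifying peak frequencies for
#'   histograms).
#' @export
band_summary <- function(gc_entries, hfo_freq, peak_min = 0.2,
                         gamma_band = c(25, 75), range = c(10, 250)) {
  rows <- list()
  for (e in gc_entries) {
    for (dir in c("xy", "yx")) {
      pk <- gc_peak(e$gc, dir, range)
      v <- if (dir == "xy") e$gc$gc_xy else e$gc$gc_yx
      hb <- e$gc$freqs >= hfo_freq - 10 & e$gc$freqs <= hfo_freq + 10
      gb <- e$gc$freqs >= gamma_band[1] & e$gc$freqs <= gamma_band[2]
      from <- if (dir == "xy") e$structure_x else e$structure_y
      to   <- if (dir == "xy") e$structure_y else e$structure_x
      rows[[length(rows) + 1L]] <- data.frame(
        from = from, to = to, peak_freq = pk$freq, peak_height = pk$height,
        qualifies = is.finite(pk$height) && pk$height >= peak_min,
        mean_gc_hfo = mean(v[hb]), mean_gc_gamma = mean(v[gb]))
    }
  }
  pairs <- do.call(rbind, rows)
  keys <- unique(pairs[, c("from", "to")])
  summ <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- pairs[pairs$from == keys$from[i] & pairs$to == keys$to[i] &
                 pairs$qualifies, , drop = FALSE]
    data.frame(from = keys$from[i], to = keys$to[i],
               median_peak = if (nrow(sub)) stats::median(sub$peak_height)
                             else NA_real_,
               n_pairs = nrow(sub))
  })
  list(pairs = pairs, summary = do.call(rbind, summ),
       peak_freqs = pairs$peak_freq[pairs$qualifies])
}
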