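# Head-twitch response (HTR) detection from head-mounted accelerometer
# traces: 8-32 Hz zero-phase bandpass of the mediolateral axis, rectification,
# Gaussian smoothing, thresholded peak picking with a dead time.

#' HTR detector parameters
#'
#' @param target_fs working sampling rate, Hz.
#' @param passband FIR passband, Hz.
#' @param fir_order FIR filter order.
#' @param gauss_sigma Gaussian smoothing SD, seconds.
#' @param threshold detection threshold on the index, g.
#' @param dead_time minimum separation between events, seconds.
#' @return list of class `htr_params`.
#' @export
htr_params <- function(target_fs = 200, passband = c(8, 32), fir_order = 100,
                       gauss_sigma = 0.050, threshold = 0.4, dead_time = 1) {
  stopifnot(passband[1] > 0, passband[2] < target_fs / 2)
  structure(list(target_fs = target_fs, passband = passband,
                 fir_order = fir_order, gauss_sigma = gauss_sigma,
                 threshold = threshold, dead_time = dead_time),
            class = "htr_params")
}

#' Head-twitch index from the mediolateral acceleration
#'
#' Downsamples to 200 Hz (anti-aliased polyphase resampling), bandpass
#' filters 8-32 Hz with a zero-phase (forward-backward) FIR, rectifies, and
#' convolves with a unit-area Gaussian window (sigma = 50 ms, truncated at
#' +/-4 sigma). Unit-area normalisation keeps the index in g.
#'
#' @param accel_ml mediolateral acceleration, g.
#' @param fs sampling rate of `accel_ml`, Hz (>= 200).
#' @param params an [htr_params()].
#' @return numeric index series on the 200 Hz grid (attribute `fs`).
#' @export
htr_index <- function(accel_ml, fs, params = htr_params()) {
  stopifnot(fs >= params$target_fs)
  x <- accel_ml
  if (fs != params$target_fs) {
    fr <- .rational_factor(params$target_fs / fs)
    x <- as.numeric(signal::resample(x, fr$p, fr$q))
  }
  fsd <- params$target_fs
  if (length(x) <= 3 * params$fir_order)
    stop("htr_index: trace shorter than the filter transient")
  b <- signal::fir1(params$fir_order, params$passband / (fsd / 2), type = "pass")
  bp <- as.numeric(signal::filtfilt(b, x))
  hw <- max(1L, round(4 * params$gauss_sigma * fsd))
  kern <- exp(-((-hw:hw) / fsd)^2 / (2 * params$gauss_sigma^2))
  kern <- kern / sum(kern)
  idx <- .fftconv(abs(bp), kern)
  attr(idx, "fs") <- fsd
  idx
}

# rational approximation p/q of a factor, denominator capped
.rational_factor <- function(x, max_den = 1000) {
  best <- c(p = 1, q = 1); err <- Inf
  for (q in 1:max_den) {
    p <- round(x * q)
    if (p < 1) next
    e <- abs(p / q - x)
    if (e < err - 1e-15) { err <- e; best <- c(p = p, q = q) }
    if (err == 0) break
  }
  list(p = unname(best["p"]), q = unname(best["q"]))
}

#' Detect head-twitch events in an HTR index series
#'
#' Greedy peak picking: local maxima above the threshold are accepted in
#' descending height, each accepted event excluding further events within the
#' dead time (1 s), so twin twitches closer than the dead time merge into the
#' larger one.
#'
#' @param index series from [htr_index()] (attribute `fs` required).
#' @param params an [htr_params()].
#' @return data.frame of class `htr_events`: `time` (s), `index_value` (g),
#'   sorted by time.
#' @export
detect_htr <- function(index, params = htr_params()) {
  fs <- attr(index, "fs")
  stopifnot(!is.null(fs))
  n <- length(index)
  is_peak <- c(FALSE, index[2:(n - 1)] >= index[1:(n - 2)] &
                      index[2:(n - 1)] > index[3:n], FALSE)
  cand <- which(is_peak & index > params$threshold)
  cand <- cand[order(index[cand], decreasing = TRUE)]
  dead <- round(params$dead_time * fs)
  taken <- integer(0)
  for (i in cand) {
    if (!length(taken) || all(abs(taken - i) > dead)) taken <- c(taken, i)
  }
  taken <- sort(taken)
  out <- data.frame(time = (taken - 1) / fs, index_value = index[taken])
  class(out) <- c("htr_events", "data.frame")
  out
}

#' Evaluate detected events against ground-truth twitch times
#'
#' Greedy one-to-one matching: detections are matched in time order to the
#' closest unmatched truth event within the tolerance.
#'
#' @param event_times detected event times, seconds (sorted).
#' @param truth_times true twitch times, seconds (sorted).
#' @param tol matching tolerance, seconds.
#' @return list: `tpr` (matched / n truth), `fp_rate` (unmatched detections /
#'   n detections; NA with 0 detections), `n_matched`, `n_detected`,
#'   `n_truth`.
#' @export
evaluate_detector <- function(event_times, truth_times, tol = 0.2) {
  matched_truth <- rep(FALSE, length(truth_times))
  n_matched <- 0L
  for (t in event_times) {
    d <- abs(truth_times - t)
    d[matched_truth] <- Inf
    if (length(d) && min(d) <= tol) {
      matched_truth[which.min(d)] <- TRUE
      n_matched <- n_matched + 1L
    }
  }
  nd <- length(event_times)
  list(tpr = if (length(truth_times)) n_matched / length(truth_times) else NA_real_,
       fp_rate = if (nd) (nd - n_matched) / nd else NA_real_,
       n_matched = n_matched, n_detected = nd, n_truth = length(truth_times))
}
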