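# Firing-rate standardisation and modulation testing, waveform-based cell
# classification, spike-HFO entrainment, and population-modulation geometry.

# counts per bin_s-second bin over [t_lo, t_hi)
.bin_counts <- function(spike_times, t_lo, t_hi, bin_s) {
  edges <- seq(t_lo, t_hi, by = bin_s)
  if (length(edges) < 2L) return(numeric(0))
  st <- spike_times[spike_times >= t_lo & spike_times < edges[length(edges)]]
  tabulate(findInterval(st, edges), nbins = length(edges) - 1L)
}

#' Standardised firing rate (z-scored against baseline)
#'
#' Bins spike times in 10-s bins over both epochs and standardises every bin
#' by the baseline mean and SD:
#' `z_t = (rate_t - mean_baseline) / sd_baseline`.
#'
#' @param spike_times spike times, seconds from recording start.
#' @param injection_time injection time, seconds.
#' @param bin_s bin width, seconds.
#' @param baseline,drug [epoch()] definitions.
#' @return list: `z` (data.frame `t_center` (s, relative to injection),
#'   `epoch`, `count`, `z`), `mean_z_drug`, `excluded` (TRUE with a
#'   `reason` when the baseline SD is zero or the baseline has under 10
#'   bins).
#' @export
standardize_rates <- function(spike_times, injection_time, bin_s = 10,
                              baseline = epoch("baseline"),
                              drug = epoch("drug")) {
  cb <- .bin_counts(spike_times, injection_time + baseline$start,
                    injection_time + baseline$end, bin_s)
  cd <- .bin_counts(spike_times, injection_time + drug$start,
                    injection_time + drug$end, bin_s)
  if (length(cb) < 10L)
    return(list(z = NULL, mean_z_drug = NA_real_, excluded = TRUE,
                reason = "baseline epoch has fewer than 10 bins"))
  m <- mean(cb); s <- stats::sd(cb)
  if (s == 0)
    return(list(z = NULL, mean_z_drug = NA_real_, excluded = TRUE,
                reason = "zero baseline SD"))
  tb <- baseline$start + (seq_along(cb) - 0.5) * bin_s
  td <- drug$start + (seq_along(cd) - 0.5) * bin_s
  z <- data.frame(
    t_center = c(tb, td),
    epoch = rep(c("baseline", "drug"), c(length(cb), length(cd))),
    count = c(cb, cd),
    z = (c(cb, cd) - m) / s)
  list(z = z, mean_z_drug = mean(z$z[z$epoch == "drug"]), excluded = FALSE,
       reason = NULL)
}

#' Per-unit firing-rate modulation class
#'
#' Wilcoxon rank-sum test for equal medians on the 10-s spike counts of the
#' two epochs at alpha = 0.01: "up" when significant with a higher drug
#' median, "down" when lower, "none" otherwise.
#'
#' @inheritParams standardize_rates
#' @param alpha significance level.
#' @return list: `class` ("up"/"down"/"none"), `p`, `median_baseline`,
#'   `median_drug`.
#' @export
unit_modulation <- function(spike_times, injection_time, bin_s = 10,
                            baseline = epoch("baseline"),
                            drug = epoch("drug"), alpha = 0.01) {
  cb <- .bin_counts(spike_times, injection_time + baseline$start,
                    injection_time + baseline$end, bin_s)
  cd <- .bin_counts(spike_times, injection_time + drug$start,
                    injection_time + drug$end, bin_s)
  if (length(cb) < 10L || length(cd) < 10L)
    stop("unit_modulation: need at least 10 bins per epoch")
  p <- stats::wilcox.test(cd, cb, exact = FALSE)$p.value
  cls <- "none"
  if (is.finite(p) && p < alpha) {
    cls <- if (stats::median(cd) > stats::median(cb)) "up" else "down"
    if (stats::median(cd) == stats::median(cb))
      cls <- if (mean(cd) > mean(cb)) "up" else "down"
  }
  list(class = cls, p = p, median_baseline = stats::median(cb),
       median_drug = stats::median(cd))
}

#' Test whether the number of modulated units exceeds chance
#'
#' Binomial tail test: under the null every unit is flagged in one direction
#' with probability `alpha/2` (one tail of the two-sided unit test).
#'
#' @param n_modulated number of units flagged in the direction of interest.
#' @param n_total number of units tested.
#' @param alpha per-unit two-sided significance level.
#' @return upper-tail binomial p-value.
#' @export
population_modulation_test <- function(n_modulated, n_total, alpha = 0.01) {
  stats::pbinom(n_modulated - 1L, n_total, alpha / 2, lower.tail = FALSE)
}

#' Extracellular waveform features
#'
#' Valley width and peak width as full width at half maximum (linear
#' interpolation at the half-extremum crossings) and the peak-to-valley time,
#' for negative-first waveforms (dominant valley followed by a positive
#' peak).
#'
#' @param waveform mean waveform, uV.
#' @param wf_fs waveform sampling rate, Hz.
#' @return list of class `waveform_features`: `valley_width`, `peak_width`,
#'   `peak_to_valley` (all ms), `reliable` (FALSE for monophasic waveforms).
#' @export
waveform_features <- function(waveform, wf_fs) {
  t_ms <- (seq_along(waveform) - 1) / wf_fs * 1000
  iv <- which.min(waveform)
  vdep <- waveform[iv]
  after <- waveform[iv:length(waveform)]
  if (vdep >= 0 || max(after) <= 0) {
    return(structure(list(valley_width = NA_real_, peak_width = NA_real_,
                          peak_to_valley = NA_real_, reliable = FALSE),
                     class = "waveform_features"))
  }
  ip <- iv - 1L + which.max(after)
  fwhm_at <- function(idx, half) {
    # crossings of `half` on both sides of the extremum at idx
    cross <- function(i1, i2) {
      # linear interpolation between samples i1 and i2
      t_ms[i1] + (half - waveform[i1]) * (t_ms[i2] - t_ms[i1]) /
        (waveform[i2] - waveform[i1])
    }
    left <- NA_real_; right <- NA_real_
    i <- idx
    while (i > 1) {
      if ((waveform[i - 1] - half) * (waveform[i] - half) <= 0 &&
          waveform[i - 1] != waveform[i]) { left <- cross(i - 1, i); break }
      i <- i - 1
    }
    i <- idx
    while (i < length(waveform)) {
      if ((waveform[i + 1] - half) * (waveform[i] - half) <= 0 &&
          waveform[i + 1] != waveform[i]) { right <- cross(i, i + 1); break }
      i <- i + 1
    }
    right - left
  }
  structure(list(
    valley_width = fwhm_at(iv, vdep / 2),
    peak_width = fwhm_at(ip, waveform[ip] / 2),
    peak_to_valley = t_ms[ip] - t_ms[iv],
    reliable = TRUE), class = "waveform_features")
}

#' Classify units into putative cell types from waveform features
#'
#' Fuzzy k-means (k = 2, fuzzifier m = 2) on z-scored features; units whose
#' maximum cluster membership is at most 0.75 are labelled "X"
#' (unclassified). The cluster with the smaller mean peak-to-valley time is
#' the narrow-spiking putative interneuron class ("IN"); the other is "PC".
#'
#' @param features data.frame with columns `valley_width`, `peak_width`,
#'   `peak_to_valley` (ms); at least 20 rows.
#' @param membership_min minimum membership for a confident label.
#' @param n_restarts restarts of the fuzzy clustering (deterministic seeds;
#'   best objective kept).
#' @return list: `labels` (character vector "PC"/"IN"/"X"), `membership`
#'   (max membership per unit), `centers` (feature-space cluster centres).
#' @export
classify_cells <- function(features, membership_min = 0.75, n_restarts = 10) {
  X <- as.matrix(features[, c("valley_width", "peak_width", "peak_to_valley")])
  if (nrow(X) < 20L) stop("classify_cells: need at least 20 units")
  if (any(apply(X, 2, stats::sd) == 0))
    stop("classify_cells: degenerate features (zero variance)")
  Z <- scale(X)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(1000 + r)
    cm <- e1071::cmeans(Z, centers = 2, m = 2, iter.max = 200)
    if (is.null(best) || cm$withinerror < best$withinerror) best <- cm
  }
  memb <- apply(best$membership, 1, max)
  cl <- best$cluster
  p2v_mean <- tapply(X[, "peak_to_valley"], cl, mean)
  in_cluster <- as.integer(names(p2v_mean)[which.min(p2v_mean)])
  labels <- ifelse(cl == in_cluster, "IN", "PC")
  labels[memb <= membership_min] <- "X"
  centers <- best$centers * attr(Z, "scaled:scale")[col(best$centers)] +
    attr(Z, "scaled:center")[col(best$centers)]
  list(labels = labels, membership = memb, centers = centers)
}

#' Spike entrainment to the structure's HFO phase
#'
#' Evaluates each spike's HFO phase as the circular mean of the instantaneous
#' phase over all same-structure channels *excluding the unit's own
#' electrode* (avoids spike leakage into the phase estimate), then fits a von
#' Mises distribution and runs the Rayleigh test. Entrainment is defined as
#' p < 0.001.
#'
#' @param unit a [spike_unit()].
#' @param ana named list of `analytic_series` (by channel id), e.g. from
#'   [session_analytic()]; series are assumed to start at `t0` seconds.
#' @param channels session channel table (to find same-structure channels).
#' @param t0 absolute time of the first analytic sample, seconds.
#' @param min_spikes minimum number of in-window spikes.
#' @param alpha entrainment significance level.
#' @return object of class `entrainment_result`: `mu` (rad, trough = 0),
#'   `kappa`, `rayleigh_p`, `entrained`, `n_spikes`, `includable`
#'   (kappa > 0.1, the strength-summary inclusion rule); or a skip record
#'   (`skipped = TRUE`, `reason`) when no eligible channel or too few spikes.
#' @export
spike_entrainment <- function(unit, ana, channels, t0 = 0, min_spikes = 50,
                              alpha = 0.001) {
  own_struct <- channels$structure[channels$channel_id == unit$electrode]
  elig <- channels$channel_id[channels$structure == own_struct &
                              channels$channel_id != unit$electrode]
  elig <- intersect(as.character(elig), names(ana))
  if (!length(elig))
    return(list(skipped = TRUE, reason = "no eligible same-structure channel"))
  fs <- ana[[elig[1]]]$fs
  n <- length(ana[[elig[1]]]$phase)
  idx <- round((unit$spike_times - t0) * fs) + 1
  idx <- idx[idx >= 1 & idx <= n]
  if (length(idx) < min_spikes)
    return(list(skipped = TRUE, reason = "too few spikes in window"))
  zsum <- complex(real = numeric(length(idx)), imaginary = numeric(length(idx)))
  for (ch in elig) zsum <- zsum + exp(1i * ana[[ch]]$phase[idx])
  phases <- wrap_angle(Arg(zsum))
  vm <- vonmises_fit(phases)
  p <- rayleigh_test(phases)
  structure(list(mu = vm$mu, kappa = vm$kappa, rayleigh_p = p,
                 entrained = p < alpha, n_spikes = length(idx),
                 includable = vm$kappa > 0.1, skipped = FALSE),
            class = "entrainment_result")
}

#' Bhattacharyya distance between two point clouds
#'
#' Gaussian Bhattacharyya distance from sample moments:
#' `D_B = (1/8) (mu_a - mu_b)' Sbar^-1 (mu_a - mu_b)
#'        + (1/2) ln(|Sbar| / sqrt(|Sa| |Sb|))`, `Sbar = (Sa + Sb)/2`.
#'
#' @param points_a,points_b numeric matrices (n x d, d >= 2, n >= 3).
#' @return distance (non-negative scalar).
#' @export
bhattacharyya <- function(points_a, points_b) {
  A <- as.matrix(points_a); B <- as.matrix(points_b)
  stopifnot(ncol(A) == ncol(B), ncol(A) >= 2, nrow(A) >= 3, nrow(B) >= 3)
  ma <- colMeans(A); mb <- colMeans(B)
  Sa <- stats::cov(A); Sb <- stats::cov(B)
  Sbar <- (Sa + Sb) / 2
  det_bar <- det(Sbar)
  if (!is.finite(det_bar) || det_bar <= 1e-300)
    stop("bhattacharyya: singular pooled covariance; consider regularising the features")
  d <- ma - mb
  as.numeric(t(d) %*% solve(Sbar, d)) / 8 +
    0.5 * log(det_bar / sqrt(det(Sa) * det(Sb)))
}
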