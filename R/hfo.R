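# Parametric HFO detection: Gaussian + linear peak model fitted to the
# fractal-normalised spectrum, printed detection criteria, prevalence classes.

#' Detection criteria for a positive HFO call
#'
#' The operative bounds (all strict inequalities): goodness-of-fit R^2 > 0.2,
#' peak height 2 < a1 < 100 dB, peak frequency 90 < a2 < 170 Hz, peak width
#' 1 < a3 < 20 Hz, slope -1 < a4 < 1 dB/Hz and offset -10 < a5 < 10 dB.
#'
#' @param r2_min minimum R^2.
#' @param a1,a2,a3,a4,a5 length-2 open intervals for each parameter.
#' @return list of class `detection_criteria`.
#' @export
detection_criteria <- function(r2_min = 0.2, a1 = c(2, 100), a2 = c(90, 170),
                               a3 = c(1, 20), a4 = c(-1, 1), a5 = c(-10, 10)) {
  stopifnot(a1[1] < a1[2], a2[1] < a2[2], a3[1] < a3[2],
            a4[1] < a4[2], a5[1] < a5[2])
  structure(list(r2_min = r2_min, a1 = a1, a2 = a2, a3 = a3, a4 = a4, a5 = a5),
            class = "detection_criteria")
}

#' Apply the detection criteria to fitted parameters
#'
#' @param params named numeric vector `a1..a5`.
#' @param r2 goodness-of-fit R^2.
#' @param criteria a [detection_criteria()].
#' @return logical: positive detection?
#' @export
apply_criteria <- function(params, r2, criteria = detection_criteria()) {
  inside <- function(v, b) is.finite(v) && v > b[1] && v < b[2]
  is.finite(r2) && r2 > criteria$r2_min &&
    inside(params[["a1"]], criteria$a1) &&
    inside(params[["a2"]], criteria$a2) &&
    inside(params[["a3"]], criteria$a3) &&
    inside(params[["a4"]], criteria$a4) &&
    inside(params[["a5"]], criteria$a5)
}

# the peak model: Gaussian bump on a linear trend
.peak_model <- function(f, a1, a2, a3, a4, a5) {
  a1 * exp(-((f - a2) / a3)^2) + a4 * f + a5
}

#' Fit the Gaussian + linear peak model to a rhythmicity spectrum
#'
#' Fits `y(f) = a1*exp(-((f - a2)/a3)^2) + a4*f + a5` to `S_dB` over
#' `fit_band` by Levenberg--Marquardt nonlinear least squares with 5
#' deterministic multi-starts (the peak-frequency start is jittered by 0,
#' -10, +10, -5, +5 Hz; the best residual sum of squares wins), then applies
#' the detection criteria.
#'
#' @param S_dB rhythmicity spectrum values, dB_fractal.
#' @param freqs frequency grid, Hz.
#' @param fit_band band used for fitting, Hz; needs >= 20 grid points.
#' @param criteria a [detection_criteria()].
#' @return object of class `hfo_fit`: `a1..a5`, `r2`, `detected`, `valid`
#'   (FALSE when no start converged).
#' @export
fit_peak_model <- function(S_dB, freqs, fit_band = c(70, 200),
                           criteria = detection_criteria()) {
  keep <- freqs >= fit_band[1] & freqs <= fit_band[2]
  if (sum(keep) < 20L)
    stop("fit_peak_model: need at least 20 frequency points in fit_band")
  f <- freqs[keep]; y <- S_dB[keep]

  # initialisation: peak at argmax within the a2 bounds; trend from band edges
  ne <- max(3L, round(0.1 * length(f)))
  edge <- c(seq_len(ne), length(f) - ne + seq_len(ne))
  lf <- stats::lm.fit(cbind(1, f[edge]), y[edge])$coefficients
  a5_0 <- unname(lf[1]); a4_0 <- unname(lf[2])
  in_pk <- f > criteria$a2[1] & f < criteria$a2[2]
  if (!any(in_pk)) in_pk <- rep(TRUE, length(f))
  resid0 <- y - (a4_0 * f + a5_0)
  i_pk <- which(in_pk)[which.max(resid0[in_pk])]
  a2_0 <- f[i_pk]; a1_0 <- max(resid0[i_pk], 0.5)

  best <- NULL
  for (jit in c(0, -10, 10, -5, 5)) {
    st <- list(a1 = a1_0, a2 = a2_0 + jit, a3 = 5, a4 = a4_0, a5 = a5_0)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a1 * exp(-((f - a2) / a3)^2) + a4 * f + a5,
                        data = list(y = y, f = f), start = st,
                        lower = c(-Inf, -Inf, 1e-3, -Inf, -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      ss <- sum(stats::resid(fit)^2)
      if (is.null(best) || ss < best$ss)
        best <- list(ss = ss, coef = stats::coef(fit))
    }
  }
  if (is.null(best)) {
    return(structure(list(a1 = NA_real_, a2 = NA_real_, a3 = NA_real_,
                          a4 = NA_real_, a5 = NA_real_, r2 = NA_real_,
                          detected = FALSE, valid = FALSE),
                     class = "hfo_fit"))
  }
  cf <- best$coef
  cf["a3"] <- abs(cf["a3"])
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot > 0) 1 - best$ss / sstot else 1
  structure(list(a1 = unname(cf["a1"]), a2 = unname(cf["a2"]),
                 a3 = unname(cf["a3"]), a4 = unname(cf["a4"]),
                 a5 = unname(cf["a5"]), r2 = r2,
                 detected = apply_criteria(cf, r2, criteria), valid = TRUE),
            class = "hfo_fit")
}

#' HFO detection rate across spectral windows
#'
#' Fraction of windows whose (structure-averaged) rhythmicity spectrum passes
#' the peak-model detection.
#'
#' @param frames list of `spectral_frame` objects.
#' @param fit_band,criteria passed to [fit_peak_model()].
#' @return list with `rate` in \[0, 1\] and the per-window `fits`.
#' @export
detection_rate <- function(frames, fit_band = c(70, 200),
                           criteria = detection_criteria()) {
  stopifnot(length(frames) >= 1L)
  fits <- lapply(frames, function(fr)
    fit_peak_model(fr$S_dB, fr$freqs, fit_band, criteria))
  det <- vapply(fits, function(f) isTRUE(f$detected), logical(1))
  list(rate = mean(det), fits = fits)
}

#' Classify HFO prevalence from per-session detection rates
#'
#' For one (structure, condition) cell: "persistent" when more than a third
#' of sessions have a detection rate above 0.9; otherwise "prevalent" when
#' more than a third are above 0.5; otherwise "absent" when fewer than 5% of
#' sessions exceed a 0.05 rate; otherwise "occasional".
#'
#' @param session_rates numeric vector of per-session detection rates.
#' @return one of "persistent", "prevalent", "occasional", "absent".
#' @export
prevalence_class <- function(session_rates) {
  stopifnot(length(session_rates) >= 1L,
            all(session_rates >= 0), all(session_rates <= 1))
  if (mean(session_rates > 0.9) > 1 / 3) return("persistent")
  if (mean(session_rates > 0.5) > 1 / 3) return("prevalent")
  if (mean(session_rates > 0.05) < 0.05) return("absent")
  "occasional"
}

#' Median HFO frequency of a recording
#'
#' Median of the fitted peak frequencies `a2` over positively detected
#' windows; this is the narrowband centre used by the phase-synchrony stage.
#'
#' @param fits list of `hfo_fit` objects.
#' @return median frequency, Hz.
#' @export
median_hfo_frequency <- function(fits) {
  a2 <- vapply(fits, function(f) f$a2, numeric(1))
  det <- vapply(fits, function(f) isTRUE(f$detected), logical(1))
  if (!any(det))
    stop("median_hfo_frequency: no positive detections; skip phase analysis for this recording")
  stats::median(a2[det])
}
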