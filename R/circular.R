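#' Wrap angles to (-pi, pi]
#'
#' Angles are mapped into the half-open interval (-pi, pi]; a value that wraps
#' to exactly -pi is reported as +pi.
#'
#' @param theta numeric vector of angles in radians.
#' @return numeric vector of wrapped angles.
#' @export
wrap_angle <- function(theta) {
  x <- theta %% (2 * pi)          # [0, 2*pi)
  gt <- !is.na(x) & x > pi
  x[gt] <- x[gt] - 2 * pi
  # %% can leave exactly -pi through floating point; tie goes to +pi
  x[!is.na(x) & x == -pi] <- pi
  x
}

#' Circular summary statistics
#'
#' Computes the circular mean direction, the resultant vector length and the
#' von Mises concentration for a sample of angles. The concentration kappa is
#' obtained from the resultant length by the piecewise Best--Fisher
#' approximation (branches at r = 0.53 and r = 0.85), capped at 1e3.
#'
#' @param angles numeric vector of angles in radians; at least one finite value.
#' @return object of class `circ_summary`: list with `mu` (mean direction,
#'   radians in (-pi, pi], `NA` and `mu_defined = FALSE` when the resultant is
#'   numerically zero), `r` (resultant length in \[0, 1\]), `kappa`
#'   (concentration, >= 0), `n` (sample size).
#' @examples
#' s <- circ_summary(c(0, pi / 2))
#' s$mu  # pi/4
#' s$r   # cos(pi/4)
#' @export
circ_summary <- function(angles) {
  if (length(angles) < 1L) stop("circ_summary: empty input")
  if (any(!is.finite(angles))) stop("circ_summary: non-finite angles")
  n <- length(angles)
  C <- mean(cos(angles))
  S <- mean(sin(angles))
  r <- min(sqrt(C^2 + S^2), 1)
  mu_defined <- r >= 1e-12
  mu <- if (mu_defined) wrap_angle(atan2(S, C)) else NA_real_
  structure(
    list(mu = mu, r = r, kappa = .kappa_from_r(r), n = n,
         mu_defined = mu_defined),
    class = "circ_summary"
  )
}

# Best-Fisher approximation of the von Mises concentration given the
# resultant length r (maximum-likelihood inversion of A(kappa) = r).
.kappa_from_r <- function(r) {
  k <- if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
  min(max(k, 0), 1e3)
}

#' Fit a von Mises distribution by circular moments
#'
#' Moment-based estimates of the preferred direction mu and concentration
#' kappa, matching [circ_summary()]. Used for spike-phase preference and for
#' phase-difference concentration. No small-sample bias correction is applied
#' to kappa.
#'
#' @param angles numeric vector of angles in radians; at least 10 values.
#' @return list with `mu` and `kappa`.
#' @export
vonmises_fit <- function(angles) {
  if (length(angles) < 10L)
    stop("vonmises_fit: need at least 10 angles for a stable fit")
  s <- circ_summary(angles)
  list(mu = s$mu, kappa = s$kappa)
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis that angles are uniformly distributed on the
#' circle, using the Rayleigh Z statistic with the standard finite-n corrected
#' p-value approximation.
#'
#' @param angles numeric vector of angles in radians; at least 10 values.
#' @return p-value (numeric scalar, clamped to \[0, 1\]).
#' @export
rayleigh_test <- function(angles) {
  if (length(angles) < 10L)
    stop("rayleigh_test: need at least 10 angles")
  n <- length(angles)
  r <- circ_summary(angles)$r
  R <- n * r
  # finite-n corrected approximation of the Rayleigh p-value
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  min(max(p, 0), 1)
}
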