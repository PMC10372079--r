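# Test-side oracles and samplers, independent of the package implementation.

# von Mises sampler (Best & Fisher rejection algorithm)
rvonmises <- function(n, mu, kappa) {
  if (kappa == 0) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- (mu + sign(u3 - 0.5) * acos(f))
    }
  }
  (out + pi) %% (2 * pi) - pi
}

# grid-search ML estimate of von Mises (mu, kappa) -- brute-force oracle
vm_mle_grid <- function(angles, kappa_grid = seq(0.01, 10, by = 0.01)) {
  mu_hat <- atan2(mean(sin(angles)), mean(cos(angles)))
  ll <- vapply(kappa_grid, function(k)
    k * sum(cos(angles - mu_hat)) - length(angles) * log(besselI(k, 0)),
    numeric(1))
  list(mu = mu_hat, kappa = kappa_grid[which.max(ll)])
}

# averaged-periodogram log-log slope oracle (for fractal noise checks)
psd_slope <- function(x, fs, f_lo, f_hi, n_seg = 16) {
  n <- floor(length(x) / n_seg)
  acc <- NULL
  for (k in seq_len(n_seg)) {
    seg <- x[((k - 1) * n + 1):(k * n)]
    seg <- seg - mean(seg)
    P <- Mod(fft(seg))^2
    kmax <- floor(n / 2)
    S <- P[2:(kmax + 1)]
    acc <- if (is.null(acc)) S else acc + S
  }
  freqs <- (1:floor(n / 2)) * fs / n
  keep <- freqs >= f_lo & freqs <= f_hi
  unname(coef(lm(log10(acc[keep]) ~ log10(freqs[keep])))[2])
}

# small two-structure synthetic session used by several test files
make_test_session <- function(seed = 5, duration = 900, injection = 300,
                              fs = 1000, base_rate = 8) {
  cfg <- synth_config("5HT2A", fs = fs, duration = duration,
                      injection_time = injection,
                      structures = c(OB = 2L, vStr = 2L),
                      spikes = list(n_per_structure = 2L,
                                    base_rate = base_rate),
                      seed = seed)
  gen_session(cfg)
}

# scaled epochs matching make_test_session timings
test_epoch_drug <- function() epoch("drug", 60, 560)
test_epoch_base <- function() epoch("baseline", -290, -40)
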