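# Independent brute-force oracles (explicit loops, no shared code with the
# implementation) and small fixture builders used across test files.

oracle_rr_features <- function(iv) {
  n <- length(iv)
  mu <- 0
  for (x in iv) mu <- mu + x
  mu <- mu / n
  mx <- iv[1]; mn <- iv[1]
  for (x in iv) { if (x > mx) mx <- x; if (x < mn) mn <- x }
  ssd <- 0
  for (i in 2:n) ssd <- ssd + (iv[i] - iv[i - 1])^2
  rmssd <- if (n - 2 > 0) sqrt(ssd / (n - 2)) else NA_real_
  ssq <- 0
  for (x in iv) ssq <- ssq + (x - mu)^2
  sdv <- sqrt(ssq / (n - 1))
  adev <- 0
  for (x in iv) adev <- adev + abs(x - mu)
  list(mean_rr = mu,
       norm_max_diff = (mx - mn) / mu,
       rmssd = rmssd,
       cov = sdv / mu,
       nad = adev / (mu * n))
}

oracle_moments <- function(x) {
  n <- length(x)
  mu <- 0
  for (v in x) mu <- mu + v
  mu <- mu / n
  ss <- 0; s3 <- 0
  for (v in x) { ss <- ss + (v - mu)^2; s3 <- s3 + (v - mu)^3 }
  vr <- ss / (n - 1)
  sk <- if (n >= 3 && vr > 0)
    (n^2 / ((n - 1) * (n - 2))) * (s3 / n) / sqrt(ss / n)^3 else NA_real_
  list(mean = mu, variance = vr, sd = sqrt(vr), skewness = sk)
}

oracle_errors <- function(est, ref) {
  n <- length(est)
  se <- 0; ae <- 0; aev <- numeric(n)
  for (i in 1:n) {
    e <- est[i] - ref[i]
    se <- se + e^2
    ae <- ae + abs(e)
    aev[i] <- abs(e)
  }
  list(mse = se / n, rmse = sqrt(se / n), mae = ae / n,
       medae = median(aev))
}

# trapezoid integral of the exact triangular pulse times cos(2*pi*n*t/T)
# over one period -- the numerical-integration oracle for the closed form
oracle_fourier_coef <- function(params, n, n_points = 1e5) {
  T <- params$period
  tt <- seq(-T / 2, T / 2, length.out = n_points + 1)
  f <- triangular_pulse(tt, params)
  h <- tt[2] - tt[1]
  trapz <- function(y) h * (sum(y) - (y[1] + y[length(y)]) / 2)
  if (n == 0) trapz(f) / T
  else 2 * trapz(f * cos(2 * pi * n * tt / T)) / T
}

# phase series built directly from the displacement model (radians)
make_phase <- function(heart_freq = 1.2, breathing_freq = 0.3,
                       heart_amp = 1.5e-4, breathing_amp = 4e-3,
                       duration = 25.6, rate = 20,
                       lambda = 299792458 / 77e9) {
  sc <- displacement_scenario(breathing_amplitude = breathing_amp,
                              breathing_freq = breathing_freq,
                              heart_amplitude = heart_amp,
                              heart_freq = heart_freq,
                              duration = duration)
  r <- simulate_chest_displacement(sc, rate)
  phase_series(4 * pi * r / lambda, rate, lambda)
}

default_cube <- function(scenario = displacement_scenario(), noise_sd = 0,
                         seed = 1, config = chirp_config()) {
  d <- simulate_chest_displacement(scenario,
                                   rate = 1 / config$slow_sample_interval)
  synthesize_if_cube(d, config, noise_sd = noise_sd, seed = seed)
}
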