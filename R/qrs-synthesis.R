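#' Symmetric triangular pulse parameters
#'
#' The QRS-like heartbeat pulse is an even triangular wave
#' `f(t) = A * (1 - B*|t|/T)` on `|t| <= T/B`, zero elsewhere on the
#' period `T`. `A` is the peak amplitude and `B >= 1` controls the QRS
#' interval: the pulse support is `2T/B`.
#'
#' @param amplitude Peak amplitude A.
#' @param width_factor Width factor B (>= 1).
#' @param period Period T in seconds.
#' @param n_terms Number of harmonics kept in the truncated Fourier series.
#' @return An object of class `triangular_pulse_params`.
#' @export
triangular_pulse_params <- function(amplitude = 1, width_factor = 4,
                                    period = 1, n_terms = 32) {
  stopifnot(is.finite(amplitude), period > 0, n_terms >= 1)
  if (width_factor < 1)
    stop("width_factor must be >= 1: pulse support may not exceed the period")
  structure(list(amplitude = amplitude, width_factor = width_factor,
                 period = period, n_terms = as.integer(n_terms)),
            class = "triangular_pulse_params")
}

#' Fourier cosine coefficients of the triangular pulse
#'
#' The pulse is even, so all sine coefficients vanish. With fundamental
#' `w = 2*pi/T`, direct integration over one period gives the mean term
#' `a0 = A/B` and harmonics
#' `a_n = (A*B / (n^2 * pi^2)) * (1 - cos(2*pi*n/B))`
#' for `B >= 2` (pulse support inside the period). For `1 <= B < 2` the
#' triangle is truncated at the period boundary `|t| = T/2` and the same
#' integration gives `a0 = A*(1 - B/4)` and
#' `a_n = (A*B / (n^2 * pi^2)) * (1 - cos(n*pi))`.
#' `convention = "printed"` instead returns the closed forms
#' `a0 = A*B*(2-B)` and `a_n = (2*B*A/(n^2*pi^2)) * (1 - cos(n*pi/B))`,
#' which circulate in the applied literature but do not agree with the
#' integral they are presented as evaluating (see the methods vignette);
#' they are retained for comparison only.
#'
#' @param params A [triangular_pulse_params()].
#' @param convention `"integral"` (default, the correct coefficients) or
#'   `"printed"`.
#' @return List with `a0` (the mean term) and `an` (vector of length
#'   `n_terms`).
#' @export
triangular_fourier_coefficients <- function(params,
                                            convention = c("integral",
                                                           "printed")) {
  stopifnot(inherits(params, "triangular_pulse_params"))
  convention <- match.arg(convention)
  A <- params$amplitude
  B <- params$width_factor
  n <- seq_len(params$n_terms)
  if (convention == "integral") {
    if (B >= 2) {
      a0 <- A / B
      an <- (A * B / (n^2 * pi^2)) * (1 - cos(2 * pi * n / B))
    } else {
      # support reaches past |t| = T/2: the periodized pulse is truncated
      # at the period boundary, which changes both integrals
      a0 <- A * (1 - B / 4)
      an <- (A * B / (n^2 * pi^2)) * (1 - cos(n * pi))
    }
  } else {
    a0 <- A * B * (2 - B)
    an <- (2 * B * A / (n^2 * pi^2)) * (1 - cos(n * pi / B))
  }
  list(a0 = a0, an = an)
}

#' Evaluate the exact triangular pulse
#'
#' One period of the even pulse, for use as the reference waveform in
#' convergence checks.
#'
#' @param t Times in seconds (taken modulo the period, centered on 0).
#' @param params A [triangular_pulse_params()].
#' @return Pulse values.
#' @export
triangular_pulse <- function(t, params) {
  stopifnot(inherits(params, "triangular_pulse_params"))
  T <- params$period
  B <- params$width_factor
  u <- (t + T / 2) %% T - T / 2    # fold into [-T/2, T/2)
  out <- numeric(length(u))
  inside <- abs(u) <= T / B
  out[inside] <- params$amplitude * (1 - B * abs(u[inside]) / T)
  out
}

#' Evaluate the truncated Fourier series of the pulse
#'
#' `S_N(t) = a0 + sum_n a_n * cos(2*pi*n*t/T)`.
#'
#' @param t Times in seconds.
#' @param params A [triangular_pulse_params()].
#' @return Series values at `t`.
#' @export
triangular_series <- function(t, params) {
  co <- triangular_fourier_coefficients(params)
  T <- params$period
  out <- rep(co$a0, length(t))
  for (n in seq_along(co$an))
    out <- out + co$an[n] * cos(2 * pi * n * t / T)
  out
}

# Fourier-domain resampling: ideal anti-aliasing low-pass by spectrum
# truncation, then inverse transform on the coarse grid. Assumes the
# signal is treated as one period (both rates share the observation
# window), which holds by construction here.
fourier_resample <- function(x, n_out) {
  n <- length(x)
  stopifnot(n_out >= 2, n_out <= n)
  X <- fft(x)
  half <- floor(n_out / 2)
  Y <- complex(n_out)
  Y[1] <- X[1]
  if (half >= 1) {
    Y[2:(half + 1)] <- X[2:(half + 1)]
    Y[(n_out - half + 1):n_out] <- X[(n - half + 1):n]
    if (n_out %% 2 == 0) {    # split the shared Nyquist bin
      Y[half + 1] <- (X[half + 1] + X[n - half + 1]) / 2
    }
  }
  Re(fft(Y, inverse = TRUE)) / n
}

#' Synthesize a QRS-like train from detected peak times
#'
#' Each inter-peak gap defines a local period; a truncated-Fourier
#' triangular pulse of that period is centered on each peak. The train is
#' synthesized at `100000 * n / duration` Hz (`n` = number of peaks,
#' i.e. 100,000 samples per beat component) and resampled to `out_rate`
#' with an anti-aliasing low-pass.
#'
#' @param peak_times Strictly increasing peak times (s) within
#'   `[0, duration]`; at least 2.
#' @param observation_duration Observation length in seconds.
#' @param amplitude Common pulse amplitude (typically the mean detected
#'   peak phase value).
#' @param width_factor,n_terms Pulse shape parameters; see
#'   [triangular_pulse_params()].
#' @param out_rate Output sampling rate in Hz (default 5).
#' @return An object of class `reconstructed_signal`: list with `values`,
#'   `rate`, `source_peak_times`, `synthesis_rate`.
#' @export
synthesize_train <- function(peak_times, observation_duration,
                             amplitude = 1, width_factor = 4, n_terms = 32,
                             out_rate = 5) {
  n_pk <- length(peak_times)
  if (n_pk < 2) stop("cannot synthesize: need at least 2 peaks")
  stopifnot(all(diff(peak_times) > 0),
            peak_times[1] >= 0,
            peak_times[n_pk] <= observation_duration,
            observation_duration > 0, out_rate > 0)
  fs_hi <- 1e5 * n_pk / observation_duration
  n_hi <- round(observation_duration * fs_hi)   # = 100000 * n_pk exactly
  t <- (seq_len(n_hi) - 1) / fs_hi
  gaps <- diff(peak_times)
  x <- numeric(n_hi)
  for (j in seq_len(n_pk)) {
    # local period: the adjacent RR interval (mean of the two for interior
    # peaks), so the train is periodic beat by beat
    T_j <- if (j == 1) gaps[1]
           else if (j == n_pk) gaps[n_pk - 1]
           else (gaps[j - 1] + gaps[j]) / 2
    params <- triangular_pulse_params(amplitude, width_factor, T_j, n_terms)
    lo <- if (j == 1) 0 else peak_times[j] - gaps[j - 1] / 2
    hi <- if (j == n_pk) observation_duration
          else peak_times[j] + gaps[j] / 2
    seg <- t >= lo & t < hi
    x[seg] <- triangular_series(t[seg] - peak_times[j], params)
  }
  n_out <- round(observation_duration * out_rate)
  y <- fourier_resample(x, n_out)
  structure(list(values = y, rate = out_rate,
                 source_peak_times = peak_times, synthesis_rate = fs_hi),
            class = "reconstructed_signal")
}

#' One-sided periodogram
#'
#' Mean-removed, one-sided periodogram normalized so the PSD sums (times
#' the bin width) to the series variance (the biased, 1/n, variance).
#'
#' @param x Numeric vector or a `reconstructed_signal`.
#' @param rate Sampling rate in Hz (ignored when `x` carries one).
#' @return List with `freq` (Hz), `psd`, and `peak_freq`, the frequency of
#'   maximal density.
#' @export
periodogram <- function(x, rate = NULL) {
  if (inherits(x, "reconstructed_signal")) {
    rate <- x$rate
    x <- x$values
  }
  stopifnot(!is.null(rate), rate > 0, length(x) >= 8)
  n <- length(x)
  x <- x - mean(x)
  X <- fft(x)
  half <- floor(n / 2)
  raw <- Mod(X[1:(half + 1)])^2 / (n^2)         # two-sided power per bin
  one <- raw
  interior <- 2:(half + if (n %% 2 == 0) 0 else 1)
  one[interior] <- 2 * raw[interior]            # fold negative frequencies
  df <- rate / n
  psd <- one / df
  freq <- (0:half) * df
  list(freq = freq, psd = psd, peak_freq = freq[which.max(psd)])
}

#' Estimate the SNR of a (reconstructed) heartbeat signal
#'
#' Signal power is the PSD mass within `guard_bins` bins of the
#' fundamental and of its 2nd harmonic; noise power is all remaining mass.
#'
#' @param x Numeric vector or `reconstructed_signal`.
#' @param fundamental_hz Fundamental frequency in Hz, inside (0, rate/2).
#' @param guard_bins Bins kept on each side of the fundamental/harmonic.
#' @param rate Sampling rate in Hz (ignored when `x` carries one).
#' @return SNR in dB.
#' @export
estimate_snr <- function(x, fundamental_hz, guard_bins = 1, rate = NULL) {
  if (inherits(x, "reconstructed_signal")) {
    rate <- x$rate
    x <- x$values
  }
  stopifnot(!is.null(rate))
  if (fundamental_hz <= 0 || fundamental_hz >= rate / 2)
    stop("fundamental outside (0, Nyquist)")
  pg <- periodogram(x, rate)
  df <- pg$freq[2] - pg$freq[1]
  sig <- rep(FALSE, length(pg$freq))
  for (f0 in c(fundamental_hz, 2 * fundamental_hz)) {
    if (f0 >= rate / 2) next
    k <- which.min(abs(pg$freq - f0))
    lo <- max(1, k - guard_bins)
    hi <- min(length(sig), k + guard_bins)
    sig[lo:hi] <- TRUE
  }
  p_sig <- sum(pg$psd[sig]) * df
  p_noise <- sum(pg$psd[!sig]) * df
  10 * log10(p_sig / max(p_noise, .Machine$double.xmin))
}
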