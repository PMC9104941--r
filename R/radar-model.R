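#' @importFrom stats fft rnorm runif sd median quantile var
#' @importFrom utils write.csv read.csv
NULL

SPEED_OF_LIGHT <- 299792458

#' Radar chirp configuration
#'
#' Waveform and sampling parameters of a linear-FMCW chirp train. Defaults
#' correspond to a 77 GHz automotive-band sensor sweeping 4 GHz in 50 us,
#' sampled at 2 Msps in fast time and 20 chirps/s in slow time.
#'
#' @param fc Chirp start frequency in Hz.
#' @param bandwidth Sweep bandwidth B in Hz.
#' @param chirp_duration Chirp duration T_C in seconds.
#' @param fast_sample_interval ADC sampling interval T_f in seconds.
#' @param slow_sample_interval Chirp repetition interval T_s in seconds.
#' @param n_fast ADC samples per chirp.
#' @param n_chirps Chirps per observation.
#' @param tx_amplitude Transmitted amplitude A_T (linear units).
#' @param rx_scale Reflection scale beta (dimensionless, >= 0).
#' @param rx_power Received power P_R (linear units); the IF amplitude is
#'   sqrt(P_R).
#' @param antenna_spacing Receive antenna spacing d_m in meters.
#' @return An object of class `chirp_config`. The carrier wavelength
#'   `wavelength = c/fc` is derived and stored.
#' @export
chirp_config <- function(fc = 77e9, bandwidth = 4e9, chirp_duration = 50e-6,
                         fast_sample_interval = 0.5e-6,
                         slow_sample_interval = 0.05,
                         n_fast = 100, n_chirps = 512,
                         tx_amplitude = 1, rx_scale = 1, rx_power = 1,
                         antenna_spacing = 0) {
  stopifnot(fc > 0, bandwidth > 0, chirp_duration > 0,
            fast_sample_interval > 0, slow_sample_interval > 0,
            n_fast >= 1, n_chirps >= 1, rx_scale >= 0, rx_power >= 0)
  if (n_fast * fast_sample_interval > chirp_duration + 1e-12)
    stop("fast-time sampling window exceeds the chirp duration")
  if (slow_sample_interval < chirp_duration)
    stop("slow_sample_interval must be >= chirp_duration")
  structure(list(
    fc = fc, bandwidth = bandwidth, chirp_duration = chirp_duration,
    fast_sample_interval = fast_sample_interval,
    slow_sample_interval = slow_sample_interval,
    n_fast = as.integer(n_fast), n_chirps = as.integer(n_chirps),
    tx_amplitude = tx_amplitude, rx_scale = rx_scale, rx_power = rx_power,
    antenna_spacing = antenna_spacing,
    wavelength = SPEED_OF_LIGHT / fc
  ), class = "chirp_config")
}

#' Range-bin size of a chirp configuration
#'
#' @param config A [chirp_config()].
#' @return Range extent of one FFT bin, `c / (2 * bandwidth)` scaled by the
#'   sampled fraction of the sweep, in meters.
#' @export
range_bin_size <- function(config) {
  stopifnot(inherits(config, "chirp_config"))
  # slope S = B / T_C; beat frequency f_b = S * 2R/c; one FFT bin spans
  # fs / n_fast in beat frequency, hence c * fs / (2 * S * n_fast) in range.
  slope <- config$bandwidth / config$chirp_duration
  fs <- 1 / config$fast_sample_interval
  SPEED_OF_LIGHT * fs / (2 * slope * config$n_fast)
}

#' Chest-displacement scenario
#'
#' Ground-truth description of a single monitored subject: a static base
#' range plus sinusoidal breathing, a pulse-like heartbeat displacement and
#' optional random-body-movement (RBM) bursts.
#'
#' @param base_range Radar-to-chest distance R0 in meters.
#' @param breathing_amplitude,breathing_freq Breathing displacement (m) and
#'   rate (Hz, typically 0.1-0.5).
#' @param heart_amplitude,heart_freq Heartbeat displacement (m) and rate
#'   (Hz, typically 0.8-2).
#' @param angle_of_arrival Angle of arrival Theta in radians.
#' @param phase_noise_sd Standard deviation of an optional residual phase
#'   random walk (rad per sample); 0 disables it (short-range range
#'   correlation makes residual phase noise negligible).
#' @param rbm_events List of RBM bursts, each `c(start, duration, amplitude)`
#'   in (s, s, m).
#' @param duration Observation length in seconds.
#' @param orientation_gain Attenuation in (0, 1] emulating subject
#'   orientation (1 = facing the radar).
#' @return An object of class `displacement_scenario`.
#' @export
displacement_scenario <- function(base_range = 0.5,
                                  breathing_amplitude = 4e-3,
                                  breathing_freq = 0.3,
                                  heart_amplitude = 1.5e-4,
                                  heart_freq = 1.2,
                                  angle_of_arrival = 0,
                                  phase_noise_sd = 0,
                                  rbm_events = list(),
                                  duration = 25.6,
                                  orientation_gain = 1) {
  stopifnot(base_range > 0, breathing_amplitude >= 0, heart_amplitude >= 0,
            breathing_freq >= 0, heart_freq >= 0, phase_noise_sd >= 0,
            duration > 0, orientation_gain > 0, orientation_gain <= 1)
  for (ev in rbm_events) {
    stopifnot(length(ev) == 3, ev[1] >= 0, ev[2] > 0,
              ev[1] + ev[2] <= duration + 1e-9)
  }
  structure(list(
    base_range = base_range,
    breathing_amplitude = breathing_amplitude, breathing_freq = breathing_freq,
    heart_amplitude = heart_amplitude, heart_freq = heart_freq,
    angle_of_arrival = angle_of_arrival, phase_noise_sd = phase_noise_sd,
    rbm_events = rbm_events, duration = duration,
    orientation_gain = orientation_gain
  ), class = "displacement_scenario")
}

# Periodic heartbeat pulse shape: raised cosine of duty cycle `duty` per
# period, peak value 1, zero elsewhere. Argument is phase in radians.
# The 0.65 default keeps a pulse-like crest while concentrating energy at
# the fundamental: narrower pulses put comparable energy into the 2nd
# harmonic, which for sub-60 BPM rates also falls inside the 0.8-2 Hz
# cardiac band and (with the harmonics' phases shifted differently by the
# causal band-pass) makes peak counting read double the true rate.
heartbeat_pulse_shape <- function(theta, duty = 0.65) {
  u <- (theta / (2 * pi)) %% 1
  out <- numeric(length(u))
  inside <- u < duty
  out[inside] <- 0.5 * (1 - cos(2 * pi * u[inside] / duty))
  out
}

# Smooth RBM burst: Hann-windowed displacement bump over [start, start+dur].
rbm_waveform <- function(t, start, dur, amp) {
  out <- numeric(length(t))
  inside <- t >= start & t < start + dur
  out[inside] <- amp * 0.5 * (1 - cos(2 * pi * (t[inside] - start) / dur))
  out
}

#' Simulate chest displacement over time
#'
#' Builds the ground-truth range series R(t): base range plus
#' orientation-scaled breathing (sinusoid) and heartbeat (raised-cosine
#' pulse train) displacements, plus any RBM bursts.
#'
#' @param scenario A [displacement_scenario()].
#' @param rate Sampling rate in samples/s; must exceed twice the heart rate.
#' @return Numeric vector of ranges in meters, length
#'   `round(duration * rate)`, with attributes `rate` and `scenario`.
#' @export
simulate_chest_displacement <- function(scenario, rate) {
  stopifnot(inherits(scenario, "displacement_scenario"))
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0)
    stop("rate must be a positive number")
  if (scenario$heart_freq >= rate / 2)
    stop("heart_freq at or above Nyquist: aliasing")
  n <- round(scenario$duration * rate)
  if (n < 2) stop("duration * rate must be at least 2 samples")
  t <- (seq_len(n) - 1) / rate
  g <- scenario$orientation_gain
  r <- rep(scenario$base_range, n)
  if (scenario$breathing_amplitude > 0 && scenario$breathing_freq > 0)
    r <- r + g * scenario$breathing_amplitude *
      sin(2 * pi * scenario$breathing_freq * t)
  if (scenario$heart_amplitude > 0 && scenario$heart_freq > 0)
    r <- r + g * scenario$heart_amplitude *
      heartbeat_pulse_shape(2 * pi * scenario$heart_freq * t)
  for (ev in scenario$rbm_events)
    r <- r + rbm_waveform(t, ev[1], ev[2], ev[3])
  attr(r, "rate") <- rate
  attr(r, "scenario") <- scenario
  r
}

#' Synthesize an IF data cube from a displacement series
#'
#' Generates the complex intermediate-frequency samples of every chirp:
#' within chirp l the target is treated as static at `R(l*T_s)` (vital-sign
#' displacements are far below a range bin, so the phase is constant across
#' fast time), giving
#' `sqrt(P_R) * exp(1i * (2*pi*f_b*k*T_f + 4*pi*R/lambda
#'   + 2*pi*d_m*sin(Theta)/lambda))`
#' with beat frequency `f_b = (B/T_C) * 2*R0/c`.
#'
#' @param displacement Range series in meters sampled at
#'   `1/slow_sample_interval`, length >= `n_chirps`.
#' @param config A [chirp_config()].
#' @param angle_of_arrival Angle of arrival in radians (adds the constant
#'   inter-antenna phase term).
#' @param noise_sd Standard deviation of additive complex Gaussian noise
#'   per I/Q component; 0 for a noiseless cube.
#' @param phase_noise_sd Standard deviation of a residual phase random walk
#'   across chirps (rad); default 0.
#' @param seed Optional integer seed for reproducible noise.
#' @return An object of class `if_cube`: list with complex matrix `samples`
#'   (`n_chirps` x `n_fast`), the `config`, and generation metadata.
#' @export
synthesize_if_cube <- function(displacement, config, angle_of_arrival = 0,
                               noise_sd = 0, phase_noise_sd = 0,
                               seed = NULL) {
  stopifnot(inherits(config, "chirp_config"))
  if (length(displacement) < config$n_chirps)
    stop("displacement series shorter than n_chirps")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_c <- config$n_chirps
  n_f <- config$n_fast
  lambda <- config$wavelength
  r <- as.numeric(displacement[seq_len(n_c)])
  r0 <- r[1]
  slope <- config$bandwidth / config$chirp_duration
  f_b <- slope * 2 * r0 / SPEED_OF_LIGHT
  k <- seq_len(n_f) - 1
  fast_phase <- 2 * pi * f_b * k * config$fast_sample_interval
  slow_phase <- 4 * pi * r / lambda +
    2 * pi * config$antenna_spacing * sin(angle_of_arrival) / lambda
  if (phase_noise_sd > 0)
    slow_phase <- slow_phase + cumsum(rnorm(n_c, 0, phase_noise_sd))
  amp <- sqrt(config$rx_power) * config$rx_scale
  # outer sum of phases: rows = chirps, cols = fast-time samples
  phase <- outer(slow_phase, fast_phase, `+`)
  samples <- amp * exp(1i * phase)
  if (noise_sd > 0)
    samples <- samples + complex(real = rnorm(n_c * n_f, 0, noise_sd),
                                 imaginary = rnorm(n_c * n_f, 0, noise_sd))
  structure(list(samples = samples, config = config,
                 truth = attr(displacement, "scenario"),
                 beat_freq = f_b, noise_sd = noise_sd),
            class = "if_cube")
}

#' Simulate an RR-interval cohort
#'
#' Generates labelled RR-interval sequences with subject metadata for
#' training and testing the arrhythmia classifier without access to
#' clinical recordings. Normal subjects draw intervals from a low-variance
#' Gaussian process (coefficient of variation ~ 0.02-0.05); arrhythmic
#' subjects from a high-variance process (CoV >= 0.15) with occasional
#' ectopic-like short or long beats.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param class_mix Fraction of subjects labelled arrhythmic, in `[0, 1]`.
#'   Exactly `round(n_subjects * class_mix)` subjects are arrhythmic.
#' @param seed Integer seed; generation is fully reproducible.
#' @param n_beats Beats per subject (default 40).
#' @return A list of subjects, each a list with `rr` (interval vector, s),
#'   `age` (years, 20-83), `gender_code` (1 = male, 0 = female) and
#'   `label` ("arrhythmia" or "normal").
#' @export
simulate_rr_cohort <- function(n_subjects, class_mix = 0.5, seed = 1,
                               n_beats = 40) {
  stopifnot(n_subjects >= 2, class_mix >= 0, class_mix <= 1, n_beats >= 4)
  set.seed(as.integer(seed))
  n_arr <- round(n_subjects * class_mix)
  labels <- c(rep("arrhythmia", n_arr), rep("normal", n_subjects - n_arr))
  labels <- sample(labels)
  lapply(seq_len(n_subjects), function(i) {
    arr <- labels[i] == "arrhythmia"
    mean_rr <- runif(1, 0.65, 1.05)
    if (arr) {
      cov_target <- runif(1, 0.16, 0.28)
      rr <- rnorm(n_beats, mean_rr, cov_target * mean_rr)
      # ectopic-like beats: premature beat followed by compensatory pause
      ect <- runif(n_beats) < 0.12
      rr[ect] <- rr[ect] * sample(c(0.55, 1.6), sum(ect), replace = TRUE)
    } else {
      cov_target <- runif(1, 0.02, 0.045)
      rr <- rnorm(n_beats, mean_rr, cov_target * mean_rr)
    }
    rr <- pmin(pmax(rr, 0.3), 2.0)
    list(rr = rr,
         age = sample(20:83, 1),
         gender_code = sample(c(0L, 1L), 1),
         label = labels[i])
  })
}
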