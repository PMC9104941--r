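#' Construct a slow-time phase series
#'
#' The pipeline's central signal type: uniformly sampled phase (radians)
#' extracted from one range bin across slow time.
#'
#' @param values Numeric phase values in radians.
#' @param rate Sampling rate in samples/s (the chirp rate).
#' @param wavelength Carrier wavelength in meters (for converting phase to
#'   displacement); may be `NA`.
#' @param origin_bin Range-bin index the phase came from; may be `NA`.
#' @return An object of class `phase_series`.
#' @export
phase_series <- function(values, rate, wavelength = NA_real_,
                         origin_bin = NA_integer_) {
  stopifnot(is.numeric(values), length(values) >= 2, rate > 0,
            all(is.finite(values)))
  structure(list(values = as.numeric(values), rate = rate,
                 wavelength = wavelength, origin_bin = origin_bin),
            class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series: %d samples @ %g Hz (%.1f s), bin %s>\n",
              length(x$values), x$rate, length(x$values) / x$rate,
              ifelse(is.na(x$origin_bin), "?", x$origin_bin)))
  invisible(x)
}

#' Range FFT of an IF data cube
#'
#' Converts each chirp's fast-time samples to a complex range profile and
#' stacks profiles along slow time. Only the one-sided spectrum is kept:
#' bins `0 .. n_fast/2`.
#'
#' @param cube An `if_cube` from [synthesize_if_cube()].
#' @return Complex matrix, rows = range bins, columns = slow-time chirps.
#' @export
range_fft <- function(cube) {
  stopifnot(inherits(cube, "if_cube"))
  s <- cube$samples
  if (length(s) == 0) stop("empty cube")
  n_f <- ncol(s)
  n_keep <- floor(n_f / 2) + 1
  # fft each row (chirp), keep one-sided bins, transpose to bins x slow time
  prof <- t(apply(s, 1, function(row) fft(row)[seq_len(n_keep)]))
  t(prof)
}

#' Select the target range bin
#'
#' Picks the bin with the largest time-averaged magnitude, at or above
#' `min_bin` (1-based matrix row `min_bin + 1`); ties go to the smaller
#' bin. `min_bin = 1` excludes the DC bin, where transmit leakage
#' accumulates.
#'
#' @param profile Complex range-profile matrix from [range_fft()].
#' @param min_bin Smallest admissible 0-based bin index.
#' @return 0-based bin index.
#' @export
select_range_bin <- function(profile, min_bin = 1) {
  stopifnot(is.matrix(profile), nrow(profile) >= 1)
  stopifnot(min_bin >= 0, min_bin < nrow(profile))
  mag <- rowMeans(Mod(profile))
  if (all(mag == 0)) stop("no target: all-zero range profile")
  cand <- seq(min_bin + 1, nrow(profile))
  best <- cand[which.max(mag[cand])]   # which.max takes the first maximum
  best - 1L
}

#' Extract the slow-time phase of a range bin
#'
#' @param profile Range-profile matrix.
#' @param bin 0-based bin index.
#' @param rate Slow-time sampling rate (Hz).
#' @param wavelength Carrier wavelength (m), optional.
#' @return A [phase_series()] with values in `(-pi, pi]`.
#' @export
extract_phase <- function(profile, bin, rate, wavelength = NA_real_) {
  stopifnot(bin >= 0, bin < nrow(profile))
  v <- profile[bin + 1, ]
  ph <- atan2(Im(v), Re(v))
  ph[ph == -pi] <- pi   # branch convention: -1 + 0i maps to +pi
  phase_series(ph, rate, wavelength, as.integer(bin))
}

#' Unwrap a phase series
#'
#' Removes 2*pi jumps so successive differences lie within `(-pi, pi]`;
#' the output is congruent to the input modulo 2*pi at every sample.
#'
#' @param series A [phase_series()].
#' @return Unwrapped [phase_series()].
#' @export
unwrap_phase <- function(series) {
  stopifnot(inherits(series, "phase_series"))
  v <- series$values
  d <- diff(v)
  # map each jump to (-pi, pi]: subtract the 2*pi multiple nearest the jump,
  # with the half-open convention that a jump of exactly -pi becomes +pi
  adj <- -2 * pi * floor((d + pi) / (2 * pi))
  out <- v + c(0, cumsum(adj))
  phase_series(out, series$rate, series$wavelength, series$origin_bin)
}

# wrap to (-pi, pi]
wrap_phase <- function(x) {
  out <- x - 2 * pi * floor((x + pi) / (2 * pi))
  out[out == -pi] <- pi
  out
}

#' Band-pass a phase series into the cardiac or breathing band
#'
#' Cascaded-biquad Butterworth band-pass: cardiac 0.8-2 Hz, breathing
#' 0.1-0.5 Hz. The cardiac band uses seven biquad sections: breathing
#' chest displacement produces phase amplitudes roughly forty times the
#' heartbeat's, and fewer sections leave enough breathing leakage in the
#' 0.8-2 Hz band to trip the motion-denoising energy threshold and to
#' rival the much weaker heartbeat fundamental. The
#' breathing band has no comparable in-band interferer and uses three
#' sections, the fewest meeting the 20 dB octave-out attenuation target.
#'
#' @param series A [phase_series()].
#' @param band `"cardiac"` or `"breathing"`.
#' @param zero_phase Forward-backward filtering (offline); default causal.
#' @param n_sections Biquad sections; default 7 (cardiac) / 3 (breathing).
#' @return Filtered [phase_series()], same length.
#' @export
bandpass_cascade <- function(series, band = c("cardiac", "breathing"),
                             zero_phase = FALSE, n_sections = NULL) {
  stopifnot(inherits(series, "phase_series"))
  band <- match.arg(band)
  edges <- switch(band, cardiac = c(0.8, 2), breathing = c(0.1, 0.5))
  if (is.null(n_sections)) n_sections <- if (band == "cardiac") 7 else 3
  casc <- design_biquad_cascade(edges[1], edges[2], series$rate, n_sections)
  # remove the mean first: the unwrapped phase carries a large constant
  # offset (4*pi*R0/lambda) that a causal band-pass would otherwise turn
  # into a long step-response transient
  x <- series$values - mean(series$values)
  if (zero_phase) {
    out <- apply_biquad_cascade(casc, x, zero_phase = TRUE)
  } else {
    # the observation is a slice of a continuously running measurement, so
    # suppress the artificial switch-on edge by odd-reflection padding at
    # the start (the filtfilt edge treatment, forward pass only), then
    # discard the pad; 20 s covers the narrow-band cascades' settle times
    n <- length(x)
    pad <- min(n - 1, round(20 * series$rate))
    xp <- c(2 * x[1] - x[(pad + 1):2], x)
    out <- apply_biquad_cascade(casc, xp)[-seq_len(pad)]
  }
  ps <- phase_series(out, series$rate, series$wavelength, series$origin_bin)
  attr(ps, "band") <- band
  ps
}

#' Motion denoising by windowed energy threshold
#'
#' Tiles the series into consecutive non-overlapping windows (default 1 s)
#' and flags any window whose energy -- the mean of squared values, in
#' rad^2 -- exceeds `e_th`. Flagged windows are excluded from downstream
#' peak detection.
#'
#' @param series A [phase_series()].
#' @param window_s Window length in seconds (default 1).
#' @param e_th Energy threshold in rad^2 (default 0.04).
#' @return List with `series` (unchanged), logical `keep` mask per sample,
#'   `window_energy` per window, and `discarded` data.frame of
#'   (start, end) times in seconds.
#' @export
motion_denoise <- function(series, window_s = 1, e_th = 0.04) {
  stopifnot(inherits(series, "phase_series"))
  w <- round(window_s * series$rate)
  if (w < 1) stop("window shorter than one sample")
  n <- length(series$values)
  n_win <- ceiling(n / w)
  idx <- rep(seq_len(n_win), each = w)[seq_len(n)]
  energy <- tapply(series$values^2, idx, mean)
  bad <- as.numeric(energy) > e_th
  keep <- !bad[idx]
  starts <- (which(bad) - 1) * w / series$rate
  ends <- pmin(which(bad) * w / series$rate, n / series$rate)
  list(series = series, keep = keep,
       window_energy = as.numeric(energy),
       discarded = data.frame(start = starts, end = ends))
}

#' Adaptive peak detection with interval-outlier rejection
#'
#' Candidate peaks are strict local maxima with positive amplitude inside
#' retained windows. Inter-peak distances are then screened: a peak whose
#' preceding interval lies outside mean +/- 1 SD of all intervals is
#' rejected in a single pass (the earlier peak is kept). When all
#' intervals are equal (SD = 0) nothing is rejected.
#'
#' @param denoised Output of [motion_denoise()], or a [phase_series()]
#'   (then no mask is applied).
#' @return List with `peak_times` (s, strictly increasing), `rejected`
#'   times, `intervals` (the inter-peak distances usable for rate
#'   estimation: gaps between consecutive accepted peaks that neither
#'   span a rejected peak nor cross a masked window), and `quality_flag`
#'   in `ok`, `insufficient_peaks`, `all_discarded`.
#' @export
detect_peaks_adaptive <- function(denoised) {
  if (inherits(denoised, "phase_series"))
    denoised <- list(series = denoised,
                     keep = rep(TRUE, length(denoised$values)))
  series <- denoised$series
  keep <- denoised$keep
  v <- series$values
  n <- length(v)
  if (!any(keep))
    return(list(peak_times = numeric(0), rejected = numeric(0),
                intervals = numeric(0), quality_flag = "all_discarded"))
  i <- 2:(n - 1)
  is_peak <- c(FALSE, v[i] > v[i - 1] & v[i] > v[i + 1] & v[i] > 0, FALSE)
  is_peak <- is_peak & keep
  cand <- which(is_peak)
  # sub-sample refinement: parabola through the maximum and its neighbours;
  # without it, sample quantization of the inter-peak gaps (e.g. a 0.833 s
  # beat on a 0.05 s grid) biases the interval statistics
  refine <- function(k) {
    num <- v[k - 1] - v[k + 1]
    den <- v[k - 1] - 2 * v[k] + v[k + 1]
    off <- if (den == 0) 0 else 0.5 * num / den
    (k - 1 + max(-0.5, min(0.5, off))) / series$rate
  }
  if (length(cand) < 3)
    return(list(peak_times = vapply(cand, refine, numeric(1)),
                rejected = numeric(0),
                intervals = numeric(0), quality_flag = "insufficient_peaks"))
  times <- vapply(cand, refine, numeric(1))
  gaps <- diff(times)
  m <- mean(gaps)
  s <- max(sd(gaps), 1e-9)
  gap_ok <- abs(gaps - m) <= s
  # a gap is usable for rate estimation only if both endpoints are
  # accepted and no masked sample lies between them
  masked_between <- vapply(seq_along(gaps), function(j) {
    any(!keep[cand[j]:cand[j + 1]])
  }, logical(1))
  accepted_peak <- c(TRUE, gap_ok)   # peak j+1 accepted iff its preceding
                                     # gap is within the tolerance band
  valid_gap <- gap_ok & accepted_peak[seq_along(gaps)] & !masked_between
  list(peak_times = times[accepted_peak],
       rejected = times[!accepted_peak],
       intervals = gaps[valid_gap],
       quality_flag = "ok")
}

#' Estimate a rate from accepted peak times
#'
#' Rate is 60 over the mean accepted inter-peak interval. Given a
#' [detect_peaks_adaptive()] result, only its usable `intervals` enter
#' the mean, so gaps inflated by a rejected peak or a masked window do
#' not bias the estimate; given bare peak times, all successive
#' differences are used.
#'
#' @param peaks A [detect_peaks_adaptive()] result, or a strictly
#'   increasing numeric vector of peak times in seconds.
#' @return Rate in events per minute; 0 with attribute
#'   `quality_flag = "insufficient_peaks"` when fewer than 2 peaks (or no
#'   usable interval) are available.
#' @export
estimate_rate <- function(peaks) {
  intervals <- if (is.list(peaks)) peaks$intervals else {
    if (length(peaks) >= 2) stopifnot(all(diff(peaks) > 0))
    diff(peaks)
  }
  if (length(intervals) < 1) {
    out <- 0
    attr(out, "quality_flag") <- "insufficient_peaks"
    return(out)
  }
  60 / mean(intervals)
}

#' Full vitals estimation from an IF cube or phase series
#'
#' Runs the complete chain: range FFT, bin selection, phase extraction and
#' unwrapping, per-band biquad filtering, motion denoising, adaptive peak
#' detection and rate estimation.
#'
#' The motion-denoising threshold is band-specific. The cardiac band uses
#' the E_th = 0.04 rad^2 rule directly: clean heartbeat phase sits well
#' below it and random-body-movement leakage far above. The breathing band
#' carries the bulk chest displacement -- several millimeters, i.e. tens of
#' radians of phase at 77 GHz -- so a 0.04 rad^2 threshold would discard
#' every breathing window by physics alone. Its default threshold is
#' instead the mean-square phase of the largest chest displacement the
#' measurement regime assumes (5 mm), `(4*pi*0.005/lambda)^2`, flagging
#' only windows whose excursion exceeds any plausible breathing motion.
#'
#' @param x An `if_cube` or an unwrapped [phase_series()].
#' @param e_th Cardiac-band motion-denoising energy threshold (rad^2).
#' @param e_th_breathing Breathing-band threshold (rad^2); default
#'   `(4*pi*0.005/lambda)^2` (about 260 rad^2 at 77 GHz).
#' @param min_bin Smallest admissible range bin for target selection.
#' @param zero_phase Use forward-backward band filtering.
#' @return An object of class `vitals_estimate`: list with `hr_bpm`,
#'   `br_bpm`, `hr_peak_times`, `br_peak_times`, `discarded_windows`
#'   (per band), and `quality_flag`.
#' @export
estimate_vitals <- function(x, e_th = 0.04, e_th_breathing = NULL,
                            min_bin = 1, zero_phase = FALSE) {
  if (inherits(x, "if_cube")) {
    prof <- range_fft(x)
    bin <- select_range_bin(prof, min_bin = min_bin)
    ph <- extract_phase(prof, bin, rate = 1 / x$config$slow_sample_interval,
                        wavelength = x$config$wavelength)
    ph <- unwrap_phase(ph)
  } else if (inherits(x, "phase_series")) {
    ph <- x
  } else stop("x must be an if_cube or phase_series")
  if (is.null(e_th_breathing)) {
    lambda <- if (is.finite(ph$wavelength)) ph$wavelength
              else SPEED_OF_LIGHT / 77e9
    e_th_breathing <- (4 * pi * 0.005 / lambda)^2
  }
  run_band <- function(band) {
    f <- bandpass_cascade(ph, band, zero_phase = zero_phase)
    dn <- motion_denoise(f, e_th = if (band == "cardiac") e_th
                                   else e_th_breathing)
    pk <- detect_peaks_adaptive(dn)
    rate <- estimate_rate(pk)
    flag <- pk$quality_flag
    # a rate outside the band's physiological range (48-120 BPM cardiac,
    # 6-30 breaths/min) means the detected peaks are not a valid vital
    lim <- switch(band, cardiac = c(48, 120), breathing = c(6, 30))
    if (flag == "ok" && (rate < lim[1] || rate > lim[2]))
      flag <- "insufficient_peaks"
    list(bpm = as.numeric(rate), peaks = pk$peak_times,
         discarded = dn$discarded, flag = flag)
  }
  hr <- run_band("cardiac")
  br <- run_band("breathing")
  flag <- if (hr$flag == "all_discarded" && br$flag == "all_discarded")
    "all_discarded"
  else if (hr$flag != "ok" || br$flag != "ok") "insufficient_peaks"
  else "ok"
  structure(list(hr_bpm = hr$bpm, br_bpm = br$bpm,
                 hr_peak_times = hr$peaks, br_peak_times = br$peaks,
                 discarded_windows = list(cardiac = hr$discarded,
                                          breathing = br$discarded),
                 quality_flag = flag),
            class = "vitals_estimate")
}

#' @export
print.vitals_estimate <- function(x, ...) {
  cat(sprintf("<vitals_estimate: HR %.1f BPM (%d peaks), BR %.1f BPM (%d peaks), %s>\n",
              x$hr_bpm, length(x$hr_peak_times),
              x$br_bpm, length(x$br_peak_times), x$quality_flag))
  invisible(x)
}
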