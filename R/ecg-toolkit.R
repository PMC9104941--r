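#' Construct an ECG record
#'
#' @param samples Amplitudes in mV (after normalization).
#' @param rate Sampling rate in Hz.
#' @param gain Digitizer gain in adu/mV.
#' @param baseline Digitizer baseline in adu.
#' @param age,gender_code Subject metadata (years; 1 = male, 0 = female).
#' @param label `"normal"`, `"arrhythmia"` or `"unknown"`.
#' @param truth_beats Optional known R-peak times (s), for synthetic
#'   records.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, rate, gain = 200, baseline = 0,
                       age = NA_real_, gender_code = NA_integer_,
                       label = "unknown", truth_beats = NULL) {
  stopifnot(rate > 0, length(samples) >= 2 * rate,
            label %in% c("normal", "arrhythmia", "unknown"))
  if (any(abs(samples) > 10))
    warning("normalized ECG amplitudes exceed +/-10 mV; check gain/baseline")
  structure(list(samples = as.numeric(samples), rate = rate, gain = gain,
                 baseline = baseline, age = age, gender_code = gender_code,
                 label = label, truth_beats = truth_beats),
            class = "ecg_record")
}

#' Normalize raw ADC samples to millivolts
#'
#' `mv = (raw - baseline) / gain`; e.g. raw 1224 with baseline 1024 and
#' gain 200 adu/mV is 1.0 mV.
#'
#' @param raw Integer ADC samples (adu).
#' @param gain Gain in adu/mV (non-zero).
#' @param baseline Baseline in adu.
#' @return Numeric vector in mV.
#' @export
normalize_record <- function(raw, gain, baseline) {
  if (!is.numeric(gain) || length(gain) != 1 || gain == 0)
    stop("gain must be a single non-zero number")
  (as.numeric(raw) - baseline) / gain
}

#' Remove ECG artifacts
#'
#' Butterworth cascade: 4th-order low-pass at 30 Hz (muscle tremor,
#' 30-300 Hz), 4th-order band-stop 48-52 Hz (mains interference; skipped
#' with a warning when the rate cannot represent 50 Hz), and 4th-order
#' high-pass at 0.8 Hz (baseline wander).
#'
#' @param record An [ecg_record()].
#' @param zero_phase Forward-backward filtering (default TRUE: offline ECG
#'   cleaning should not skew R-peak timing).
#' @return Filtered [ecg_record()], length preserved.
#' @export
remove_artifacts <- function(record, zero_phase = TRUE) {
  stopifnot(inherits(record, "ecg_record"))
  x <- record$samples
  fs <- record$rate
  nyq <- fs / 2
  app <- function(flt, x) {
    if (zero_phase) as.numeric(signal::filtfilt(flt, x))
    else as.numeric(signal::filter(flt, x))
  }
  x <- app(signal::butter(4, 30 / nyq, type = "low"), x)
  if (fs > 2 * 52) {
    x <- app(signal::butter(4, c(48, 52) / nyq, type = "stop"), x)
  } else if (fs > 60) {
    warning("rate too low for the 48-52 Hz band-stop; stage skipped")
  }
  x <- app(signal::butter(4, 0.8 / nyq, type = "high"), x)
  out <- record
  out$samples <- x
  out
}

#' Detect R peaks
#'
#' Squared-derivative energy with moving-average smoothing and an adaptive
#' threshold at half the rolling 2 s maximum; detections closer than the
#' 0.2 s refractory interval are suppressed (largest kept). Squaring makes
#' detection robust to lead polarity.
#'
#' @param record A filtered [ecg_record()].
#' @return Strictly increasing R-peak times in seconds (possibly empty).
#' @export
detect_r_peaks <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  x <- record$samples
  fs <- record$rate
  n <- length(x)
  e <- c(0, diff(x))^2
  w <- max(1, round(0.08 * fs))            # ~QRS-width integration window
  e <- as.numeric(stats::filter(e, rep(1 / w, w), sides = 2))
  e[is.na(e)] <- 0
  # rolling 2 s maximum for the adaptive threshold
  half <- round(fs)                        # 1 s each side
  thr <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    0.5 * max(e[lo:hi])
  }, numeric(1))
  i <- 2:(n - 1)
  cand <- which(c(FALSE, e[i] > e[i - 1] & e[i] >= e[i + 1], FALSE) &
                  e > thr & thr > 0)
  if (length(cand) == 0) return(numeric(0))
  # refractory suppression: keep the larger of any pair closer than 0.2 s
  refr <- round(0.2 * fs)
  keep <- integer(0)
  for (c0 in cand) {
    if (length(keep) == 0 || c0 - keep[length(keep)] >= refr) {
      keep <- c(keep, c0)
    } else if (e[c0] > e[keep[length(keep)]]) {
      keep[length(keep)] <- c0
    }
  }
  # refine each detection to the local |x| maximum within the window
  refine <- vapply(keep, function(k) {
    lo <- max(1, k - w); hi <- min(n, k + w)
    lo + which.max(abs(x[lo:hi])) - 1
  }, numeric(1))
  sort(unique(refine - 1)) / fs
}

#' Simulate an ECG record
#'
#' Gaussian-bump morphology per beat (P, Q, R, S, T waves scaled to the
#' local RR interval), stored in raw ADC units via the supplied gain and
#' baseline so that [normalize_record()] is exercised on reading back.
#'
#' @param rr_sequence RR intervals in seconds, each in `[0.3, 2]`.
#' @param rate Sampling rate in Hz (128 and 360 are the common clinical
#'   values).
#' @param gain,baseline Digitizer constants (adu/mV, adu).
#' @param noise_sd Additive Gaussian noise SD in mV.
#' @param age,gender_code,label Metadata passed through to the record.
#' @param seed Optional seed for reproducible noise.
#' @return An [ecg_record()] (samples in mV, already normalized) with
#'   `truth_beats` set to the cumulative RR times and `raw` attribute
#'   holding the integer adu trace.
#' @export
simulate_ecg <- function(rr_sequence, rate = 128, gain = 200, baseline = 0,
                         noise_sd = 0, age = NA_real_,
                         gender_code = NA_integer_, label = "unknown",
                         seed = NULL) {
  stopifnot(all(rr_sequence >= 0.3), all(rr_sequence <= 2.0))
  if (!is.null(seed)) set.seed(as.integer(seed))
  beats <- cumsum(c(0.5, rr_sequence))   # first beat at 0.5 s
  duration <- beats[length(beats)] + 0.5
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  x <- numeric(n)
  bump <- function(center, width, amp) amp * exp(-((t - center) / width)^2)
  for (j in seq_along(beats)) {
    rr <- if (j == 1) rr_sequence[1] else rr_sequence[j - 1]
    x <- x +
      bump(beats[j] - 0.20 * rr, 0.025 * rr, 0.15) +   # P
      bump(beats[j] - 0.025,     0.010,      -0.2) +   # Q
      bump(beats[j],             0.012,      1.2) +    # R
      bump(beats[j] + 0.025,     0.010,      -0.3) +   # S
      bump(beats[j] + 0.30 * rr, 0.060 * rr, 0.3)      # T
  }
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  raw <- round(x * gain + baseline)
  mv <- normalize_record(raw, gain, baseline)
  rec <- ecg_record(mv, rate, gain, baseline, age, gender_code, label,
                    truth_beats = beats)
  attr(rec, "raw") <- as.integer(raw)
  rec
}

#' Read a WFDB record
#'
#' Minimal reader for single- or multi-signal WFDB records in format 16
#' (little-endian 16-bit) or format 212 (packed 12-bit pairs). Returns the
#' first signal, normalized to mV by its header gain and baseline.
#'
#' @param header_path Path to the `.hea` file; the `.dat` file is expected
#'   alongside it.
#' @param label Label to attach to the record.
#' @return An [ecg_record()].
#' @export
read_wfdb_record <- function(header_path, label = "unknown") {
  hdr <- readLines(header_path, warn = FALSE)
  hdr <- hdr[!grepl("^#", hdr)]
  top <- strsplit(trimws(hdr[1]), "\\s+")[[1]]
  n_sig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(top[3]) else 250
  sig <- strsplit(trimws(hdr[2]), "\\s+")[[1]]
  dat_file <- sig[1]
  fmt <- as.integer(sub("[x:+].*$", "", sig[2]))
  gain_field <- sig[3]
  gain <- as.numeric(sub("[(/].*$", "", gain_field))
  if (gain == 0 || is.na(gain)) gain <- 200
  baseline <- if (grepl("\\(", gain_field))
    as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_field)) else 0
  dat_path <- file.path(dirname(header_path), dat_file)
  raw <- readBin(dat_path, "raw", n = file.info(dat_path)$size)
  if (fmt == 16) {
    vals <- readBin(raw, "integer", n = length(raw) / 2, size = 2,
                    signed = TRUE, endian = "little")
  } else if (fmt == 212) {
    b <- as.integer(raw)
    n_tri <- floor(length(b) / 3)
    b1 <- b[seq(1, by = 3, length.out = n_tri)]
    b2 <- b[seq(2, by = 3, length.out = n_tri)]
    b3 <- b[seq(3, by = 3, length.out = n_tri)]
    s1 <- bitwAnd(b2, 15L) * 256L + b1
    s2 <- bitwAnd(bitwShiftR(b2, 4L), 15L) * 256L + b3
    s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
    s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
    vals <- as.vector(rbind(s1, s2))
  } else stop("unsupported WFDB format: ", fmt)
  chan <- vals[seq(1, length(vals), by = n_sig)]
  ecg_record(normalize_record(chan, gain, baseline), fs, gain, baseline,
             label = label)
}
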