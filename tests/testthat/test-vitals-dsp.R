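test_that("range FFT handles zero cubes, tones and Parseval per column", {
  sc <- displacement_scenario(breathing_amplitude = 0, heart_amplitude = 0)
  cube <- default_cube(sc, config = chirp_config(rx_power = 0))
  expect_true(all(range_fft(cube) == 0))
  # bin-centered complex exponential across fast time -> single dominant bin
  cfg <- chirp_config(n_chirps = 4)
  k <- 0:(cfg$n_fast - 1)
  tone <- exp(2i * pi * 7 * k / cfg$n_fast)
  cube$samples <- matrix(rep(tone, each = 4), nrow = 4)
  cube$config <- cfg
  prof <- range_fft(cube)
  mags <- Mod(prof[, 1])
  expect_identical(which.max(mags) - 1L, 7L)
  expect_gte(max(mags) / max(mags[-which.max(mags)]), 10)
  expect_equal(sum(Mod(cube$samples[1, ])^2),
               sum(Mod(fft(cube$samples[1, ]))^2) / cfg$n_fast,
               tolerance = 1e-9)
})

test_that("range-bin selection breaks ties low and respects min_bin", {
  m <- matrix(0 + 0i, nrow = 12, ncol = 3)
  m[6, ] <- 1 + 0i   # bin 5
  m[10, ] <- 1 + 0i  # bin 9
  expect_identical(select_range_bin(m, min_bin = 0), 5L)
  m2 <- matrix(0 + 0i, nrow = 12, ncol = 3)
  m2[1, ] <- 5 + 0i
  m2[4, ] <- 1 + 0i
  expect_gte(select_range_bin(m2, min_bin = 2), 2L)
  expect_error(select_range_bin(matrix(0 + 0i, 4, 2)), "no target")
})

test_that("phase extraction uses the (-pi, pi] four-quadrant convention", {
  m <- matrix(c(1 + 0i, -1 + 0i, 0 + 1i), nrow = 1)
  ph <- extract_phase(m, 0, rate = 20)
  expect_equal(ph$values, c(0, pi, pi / 2))
  m1 <- matrix(1 + 0i, nrow = 2, ncol = 5)
  expect_true(all(extract_phase(m1, 1, 20)$values == 0))
})

test_that("a 1 mm sinusoidal displacement yields 8*pi*0.001/lambda phase swing", {
  cfg <- chirp_config()
  sc <- displacement_scenario(breathing_amplitude = 1e-3, breathing_freq = 0.3,
                              heart_amplitude = 0)
  cube <- default_cube(sc)
  prof <- range_fft(cube)
  ph <- unwrap_phase(extract_phase(prof, select_range_bin(prof), 20))
  swing <- max(ph$values) - min(ph$values)
  expect_equal(swing, 8 * pi * 0.001 / cfg$wavelength, tolerance = 0.01)
})

test_that("phase unwrapping recovers ramps and is a modular identity", {
  ramp <- seq(0, 10, length.out = 100)
  wrapped <- phase_series(radarvitals:::wrap_phase(ramp), 20)
  un <- unwrap_phase(wrapped)
  expect_equal(diff(un$values), diff(ramp), tolerance = 1e-12)
  const <- phase_series(rep(1.2, 50), 20)
  expect_equal(unwrap_phase(const)$values, rep(1.2, 50))
  x <- phase_series(rnorm(200, sd = 2), 20)
  expect_equal(radarvitals:::wrap_phase(unwrap_phase(x)$values),
               radarvitals:::wrap_phase(x$values), tolerance = 1e-12)
})

test_that("band-pass cascade separates cardiac from breathing content", {
  t <- (0:511) / 20
  tone <- phase_series(sin(2 * pi * 1.3 * t), 20)
  card <- bandpass_cascade(tone, "cardiac")
  expect_length(card$values, 512)
  expect_gte(sqrt(mean(card$values^2)), 0.6 * sqrt(mean(tone$values^2)))
  brth <- bandpass_cascade(tone, "breathing")
  expect_lte(sqrt(mean(brth$values^2)), 0.1 * sqrt(mean(tone$values^2)))
  zero <- phase_series(c(0, numeric(511)), 20)
  expect_true(all(abs(bandpass_cascade(zero, "cardiac")$values) < 1e-12))
})

test_that("cascade meets pass-band and stop-band specifications", {
  for (band in list(c(0.8, 2, 7), c(0.1, 0.5, 3))) {
    casc <- design_biquad_cascade(band[1], band[2], 20, band[3])
    centre <- sqrt(band[1] * band[2])
    g <- radarvitals:::biquad_cascade_gain(casc, centre)
    expect_gte(20 * log10(g), -3)
    expect_lte(20 * log10(g), 0.5)
    g_out <- radarvitals:::biquad_cascade_gain(casc,
                                               c(band[1] / 2, band[2] * 2))
    expect_true(all(20 * log10(g_out) <= -20))
  }
})

test_that("cascade response matches the direct transfer function", {
  # factored biquads must reproduce the single-section design exactly
  set.seed(1)
  x <- rnorm(400)
  casc <- design_biquad_cascade(0.8, 2, 20, 2)
  y1 <- apply_biquad_cascade(casc, x)
  flt <- signal::butter(2, c(0.8, 2) / 10, type = "pass")
  y2 <- as.numeric(signal::filter(flt, x))
  expect_equal(y1, y2, tolerance = 1e-9)
})

test_that("motion denoising applies the windowed energy rule exactly", {
  zero <- phase_series(numeric(100), 20)
  expect_identical(nrow(motion_denoise(zero)$discarded), 0L)
  # one window held at 0.25 rad: energy 0.0625 > 0.04 -> discarded
  v <- numeric(100)
  v[41:60] <- 0.25
  dn <- motion_denoise(phase_series(v, 20))
  expect_equal(dn$window_energy[3], 0.0625)
  expect_equal(dn$discarded$start, 2)
  expect_equal(dn$discarded$end, 3)
  expect_identical(sum(!dn$keep), 20L)
  # 0.2 rad sinusoid: energy 0.02 < 0.04 -> nothing discarded
  t <- (0:99) / 20
  s <- phase_series(0.2 * sin(2 * pi * 1.25 * t), 20)
  expect_identical(nrow(motion_denoise(s)$discarded), 0L)
})

test_that("adaptive peak filter keeps regular trains and drops outliers", {
  rate <- 20
  train <- numeric(510)
  train[seq(6, 510, by = rate)] <- 1   # exact 1 Hz impulses from t = 0.25 s
  pk <- detect_peaks_adaptive(phase_series(train, rate))
  expect_length(pk$peak_times, 26)
  expect_length(pk$rejected, 0)
  expect_true(all(abs(diff(pk$peak_times) - 1) < 1e-9))
  # add a spurious peak 0.15 s after a true peak
  spur <- 6 + 10 * rate + 3
  train2 <- train
  train2[spur] <- 0.5
  spur_t <- (spur - 1) / rate
  pk2 <- detect_peaks_adaptive(phase_series(train2, rate))
  expect_true(any(abs(pk2$rejected - spur_t) < 0.05))
  expect_false(any(abs(pk2$peak_times - spur_t) < 0.04))
  # all-negative series has no positive local maxima
  neg <- phase_series(-1 - abs(rnorm(100)), 20)
  expect_identical(detect_peaks_adaptive(neg)$quality_flag,
                   "insufficient_peaks")
})

test_that("rate estimation is 60 over the mean inter-peak interval", {
  expect_equal(estimate_rate(0:25), 60)
  expect_equal(estimate_rate(seq(0, 24, by = 0.75)), 80)
  short <- estimate_rate(c(1))
  expect_equal(as.numeric(short), 0)
  expect_identical(attr(short, "quality_flag"), "insufficient_peaks")
})

test_that("noise-free scenarios are recovered within 2 BPM HR and 1 BPM BR", {
  for (hf in c(0.9, 1.2, 1.8)) for (bf in c(0.15, 0.45)) {
    r <- run_vitals_demo(displacement_scenario(heart_freq = hf,
                                               breathing_freq = bf),
                         seed = 1)
    expect_lte(abs(r$hr_error_bpm), 2)
    expect_lte(abs(r$br_error_bpm), 1)
    expect_identical(r$estimate$quality_flag, "ok")
  }
})

test_that("no accepted peak falls inside a discarded window", {
  sc <- displacement_scenario(rbm_events = list(c(8, 1, 0.01),
                                                c(17, 1.5, 0.02)))
  cube <- default_cube(sc)
  est <- estimate_vitals(cube)
  for (band in c("cardiac", "breathing")) {
    disc <- est$discarded_windows[[band]]
    pks <- if (band == "cardiac") est$hr_peak_times else est$br_peak_times
    if (nrow(disc) > 0 && length(pks) > 0)
      for (i in seq_len(nrow(disc)))
        expect_false(any(pks >= disc$start[i] & pks < disc$end[i]))
  }
})

test_that("HR error degrades monotonically with IF noise", {
  noise_levels <- c(0, 0.1, 0.3)
  med_err <- vapply(noise_levels, function(ns) {
    median(vapply(1:20, function(s) {
      abs(run_vitals_demo(displacement_scenario(), noise_sd = ns,
                          seed = s)$hr_error_bpm)
    }, numeric(1)))
  }, numeric(1))
  expect_gte(cor(noise_levels, med_err, method = "spearman"), 0)
})
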