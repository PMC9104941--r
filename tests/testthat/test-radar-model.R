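test_that("chest displacement spectrum is dominated by the breathing line", {
  sc <- displacement_scenario(breathing_amplitude = 4e-3, breathing_freq = 0.3,
                              heart_amplitude = 3e-4, heart_freq = 1.2,
                              base_range = 0.5, duration = 25.6)
  r <- simulate_chest_displacement(sc, rate = 20)
  expect_length(r, 512)
  sp <- Mod(fft(r - mean(r)))[2:256]
  freqs <- (1:255) * 20 / 512
  expect_identical(which.max(sp), which.min(abs(freqs - 0.3)))
})

test_that("zero-amplitude scenario gives a constant range series", {
  sc <- displacement_scenario(breathing_amplitude = 0, heart_amplitude = 0,
                              base_range = 0.7)
  r <- simulate_chest_displacement(sc, 20)
  expect_true(all(r == 0.7))
})

test_that("an RBM burst perturbs only its own time window", {
  sc <- displacement_scenario(breathing_amplitude = 0, heart_amplitude = 0,
                              rbm_events = list(c(10, 1, 0.01)))
  r <- simulate_chest_displacement(sc, 20)
  t <- (seq_along(r) - 1) / 20
  inside <- t >= 10 & t < 11
  expect_true(all(r[!inside] == sc$base_range))
  expect_true(any(r[inside] != sc$base_range))
  expect_equal(max(r), sc$base_range + 0.01, tolerance = 1e-6)
})

test_that("displacement sampling preconditions are enforced", {
  sc <- displacement_scenario()
  expect_error(simulate_chest_displacement(sc, -1), "positive")
  expect_error(simulate_chest_displacement(
    displacement_scenario(heart_freq = 11), 20), "aliasing|Nyquist")
})

test_that("chirp config derives the wavelength and validates timing", {
  cfg <- chirp_config()
  expect_equal(cfg$wavelength, 299792458 / 77e9, tolerance = 1e-12)
  expect_error(chirp_config(slow_sample_interval = 1e-6), "slow_sample")
  expect_error(chirp_config(n_fast = 1000, fast_sample_interval = 1e-6),
               "chirp duration")
})

test_that("IF cube places a static target in the correct range bin", {
  sc <- displacement_scenario(breathing_amplitude = 0, heart_amplitude = 0,
                              base_range = 0.5)
  cube <- default_cube(sc)
  expect_equal(dim(cube$samples), c(512, 100))
  expect_equal(range_bin_size(cube$config), 0.0375, tolerance = 1e-3)
  prof <- range_fft(cube)
  expect_identical(select_range_bin(prof), 13L)
})

test_that("zero received power gives an all-zero cube", {
  sc <- displacement_scenario(breathing_amplitude = 0, heart_amplitude = 0)
  d <- simulate_chest_displacement(sc, 20)
  cube <- synthesize_if_cube(d, chirp_config(rx_power = 0))
  expect_true(all(cube$samples == 0))
})

test_that("a 1 mm range step advances slow-time phase by 4*pi*d/lambda", {
  cfg <- chirp_config()
  sc <- displacement_scenario(breathing_amplitude = 0, heart_amplitude = 0)
  d1 <- simulate_chest_displacement(sc, 20)
  d2 <- d1 + c(0, rep(0.001, length(d1) - 1))
  p1 <- extract_phase(range_fft(synthesize_if_cube(d1, cfg)), 13, 20)
  p2 <- extract_phase(range_fft(synthesize_if_cube(d2, cfg)), 13, 20)
  dphi <- (p2$values[2] - p1$values[2]) %% (2 * pi)
  expect_equal(dphi, (4 * pi * 0.001 / cfg$wavelength) %% (2 * pi),
               tolerance = 1e-6)
})

test_that("slow-time phase at the target bin is linear in displacement", {
  # phase at the selected bin must equal 4*pi*R(t)/lambda up to a constant
  cfg <- chirp_config()
  sc <- displacement_scenario(heart_amplitude = 0, breathing_amplitude = 2e-3)
  d <- simulate_chest_displacement(sc, 20)
  cube <- synthesize_if_cube(d, cfg)
  prof <- range_fft(cube)
  ph <- unwrap_phase(extract_phase(prof, select_range_bin(prof), 20))
  expected <- 4 * pi * as.numeric(d) / cfg$wavelength
  centred <- ph$values - mean(ph$values)
  expect_equal(centred, expected - mean(expected), tolerance = 1e-9)
})

test_that("each chirp satisfies Parseval and cubes are seed-deterministic", {
  cube <- default_cube(displacement_scenario(), noise_sd = 0.1, seed = 9)
  row <- cube$samples[1, ]
  expect_equal(sum(Mod(row)^2), sum(Mod(fft(row))^2) / length(row),
               tolerance = 1e-9)
  cube2 <- default_cube(displacement_scenario(), noise_sd = 0.1, seed = 9)
  expect_identical(cube$samples, cube2$samples)
})

test_that("short displacement series is rejected", {
  expect_error(synthesize_if_cube(rep(0.5, 10), chirp_config()), "shorter")
})

test_that("RR cohort honours the class mix exactly and reproducibly", {
  co <- simulate_rr_cohort(10, 0.5, seed = 1)
  labels <- vapply(co, `[[`, "", "label")
  expect_identical(sum(labels == "arrhythmia"), 5L)
  co2 <- simulate_rr_cohort(10, 0.5, seed = 7)
  co3 <- simulate_rr_cohort(10, 0.5, seed = 7)
  expect_identical(co2, co3)
})

test_that("arrhythmic subjects have higher RR variability than normal", {
  co <- simulate_rr_cohort(200, 0.5, seed = 2)
  cov_of <- function(s) sd(s$rr) / mean(s$rr)
  covs <- vapply(co, cov_of, numeric(1))
  arr <- vapply(co, `[[`, "", "label") == "arrhythmia"
  expect_gt(mean(covs[arr]), mean(covs[!arr]))
  expect_lte(mean(covs[!arr]), 0.05)
  expect_gte(mean(covs[arr]), 0.15)
})
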