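test_that("amplitude statistics match sinusoid closed forms", {
  x <- sine_signal(32, 1000, 1)    # whole periods
  s <- amplitude_stats(x)
  expect_equal(s$peak_factor, sqrt(2), tolerance = 0.01)
  expect_equal(s$form_factor, pi / (2 * sqrt(2)), tolerance = 0.01)
  expect_equal(s$pulse_factor, pi / 2, tolerance = 0.01)
  expect_equal(s$kurtosis, 1.5, tolerance = 0.01)
  expect_equal(s$max_amplitude, 1, tolerance = 1e-3)
})

test_that("a unit impulse gives the hand-computed factor values", {
  s <- amplitude_stats(c(0, 0, 1, 0, 0))   # RMS = 1/sqrt(5), mean|x| = 1/5
  expect_equal(s$pulse_factor, 5, tolerance = 1e-12)
  expect_equal(s$peak_factor, sqrt(5), tolerance = 1e-12)
  expect_equal(s$form_factor, sqrt(5), tolerance = 1e-12)
})

test_that("amplitude scaling moves only max_amplitude", {
  set.seed(3)
  x <- rnorm(500)
  s1 <- amplitude_stats(x)
  s2 <- amplitude_stats(x * 3.7)
  expect_equal(s2$max_amplitude, 3.7 * s1$max_amplitude)
  for (f in c("kurtosis", "peak_factor", "pulse_factor", "form_factor"))
    expect_equal(s2[[f]], s1[[f]], tolerance = 1e-12)
  expect_error(amplitude_stats(numeric(0)), "empty")
  expect_error(amplitude_stats(numeric(10)), "zero-energy")
})

test_that("envelope moments match the weighted-moment oracle", {
  win <- list(start = 0L, end = 4000L)
  # symmetric beats about the midpoint: both moments vanish
  sym <- data.frame(peak_time_s = c(1, 2, 3), peak_amp = c(1, 2, 1))
  m <- envelope_moments(sym, win, 1000)
  expect_equal(m$center_of_mass, 0, tolerance = 1e-12)
  expect_equal(m$skewness, 0, tolerance = 1e-12)

  # hand-computed: w = (0.6, 0.2, 0.2), mu = 1.6, m2 = 0.64, m3 = 0.432
  toy <- data.frame(peak_time_s = c(1, 2, 3), peak_amp = c(3, 1, 1))
  m <- envelope_moments(toy, win, 1000)
  expect_equal(m$center_of_mass, -0.4, tolerance = 1e-12)
  expect_equal(m$skewness, 0.432 / 0.64^1.5, tolerance = 1e-12)

  # time reversal inside the window negates both outputs
  rev_toy <- data.frame(peak_time_s = 4 - c(3, 2, 1), peak_amp = c(1, 1, 3))
  mr <- envelope_moments(rev_toy, win, 1000)
  expect_equal(mr$center_of_mass, -m$center_of_mass, tolerance = 1e-12)
  expect_equal(mr$skewness, -m$skewness, tolerance = 1e-12)

  expect_error(envelope_moments(toy[1:2, ], win, 1000), "fewer than 3")
  zero <- data.frame(peak_time_s = 1:3, peak_amp = c(0, 0, 0))
  expect_error(envelope_moments(zero, win, 1000), "all-zero")
})

test_that("envelope moments agree with brute-force enumeration", {
  win <- list(start = 0L, end = 10000L)
  brute <- function(t, A) {
    w <- A / sum(A)
    mu <- sum(w * t)
    list(cm = mu - 5, sk = sum(w * (t - mu)^3) / sum(w * (t - mu)^2)^1.5)
  }
  set.seed(9)
  for (i in 1:20) {
    k <- sample(3:10, 1)
    t <- sort(runif(k, 0.2, 9.8))
    A <- runif(k, 0.1, 2)
    m <- envelope_moments(data.frame(peak_time_s = t, peak_amp = A), win, 1000)
    b <- brute(t, A)
    expect_equal(m$center_of_mass, b$cm, tolerance = 1e-12)
    expect_equal(m$skewness, b$sk, tolerance = 1e-12)
  }
})

test_that("spectral moments localize single and double tones", {
  fs <- 1000
  x <- sine_signal(32, fs, 10)
  sp <- spectral_features(x, fs)
  df <- 1                       # 1-s segments: 1 Hz bins
  expect_lte(abs(sp$peak_frequency - 32), df)
  expect_lte(abs(sp$centroid_frequency - 32), df)
  expect_lte(abs(sp$mean_square_frequency - 32^2), 2 * 32 * df + df^2)

  two <- sine_signal(20, fs, 10) + sine_signal(40, fs, 10)
  sp2 <- spectral_features(two, fs)
  expect_lte(abs(sp2$centroid_frequency - 30), df)
  expect_equal(sp2$mean_square_frequency, (20^2 + 40^2) / 2,
               tolerance = 0.05)

  sp3 <- spectral_features(two * 0.01, fs)
  for (f in names(sp2)) expect_equal(sp3[[f]], sp2[[f]], tolerance = 1e-9)
  expect_error(spectral_features(numeric(100), fs), "zero-energy")
})

test_that("feature identities hold on random synthetic recordings", {
  set.seed(14)
  for (i in 1:15) {
    x <- rnorm(600) * (0.2 + runif(1)) + burst_train(c(0.15, 0.35), dur = 0.6)
    s <- amplitude_stats(x)
    expect_equal(s$pulse_factor, s$peak_factor * s$form_factor,
                 tolerance = 1e-12)
    sp <- spectral_features(x, 1000, nperseg = 256)
    expect_gte(sp$mean_square_frequency, sp$centroid_frequency^2 - 1e-9)
  }
})

test_that("full extraction is deterministic and orders the presets", {
  gen <- generate_recording(ground_truth_params(seed = 12))
  f1 <- extract_features(gen$recording)
  f2 <- extract_features(gen$recording)
  expect_identical(f1, f2)
  expect_named(f1, c("subject_id", feature_names(), "n_beats"),
               ignore.order = TRUE)

  # directionality at the single-recording level, averaged over seeds
  fy <- extract_features_cohort(
    generate_cohort(cohort_preset("young"), 8, seed = 61)$recordings)
  fo <- extract_features_cohort(
    generate_cohort(cohort_preset("older"), 8, seed = 62)$recordings)
  expect_gt(mean(fy$center_of_mass), 0)
  expect_lt(mean(fo$center_of_mass), 0)
  expect_gt(mean(fy$peak_frequency), mean(fo$peak_frequency))
})

test_that("extraction failures carry the stage label", {
  silent <- koro_recording(numeric(3000) + 1e-9, fs = 1000)
  expect_error(extract_features(silent), "detect_window")
  expect_error(feature_config(wavelet = "sym9"), "unknown wavelet")
  cfg <- feature_config()
  cfg$wavelet <- "sym9"     # bypass construction-time validation
  gen <- generate_recording(ground_truth_params(seed = 2))
  expect_error(extract_features(gen$recording, cfg), "wavelet_denoise")
})
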