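test_that("identical seeds give bitwise-identical recordings and cohorts", {
  g1 <- generate_recording(ground_truth_params(seed = 9))
  g2 <- generate_recording(ground_truth_params(seed = 9))
  expect_identical(g1$recording$sound, g2$recording$sound)
  expect_identical(g1$beat_times, g2$beat_times)

  c1 <- generate_cohort(cohort_preset("hospital"), 5, seed = 21)
  c2 <- generate_cohort(cohort_preset("hospital"), 5, seed = 21)
  expect_identical(vapply(c1$subjects, `[[`, 0, "bapwv"),
                   vapply(c2$subjects, `[[`, 0, "bapwv"))
  expect_identical(c1$recordings[[3]]$sound, c2$recordings[[3]]$sound)
  c3 <- generate_cohort(cohort_preset("hospital"), 5, seed = 22)
  expect_false(identical(c1$recordings[[3]]$sound, c3$recordings[[3]]$sound))
})

test_that("beats are confined to the open pressure window", {
  for (s in 1:5) {
    gen <- generate_recording(ground_truth_params(seed = s,
                                                  heart_rate = 60 + 10 * s))
    p_at <- gen$recording$cuff_pressure[round(gen$beat_times * 1000) + 1]
    expect_true(all(p_at < gen$params$sbp & p_at > gen$params$dbp))
  }
})

test_that("beat count matches the heart-rate/window enumeration", {
  # 20-s window at 60 bpm: floor(20 * 60/60) beats, plus/minus the boundary
  gen <- generate_recording(ground_truth_params(
    sbp = 120, dbp = 60, deflation_rate = 3, heart_rate = 60, seed = 2))
  win_s <- (gen$window$end - gen$window$start) / 1000
  expect_equal(win_s, 20, tolerance = 1e-3)
  expect_lte(abs(length(gen$beat_times) - floor(win_s * 60 / 60)), 1)
  # brute-force enumeration: emitted beats are exactly the jittered onsets
  # that fall strictly inside the window
  expect_true(all(diff(gen$beat_times) > 0))
})

test_that("noise-free and drift-free records are silent outside the window", {
  gen <- generate_recording(ground_truth_params(noise_sd = 0, drift_amp = 0,
                                                seed = 3))
  margin <- round(4 * gen$params$beat_decay * 1000)
  pre <- gen$recording$sound[seq_len(gen$window$start - margin)]
  post_start <- gen$window$end + margin
  post <- gen$recording$sound[post_start:length(gen$recording$sound)]
  expect_identical(max(abs(pre)), 0)
  expect_identical(max(abs(post)), 0)
})

test_that("infeasible parameter combinations error", {
  expect_error(ground_truth_params(sbp = 100, dbp = 110), "sbp")
  expect_error(generate_recording(ground_truth_params(heart_rate = 2)),
               "shorter than one beat interval")
  expect_error(generate_recording(ground_truth_params(beat_center_freq = 600)),
               "fs/2")
  expect_error(generate_recording(ground_truth_params(), duration = 5),
               "too short")
  expect_error(cohort_preset("nursing_home"), "arg")
})

test_that("envelope_skew monotonically controls extracted skewness", {
  grid <- c(-0.9, -0.45, 0, 0.45, 0.9)
  mean_skew <- vapply(grid, function(s) {
    vals <- vapply(1:3, function(k) {
      gen <- generate_recording(ground_truth_params(
        envelope_skew = s, noise_sd = 0, drift_amp = 0, seed = 100 + k))
      extract_features(gen$recording)$skewness
    }, 0)
    mean(vals)
  }, 0)
  expect_true(all(diff(mean_skew) > 0))
})

test_that("young preset reproduces the target age distribution", {
  co <- generate_cohort(cohort_preset("young"), 40, seed = 5)
  ages <- vapply(co$subjects, `[[`, 0, "age")
  expect_lt(abs(mean(ages) - 25.9), 3 * 2.2 / sqrt(40))
  expect_true(all(ages >= 20 & ages <= 30))
})

test_that("hospital covariate model recovers its coefficients at n = 500", {
  co <- generate_cohort(cohort_preset("hospital"), 500, seed = 17)
  d <- cohort_to_df(co$subjects)
  d$z <- vapply(co$ground_truth, `[[`, 0, "latent_stiffness")
  fit <- lm(bapwv ~ age + sbp + bmi + diabetes + z, data = d)
  truth <- c(age = 10, sbp = 5, bmi = 5, diabetes = 80, z = 100)
  est <- coef(summary(fit))
  for (nm in names(truth))
    expect_lt(abs(est[nm, "Estimate"] - truth[[nm]]),
              3 * est[nm, "Std. Error"])
})

test_that("zero stiffness coupling leaves no partial baPWV association", {
  preset <- cohort_preset("hospital")
  preset$bapwv_model["g"] <- 0
  co <- generate_cohort(preset, 200, seed = 31)
  d <- cohort_to_df(co$subjects)
  d$z <- vapply(co$ground_truth, `[[`, 0, "latent_stiffness")
  r_bapwv <- resid(lm(bapwv ~ age + sbp + bmi + diabetes, data = d))
  r_z <- resid(lm(z ~ age + sbp + bmi + diabetes, data = d))
  expect_lt(abs(cor(r_bapwv, r_z)), 0.15)
})

test_that("preset calibration flags swapped presets", {
  swapped <- calibrate_presets(list(cohort_preset("older"),
                                    cohort_preset("young")),
                               n_per_group = 15, seed = 2)
  expect_false(swapped$ok)
  expect_false(any(swapped$checks[c("center_of_mass_signs",
                                    "skewness_signs")]))
})

test_that("matched envelope skew yields no spurious skewness difference", {
  # null simulation: both presets get the older group's envelope shape
  hits <- vapply(1:6, function(s) {
    py <- cohort_preset("young"); po <- cohort_preset("older")
    py$envelope_skew <- po$envelope_skew
    py$envelope_peak_pos <- po$envelope_peak_pos
    fy <- extract_features_cohort(
      generate_cohort(py, 12, seed = 400 + s)$recordings)
    fo <- extract_features_cohort(
      generate_cohort(po, 12, seed = 500 + s)$recordings)
    res <- compare_groups(data.frame(skewness = c(fy$skewness, fo$skewness)),
                          rep(c("y", "o"), c(nrow(fy), nrow(fo))),
                          family_alpha = 0.05)
    res$p < 0.005
  }, TRUE)
  expect_lte(sum(hits), 1)
})
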