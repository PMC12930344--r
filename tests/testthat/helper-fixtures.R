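# Shared fixtures, all generated in code.

# one-second-resolution unit sine sampled at fs, whole periods
sine_signal <- function(f0 = 32, fs = 1000, dur = 1) {
  sin(2 * pi * f0 * seq_len(round(dur * fs)) / fs)
}

sine_recording <- function(f0 = 32, fs = 1000, dur = 2, id = "sine") {
  koro_recording(sine_signal(f0, fs, dur), fs = fs, subject_id = id)
}

# a hand-built beat train: equal-amplitude Gaussian bursts at known times
burst_train <- function(times_s, amps = rep(1, length(times_s)), fs = 1000,
                        dur = max(times_s) + 1, f0 = 35, sigma = 0.02) {
  n <- round(dur * fs)
  x <- numeric(n)
  for (i in seq_along(times_s)) {
    c_idx <- round(times_s[i] * fs) + 1L
    idx <- max(1L, c_idx - 100L):min(n, c_idx + 100L)
    tt <- (idx - c_idx) / fs
    x[idx] <- x[idx] + amps[i] * exp(-tt^2 / (2 * sigma^2)) *
      sin(2 * pi * f0 * tt)
  }
  x
}

# Jaccard overlap of two half-open windows
window_jaccard <- function(w1, w2) {
  inter <- max(0, min(w1$end, w2$end) - max(w1$start, w2$start))
  inter / (max(w1$end, w2$end) - min(w1$start, w2$start))
}

# small cohort CSV written to a temp file
write_toy_cohort <- function(path, rows = NULL) {
  if (is.null(rows))
    rows <- data.frame(
      subject_id = c("s1", "s2", "s3"), age = c(25, 67, 44),
      sex = c("male", "female", "male"), bmi = c(22.5, 23.1, 26.0),
      sbp = c(118, 121, 135), dbp = c(76, 80, 82),
      heart_rate = c(72, 80, 75), diabetes = c("no", "yes", "0"),
      smoking = c(0, 0, 1), group_label = c("young", "older", "none"),
      bapwv = c(NA, NA, 1625))
  write.csv(rows, path, row.names = FALSE, na = "")
  path
}

# tone "recordings" with disjoint spectral bands for classifier tests
tone_class_recordings <- function(n_per_class = 20, f_low = 15, f_high = 60,
                                  seed = 42) {
  set.seed(seed)
  mk <- function(f0, id) {
    t <- seq(0, 3, 1e-3)
    x <- sin(2 * pi * (f0 + rnorm(1, 0, 2)) * t) *
      (0.5 + 0.5 * sin(2 * pi * 1.2 * t)) + rnorm(length(t), 0, 0.2)
    koro_recording(x, fs = 1000, subject_id = id)
  }
  recs <- c(lapply(seq_len(n_per_class), function(i) mk(f_low, paste0("lo", i))),
            lapply(seq_len(n_per_class), function(i) mk(f_high, paste0("hi", i))))
  list(recordings = recs, labels = rep(0:1, each = n_per_class))
}
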