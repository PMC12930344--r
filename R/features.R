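# The ten-feature acoustic characterisation of one recording: six
# time-domain features (maximum amplitude, kurtosis, envelope temporal
# skewness, peak/pulse/form factors), the amplitude-weighted temporal
# centre of mass, and three spectral moments (peak, centroid and
# mean-square frequency). Definitions are the standard vibration-analysis
# ones, frozen here in one place:
#   peak_factor  = max|x| / RMS          (crest factor)
#   pulse_factor = max|x| / mean|x|      (impulse factor)
#   form_factor  = RMS / mean|x|
#   kurtosis     = fourth standardized central moment (non-excess)
#   center_of_mass, skewness: amplitude-weighted temporal moments of the
#     beat-peak train (weights = beat peak amplitudes), centre of mass in
#     seconds relative to the window midpoint, skewness standardized; mass
#     early in the window gives positive skewness.
#   spectral moments on the Welch PSD P(f) of the concatenated beat
#     segments: argmax, sum(f P)/sum(P), sum(f^2 P)/sum(P).

#' Names of the ten acoustic features, in canonical order
#' @return character vector of length 10.
#' @export
feature_names <- function() {
  c("max_amplitude", "kurtosis", "skewness", "peak_factor", "pulse_factor",
    "form_factor", "center_of_mass", "peak_frequency", "centroid_frequency",
    "mean_square_frequency")
}

#' Extraction configuration
#'
#' One home for every tunable of the preprocessing + feature chain.
#'
#' @param baseline_cutoff high-pass cutoff (Hz).
#' @param wavelet,denoise_level,denoise_rule wavelet-denoise settings
#'   (see [wavelet_denoise()]).
#' @param envelope_smooth envelope moving-average length (s).
#' @param beat_threshold adaptive beat threshold as a fraction of the
#'   window envelope maximum.
#' @param window_threshold excursion threshold used by window detection.
#' @param min_separation minimum beat separation (s).
#' @param psd_seg Welch PSD segment length (s).
#' @param window_mode window source passed to [detect_window()].
#' @return list of class `koro_config`.
#' @export
feature_config <- function(baseline_cutoff = 5, wavelet = "db6",
                           denoise_level = 4L,
                           denoise_rule = "universal-soft",
                           envelope_smooth = 0.05, beat_threshold = 0.2,
                           window_threshold = 0.08, min_separation = 0.35,
                           psd_seg = 1.0, window_mode = "auto") {
  if (!wavelet %in% c("haar", "db4", "db6"))
    stop("unknown wavelet: ", wavelet)
  if (denoise_level < 1L) stop("denoise_level must be >= 1")
  if (!(beat_threshold > 0 && beat_threshold < 1))
    stop("beat_threshold must lie in (0, 1)")
  structure(as.list(environment()), class = "koro_config")
}

#' Time-domain amplitude statistics of a windowed signal
#'
#' @param x numeric signal (the samples inside the analysis window).
#' @return named list: `max_amplitude`, `kurtosis`, `peak_factor`,
#'   `pulse_factor`, `form_factor`.
#' @examples
#' s <- amplitude_stats(sin(2 * pi * seq(0, 1, by = 1e-3)[-1]))
#' all.equal(s$peak_factor, sqrt(2), tolerance = 1e-5)
#' @export
amplitude_stats <- function(x) {
  if (!length(x)) stop("empty window")
  rms <- sqrt(mean(x^2))
  mabs <- mean(abs(x))
  if (rms == 0 || mabs == 0) stop("zero-energy window: factors undefined")
  m <- mean(x)
  v <- mean((x - m)^2)
  list(max_amplitude = max(abs(x)),
       kurtosis = mean((x - m)^4) / v^2,
       peak_factor = max(abs(x)) / rms,
       pulse_factor = max(abs(x)) / mabs,
       form_factor = rms / mabs)
}

#' Amplitude-weighted temporal moments of the beat train
#'
#' With weights `w_i = A_i / sum(A)` over beat peak times `t_i`:
#' centre of mass `= sum(w t) - t_mid` (seconds from the window midpoint,
#' positive = amplitude mass late in the window) and weighted skewness
#' `sum(w (t - mu)^3) / (sum(w (t - mu)^2))^{3/2}` (positive = mass early,
#' tail late).
#'
#' @param beats beat table from [segment_beats()] (needs `peak_time_s`,
#'   `peak_amp`), or a list/data.frame with those fields.
#' @param window 0-based half-open sample window.
#' @param fs sampling rate (Hz).
#' @return named list: `center_of_mass` (s), `skewness`.
#' @export
envelope_moments <- function(beats, window, fs) {
  if (nrow(as.data.frame(beats)) < 3L) stop("fewer than 3 beats")
  t_i <- beats$peak_time_s
  A <- beats$peak_amp
  if (any(A < 0)) stop("beat amplitudes must be magnitudes (>= 0)")
  if (sum(A) <= 0) stop("all-zero amplitudes")
  w <- A / sum(A)
  t_mid <- (window$start + window$end) / 2 / fs
  mu <- sum(w * t_i)
  m2 <- sum(w * (t_i - mu)^2)
  m3 <- sum(w * (t_i - mu)^3)
  list(center_of_mass = mu - t_mid,
       skewness = if (m2 > 0) m3 / m2^1.5 else 0)
}

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

#' Welch averaged-periodogram power spectral density
#'
#' Hann-tapered segments with 50% overlap, one-sided.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param nperseg segment length in samples (shrunk to `length(x)` when
#'   the signal is shorter).
#' @return list with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, nperseg = fs) {
  n <- length(x)
  if (n < 8L) stop("signal too short for spectral estimation")
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg / 2))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  win <- .hann(nperseg)
  scale <- sum(win^2) * fs
  nf <- floor(nperseg / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)] * win
    sp <- Mod(fft(seg)[seq_len(nf)])^2 / scale
    sp[2:(nf - 1L)] <- 2 * sp[2:(nf - 1L)]
    acc <- acc + sp
  }
  list(freq = (seq_len(nf) - 1L) * fs / nperseg, psd = acc / length(starts))
}

#' Spectral moments of a windowed signal
#'
#' Peak, centroid (power-weighted mean) and mean-square (power-weighted
#' mean of squared) frequency of the Welch PSD. All three are invariant to
#' amplitude scaling; mean-square frequency is reported in Hz^2 and always
#' satisfies `msf >= centroid^2` (Jensen).
#'
#' @param x numeric signal (concatenated beat segments, typically).
#' @param fs sampling rate (Hz).
#' @param nperseg Welch segment length (samples).
#' @return named list: `peak_frequency`, `centroid_frequency` (Hz),
#'   `mean_square_frequency` (Hz^2).
#' @export
spectral_features <- function(x, fs, nperseg = fs) {
  if (sqrt(mean(x^2)) == 0) stop("zero-energy input")
  ps <- welch_psd(x, fs, nperseg)
  tot <- sum(ps$psd)
  list(peak_frequency = ps$freq[which.max(ps$psd)],
       centroid_frequency = sum(ps$freq * ps$psd) / tot,
       mean_square_frequency = sum(ps$freq^2 * ps$psd) / tot)
}

#' Extract the ten-feature vector of one recording
#'
#' Orchestrates the full chain: baseline removal, wavelet denoising,
#' Korotkoff-window location, beat segmentation, then the time-domain
#' statistics and spectral moments on the concatenated beat segments and
#' the amplitude-weighted temporal moments on the beat train. The result
#' is deterministic given the recording and configuration. Stage failures
#' are re-raised with the stage name.
#'
#' @param rec a [koro_recording()].
#' @param config a [feature_config()].
#' @return one-row data.frame with `subject_id` plus the ten
#'   [feature_names()] columns, plus `n_beats`.
#' @export
extract_features <- function(rec, config = feature_config()) {
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop(name, ": ", conditionMessage(e), call. = FALSE))
  x <- stage("remove_baseline",
             remove_baseline(rec$sound, rec$fs, config$baseline_cutoff))
  x <- stage("wavelet_denoise",
             wavelet_denoise(x, config$wavelet, config$denoise_level,
                             config$denoise_rule))
  win <- stage("detect_window",
               detect_window(rec, config, mode = config$window_mode))
  beats <- stage("segment_beats",
                 segment_beats(x, win, rec$fs, config, rec$cuff_pressure))
  if (nrow(beats) < 3L)
    stop("segment_beats: fewer than 3 beats detected", call. = FALSE)
  seg_idx <- unlist(lapply(seq_len(nrow(beats)), function(i)
    (beats$onset[i] + 1L):beats$end[i]))
  xa <- x[seg_idx]
  amp <- stage("amplitude_stats", amplitude_stats(xa))
  env <- stage("envelope_moments", envelope_moments(beats, win, rec$fs))
  spec <- stage("spectral_features",
                spectral_features(xa, rec$fs,
                                  nperseg = round(config$psd_seg * rec$fs)))
  data.frame(subject_id = rec$subject_id,
             max_amplitude = amp$max_amplitude, kurtosis = amp$kurtosis,
             skewness = env$skewness, peak_factor = amp$peak_factor,
             pulse_factor = amp$pulse_factor, form_factor = amp$form_factor,
             center_of_mass = env$center_of_mass,
             peak_frequency = spec$peak_frequency,
             centroid_frequency = spec$centroid_frequency,
             mean_square_frequency = spec$mean_square_frequency,
             n_beats = nrow(beats), stringsAsFactors = FALSE)
}

#' Extract features for a list of recordings
#'
#' @param recordings list of [koro_recording()]s.
#' @param config a [feature_config()].
#' @param on_error `"stop"` or `"drop"` (skip failing recordings with a
#'   warning).
#' @return data.frame, one row per successfully processed recording.
#' @export
extract_features_cohort <- function(recordings, config = feature_config(),
                                    on_error = c("stop", "drop")) {
  on_error <- match.arg(on_error)
  rows <- lapply(recordings, function(r) {
    if (on_error == "stop") extract_features(r, config)
    else tryCatch(extract_features(r, config), error = function(e) {
      warning("dropping ", r$subject_id, ": ", conditionMessage(e))
      NULL
    })
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}
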