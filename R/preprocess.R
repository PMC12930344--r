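# Cleaning and segmentation of raw cuff recordings: zero-phase high-pass
# baseline removal, analytic-signal envelope, Korotkoff-window location and
# beat segmentation. Beats are detected once here and shared by all
# envelope-based features downstream.

#' Remove baseline drift with a zero-phase high-pass filter
#'
#' 4th-order Butterworth high-pass applied forward and backward
#' (zero-phase), so DC is rejected and frequencies above twice the cutoff
#' pass within 1% of unity while the Korotkoff band (roughly 20-60 Hz) is
#' untouched.
#'
#' @param sound numeric signal.
#' @param fs sampling rate (Hz).
#' @param cutoff high-pass cutoff (Hz), `0 < cutoff < fs/2`.
#' @param order filter order (per pass).
#' @return filtered signal, same length.
#' @export
remove_baseline <- function(sound, fs, cutoff = 5, order = 4L) {
  if (!(cutoff > 0 && cutoff < fs / 2))
    stop("cutoff out of range (0, fs/2)")
  bt <- signal::butter(order, cutoff / (fs / 2), type = "high")
  # mean removal makes DC rejection exact instead of limited by the
  # conditioning of the near-unity pole pair
  sound <- sound - mean(sound)
  # odd-reflection padding confines the filter's start-up transient to the
  # pads, which are trimmed after the two passes
  n <- length(sound)
  np <- min(n - 1L, max(order * 3L, round(2 * fs / cutoff)))
  if (np > 0L) {
    pre <- 2 * sound[1] - sound[(np + 1L):2L]
    post <- 2 * sound[n] - sound[(n - 1L):(n - np)]
    y <- signal::filtfilt(bt, c(pre, sound, post))
    as.numeric(y[(np + 1L):(np + n)])
  } else {
    as.numeric(signal::filtfilt(bt, sound))
  }
}

#' Squared-magnitude response of the baseline filter
#'
#' Numerical evaluation of the designed zero-phase transfer function
#' (|H(f)|^2 of the single-pass Butterworth, since the filter is applied
#' twice). Used as an oracle for the residual drift amplitude.
#'
#' @param f frequencies (Hz) at which to evaluate.
#' @inheritParams remove_baseline
#' @return gain of the zero-phase filter at `f`.
#' @export
baseline_filter_gain <- function(f, fs, cutoff = 5, order = 4L) {
  bt <- signal::butter(order, cutoff / (fs / 2), type = "high")
  z <- exp(2i * pi * f / fs)
  ev <- function(p) vapply(z, function(zz)
    sum(p * zz^-(seq_along(p) - 1)), complex(1))
  Mod(ev(bt$b) / ev(bt$a))^2
}

#' Smoothed analytic-signal envelope
#'
#' Magnitude of the Hilbert analytic signal, smoothed by a moving average.
#'
#' @param sound numeric signal.
#' @param fs sampling rate (Hz).
#' @param smooth_s moving-average length (s).
#' @return non-negative envelope, same length.
#' @export
smooth_envelope <- function(sound, fs, smooth_s = 0.05) {
  n <- length(sound)
  # zero-pad to a highly composite length: mixed-radix FFTs of awkward
  # (near-prime) lengths are orders of magnitude slower
  np <- stats::nextn(n, c(2L, 3L, 5L))
  X <- fft(c(sound, numeric(np - n)))
  u <- numeric(np)
  u[1] <- 1
  if (np %% 2L == 0L) {
    u[2:(np / 2)] <- 2; u[np / 2 + 1] <- 1
  } else {
    u[2:((np + 1) / 2)] <- 2
  }
  env <- Mod(fft(X * u, inverse = TRUE) / np)[seq_len(n)]
  k <- max(1L, round(smooth_s * fs))
  kern <- rep(1 / k, k)
  as.numeric(stats::filter(c(rep(env[1], k), env, rep(env[n], k)),
                           kern, sides = 2))[(k + 1):(k + n)]
}

# local maxima of env above an absolute threshold, greedily enforcing a
# minimum separation (larger peaks win)
.find_peaks <- function(env, thr, min_sep) {
  cand <- which(diff(sign(diff(env))) < 0) + 1L
  cand <- cand[env[cand] >= thr]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(env[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in cand)
    if (!length(kept) || all(abs(kept - p) >= min_sep)) kept <- c(kept, p)
  sort(kept)
}

#' Locate the Korotkoff window of a recording
#'
#' Annotated recordings return their annotation verbatim. Otherwise, in
#' pressure-derived mode, beat-like envelope excursions (above an adaptive
#' threshold and a robust noise floor) estimate SBP and DBP as the cuff
#' pressures at the first and last excursion, widened by one
#' deflation-rate x beat-interval margin (the first audible beat appears
#' up to one heart period after the cuff crosses SBP); the window is the
#' sample run where the pressure lies strictly between the estimates. With
#' no pressure channel, the envelope-derived fallback spans first to last
#' excursion directly.
#'
#' @param rec a [koro_recording()].
#' @param config a [feature_config()] (envelope smoothing, thresholds).
#' @param mode `"auto"` prefers annotation, then pressure, then envelope.
#' @return list with `start`, `end` (0-based half-open samples) and
#'   `method` tag.
#' @export
detect_window <- function(rec, config = feature_config(),
                          mode = c("auto", "annotated", "pressure", "envelope")) {
  mode <- match.arg(mode)
  if (mode == "auto")
    mode <- if (!is.null(rec$annotations)) "annotated"
            else if (!is.null(rec$cuff_pressure)) "pressure" else "envelope"
  if (mode == "annotated") {
    if (is.null(rec$annotations)) stop("recording carries no annotation")
    return(list(start = rec$annotations$start, end = rec$annotations$end,
                method = "annotated"))
  }
  fs <- rec$fs
  x <- remove_baseline(rec$sound, fs, config$baseline_cutoff)
  env <- smooth_envelope(x, fs, config$envelope_smooth)
  floor_thr <- median(env) + 6 * mad(env)
  thr <- max(config$window_threshold * max(env), floor_thr)
  peaks <- .find_peaks(env, thr, round(config$min_separation * fs))
  if (length(peaks) < 2L) stop("no beats detected")
  if (mode == "pressure") {
    p <- rec$cuff_pressure
    if (is.null(p)) stop("no cuff pressure channel")
    n <- length(p)
    slope <- coef(lm(p ~ seq_along(p)))[2] * fs   # mmHg/s
    if (slope >= 0) stop("pressure channel monotone-increasing (inflation-only record)")
    gap_s <- median(diff(peaks)) / fs
    margin <- abs(slope) * gap_s
    sbp_est <- p[peaks[1]] + margin
    dbp_est <- p[peaks[length(peaks)]] - margin
    inside <- which(p < sbp_est & p > dbp_est)
    if (!length(inside)) stop("no samples between estimated DBP and SBP")
    list(start = inside[1] - 1L, end = inside[length(inside)],
         method = "pressure-derived")
  } else {
    half <- round(config$min_separation * fs / 2)
    list(start = max(0L, peaks[1] - 1L - half),
         end = min(length(env), peaks[length(peaks)] + half),
         method = "envelope-derived")
  }
}

#' Segment the beats inside a Korotkoff window
#'
#' Peaks are local maxima of the smoothed magnitude envelope above an
#' adaptive threshold (a fraction of the window's envelope maximum and a
#' robust noise floor), separated by at least `min_separation`; when two
#' candidates conflict the larger is kept. Segment boundaries are the
#' midpoints between consecutive peaks, so segments tile the window
#' without overlap.
#'
#' @param sound preprocessed signal (full record).
#' @param window list with `start`, `end` (0-based half-open samples).
#' @param fs sampling rate (Hz).
#' @param config a [feature_config()].
#' @param cuff_pressure optional pressure channel for the per-beat mmHg.
#' @return data.frame with columns `onset`, `peak`, `end` (0-based
#'   samples), `peak_amp`, `peak_time_s`, `cuff_mmHg`, ordered by time.
#' @export
segment_beats <- function(sound, window, fs, config = feature_config(),
                          cuff_pressure = NULL) {
  if (window$end <= window$start) stop("empty window")
  idx <- (window$start + 1L):window$end
  env <- smooth_envelope(sound, fs, config$envelope_smooth)[idx]
  # beats must clear both the adaptive fraction of the window maximum and a
  # robust noise floor; a window whose envelope never leaves the floor
  # (pure noise) yields no beats
  thr <- max(config$beat_threshold * max(env), median(env) + 6 * mad(env))
  peaks <- .find_peaks(env, thr, round(config$min_separation * fs))
  if (!length(peaks))
    return(data.frame(onset = integer(0), peak = integer(0), end = integer(0),
                      peak_amp = numeric(0), peak_time_s = numeric(0),
                      cuff_mmHg = numeric(0)))
  # 0-based cut positions within the window; segments tile it exactly
  cuts <- c(0L, as.integer(floor((peaks[-1] + peaks[-length(peaks)]) / 2)),
            length(idx))
  peak_abs <- window$start + peaks - 1L     # 0-based absolute sample
  df <- data.frame(
    onset = window$start + cuts[seq_along(peaks)],
    peak = peak_abs,
    end = window$start + cuts[-1],
    peak_amp = env[peaks],
    peak_time_s = peak_abs / fs,
    cuff_mmHg = if (is.null(cuff_pressure)) NA_real_
                else cuff_pressure[peak_abs + 1L])
  df[order(df$peak_time_s), , drop = FALSE]
}
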