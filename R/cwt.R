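# Continuous wavelet transform scalograms (analytic Morlet, FFT-based)
# and their conversion to fixed-size RGB images for the classifier.

#' Continuous wavelet transform scalogram
#'
#' Analytic Morlet transform (centre angular frequency 6) evaluated on
#' log-spaced centre frequencies, computed in the frequency domain. The
#' magnitude matrix is linear in the input amplitude.
#'
#' @param sound numeric signal.
#' @param fs sampling rate (Hz).
#' @param f_min,f_max frequency band (Hz), `0 < f_min < f_max <= fs/2`.
#' @param n_scales number of log-spaced scales (>= 8).
#' @return list of class `koro_scalogram`: `mag` (n_scales x n matrix,
#'   rows ordered by ascending frequency), `freq` (Hz, ascending), `time`
#'   (s).
#' @export
cwt_scalogram <- function(sound, fs, f_min = 5, f_max = 100, n_scales = 64L) {
  if (!(f_min > 0 && f_min < f_max && f_max <= fs / 2))
    stop("invalid band: need 0 < f_min < f_max <= fs/2")
  if (n_scales < 8L) stop("n_scales must be >= 8")
  n <- length(sound)
  omega0 <- 6
  freqs <- exp(seq(log(f_min), log(f_max), length.out = n_scales))
  scales <- omega0 * fs / (2 * pi * freqs)        # in samples
  if (n < 4 * max(scales))
    stop("signal shorter than the longest wavelet support (",
         ceiling(4 * max(scales)), " samples needed)")
  # zero-pad to a composite FFT length (speed + reduced wraparound)
  np <- stats::nextn(n, c(2L, 3L, 5L))
  X <- fft(c(sound, numeric(np - n)))
  omega <- 2 * pi * (seq_len(np) - 1) / np
  omega[omega > pi] <- omega[omega > pi] - 2 * pi   # signed angular freq
  mag <- matrix(0, n_scales, n)
  for (k in seq_len(n_scales)) {
    s <- scales[k]
    psi <- sqrt(2 * pi * s) * pi^-0.25 *
      exp(-0.5 * (s * omega - omega0)^2) * (omega > 0)
    mag[k, ] <- Mod(fft(X * psi, inverse = TRUE) / np)[seq_len(n)]
  }
  structure(list(mag = mag, freq = freqs, time = (seq_len(n) - 1) / fs),
            class = "koro_scalogram")
}

#' Ridge of a scalogram
#'
#' Frequency of maximum magnitude per time column.
#' @param sc a [cwt_scalogram()] result.
#' @return numeric vector of ridge frequencies (Hz), one per column.
#' @export
scalogram_ridge <- function(sc) {
  sc$freq[apply(sc$mag, 2, which.max)]
}

.resize_bilinear <- function(m, h, w) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- if (h == 1L) rep(1, h) else seq(1, nr, length.out = h)
  ci <- if (w == 1L) rep(1, w) else seq(1, nc, length.out = w)
  r0 <- pmin(floor(ri), nr - 1L); r1 <- r0 + 1L; fr <- ri - r0
  c0 <- pmin(floor(ci), nc - 1L); c1 <- c0 + 1L; fc <- ci - c0
  if (nr == 1L) { r0 <- r1 <- rep(1L, h); fr <- rep(0, h) }
  if (nc == 1L) { c0 <- c1 <- rep(1L, w); fc <- rep(0, w) }
  a <- m[r0, c0, drop = FALSE] * ((1 - fr) %o% (1 - fc)) +
       m[r1, c0, drop = FALSE] * (fr %o% (1 - fc)) +
       m[r0, c1, drop = FALSE] * ((1 - fr) %o% fc) +
       m[r1, c1, drop = FALSE] * (fr %o% fc)
  a
}

#' Fixed 256-entry colormap lookup table
#'
#' A perceptually uniform map shipped as an explicit table so images are
#' bit-identical across plotting backends.
#'
#' @param name a palette known to [grDevices::hcl.colors()].
#' @return 256 x 3 integer matrix of RGB values in 0..255.
#' @export
colormap_table <- function(name = "viridis") {
  t(col2rgb(hcl.colors(256L, name)))
}

#' Render a scalogram as a fixed-size RGB image
#'
#' Per-image min-max normalization of the log-magnitude, bilinear resize
#' to the target size, then lookup in a fixed 256-colour table. The result
#' is deterministic and invariant to global amplitude scaling of the
#' scalogram. A degenerate (constant) scalogram maps to the mid-colormap
#' colour. Rows run from high frequency (top) to low (bottom).
#'
#' @param sc a [cwt_scalogram()] result.
#' @param height,width output size in pixels.
#' @param colormap palette name for [colormap_table()].
#' @return `height x width x 3` integer array with values in 0..255.
#' @export
scalogram_to_rgb <- function(sc, height = 224L, width = 224L,
                             colormap = "viridis") {
  if (height < 1L || width < 1L) stop("target size must be positive")
  peak <- max(sc$mag)
  # relative floor 120 dB below the peak keeps the log map exactly
  # invariant to global amplitude scaling
  lm <- if (peak > 0) log10(pmax(sc$mag / peak, 1e-6))
        else sc$mag
  lm <- lm[rev(seq_len(nrow(lm))), , drop = FALSE]   # high freq on top
  rng <- range(lm)
  z <- if (diff(rng) <= 0) matrix(0.5, nrow(lm), ncol(lm))
       else (lm - rng[1]) / diff(rng)
  z <- .resize_bilinear(z, height, width)
  z <- pmin(pmax(z, 0), 1)
  lut <- colormap_table(colormap)
  idx <- matrix(as.integer(round(z * 255)) + 1L, height, width)
  img <- array(0L, c(height, width, 3L))
  for (ch in 1:3) img[, , ch] <- matrix(lut[idx, ch], height, width)
  img
}

#' Write an RGB image array to a PNG file
#' @param img `h x w x 3` array with values in 0..255.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_rgb_png <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}
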