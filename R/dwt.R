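# Orthogonal periodized discrete wavelet transform with the standard
# Daubechies filter banks, used for wavelet denoising. Coefficients are the
# published Daubechies scaling filters (sum = sqrt(2)); perfect
# reconstruction is asserted in the test suite.

.wavelet_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db4 = c(2.3037781330889651e-01, 7.1484657055291567e-01,
          6.3088076792985892e-01, -2.7983769416859854e-02,
          -1.8703481171909309e-01, 3.0841381835560764e-02,
          3.2883011666885197e-02, -1.0597401785069032e-02),
  db6 = c(1.1154074335010947e-01, 4.9462389039845306e-01,
          7.5113390802109536e-01, 3.1525035170919763e-01,
          -2.2626469396543983e-01, -1.2976686756726194e-01,
          9.7501605587323043e-02, 2.7522865530305727e-02,
          -3.1582039317486030e-02, 5.5384220116149613e-04,
          4.7772575109455108e-03, -1.0773010853084796e-03))

.qmf <- function(h) {
  L <- length(h)
  rev(h) * (-1)^(seq_len(L) - 1)
}

.dwt_step <- function(x, h, g) {
  n <- length(x)
  stopifnot(n %% 2L == 0L)
  L <- length(h)
  even <- seq(0L, n - 2L, by = 2L)
  a <- numeric(n / 2L); d <- numeric(n / 2L)
  for (k in seq_len(L)) {
    xk <- x[(even + (k - 1L)) %% n + 1L]
    a <- a + h[k] * xk
    d <- d + g[k] * xk
  }
  list(a = a, d = d)
}

.idwt_step <- function(a, d, h, g) {
  n <- 2L * length(a)
  ua <- numeric(n); ud <- numeric(n)
  ua[seq(1L, n, by = 2L)] <- a
  ud[seq(1L, n, by = 2L)] <- d
  x <- numeric(n)
  for (k in seq_along(h)) {
    s <- k - 1L                       # circular right-shift by the tap lag
    if (s == 0L) { ra <- ua; rd <- ud }
    else { ra <- c(ua[(n - s + 1L):n], ua[1L:(n - s)])
           rd <- c(ud[(n - s + 1L):n], ud[1L:(n - s)]) }
    x <- x + h[k] * ra + g[k] * rd
  }
  x
}

#' Multi-level discrete wavelet decomposition
#'
#' Periodized orthogonal DWT. The signal is extended at the tail by
#' edge-value padding to a multiple of `2^level`; [idwt()] trims back to
#' the original length.
#'
#' @param x numeric signal.
#' @param wavelet `"haar"`, `"db4"` or `"db6"`.
#' @param level decomposition depth (>= 1 and feasible for the length).
#' @return list with approximation `a`, details `d` (list, level 1 first),
#'   original length `n`, and the wavelet name.
#' @export
dwt <- function(x, wavelet = "db6", level = 4L) {
  h <- .wavelet_filters[[wavelet]]
  if (is.null(h)) stop("unknown wavelet: ", wavelet)
  if (level < 1L) stop("level must be >= 1")
  n <- length(x)
  block <- 2L^level
  if (n < 2L * block) stop("infeasible level ", level, " for length ", n)
  n_pad <- ceiling(n / block) * block
  xp <- c(x, rep(x[n], n_pad - n))
  g <- .qmf(h)
  details <- vector("list", level)
  a <- xp
  for (l in seq_len(level)) {
    st <- .dwt_step(a, h, g)
    a <- st$a
    details[[l]] <- st$d
  }
  list(a = a, d = details, n = n, wavelet = wavelet)
}

#' Inverse multi-level discrete wavelet transform
#' @param w a decomposition from [dwt()].
#' @return numeric signal of the original length.
#' @export
idwt <- function(w) {
  h <- .wavelet_filters[[w$wavelet]]
  g <- .qmf(h)
  a <- w$a
  for (l in rev(seq_along(w$d))) a <- .idwt_step(a, w$d[[l]], h, g)
  a[seq_len(w$n)]
}

#' Wavelet denoising of a sound channel
#'
#' Decomposes the signal, shrinks the detail coefficients, and
#' reconstructs; the approximation band is left untouched. The default
#' `"universal-soft"` rule soft-thresholds every detail level at
#' `sigma * sqrt(2 log n)` with the noise scale `sigma` estimated from the
#' finest-level details by `median(|d1|) / 0.6745`.
#'
#' @param sound numeric signal.
#' @param wavelet wavelet name (see [dwt()]).
#' @param level decomposition depth.
#' @param rule `"universal-soft"` or `"universal-hard"`.
#' @return denoised signal, same length as the input.
#' @export
wavelet_denoise <- function(sound, wavelet = "db6", level = 4L,
                            rule = c("universal-soft", "universal-hard")) {
  rule <- match.arg(rule)
  w <- dwt(sound, wavelet, level)
  sigma <- median(abs(w$d[[1]])) / 0.6745
  thr <- sigma * sqrt(2 * log(length(sound)))
  w$d <- lapply(w$d, function(d) {
    if (rule == "universal-soft") sign(d) * pmax(abs(d) - thr, 0)
    else d * (abs(d) > thr)
  })
  idwt(w)
}
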