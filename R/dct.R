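# Orthonormal DCT-II and its inverse (DCT-III), computed via the FFT of the
# even extension. The DCT implicitly extends the analyzed signal by pivoting
# it at onset and offset so the periodic extension is even; this avoids the
# spectral artifacts a DFT would create by juxtaposing a drawn-out,
# low-amplitude offset with an abrupt, high-amplitude onset. With orthonormal
# scaling the transform is an isometry, so coefficient energy equals signal
# energy (Parseval) and band splits are exact.

#' Orthonormal type-II discrete cosine transform
#'
#' `X[k+1] = a_k * sum_n x[n+1] * cos(pi * (n + 1/2) * k / N)` for
#' `k = 0, ..., N-1`, with `a_0 = sqrt(1/N)` and `a_k = sqrt(2/N)` otherwise.
#' `idct_ii()` inverts it exactly.
#'
#' @param x numeric vector, length >= 1.
#' @return numeric vector of DCT coefficients, same length as `x`.
#' @export
dct_ii <- function(x) {
  n <- length(x)
  if (n == 1L) return(x)
  y <- stats::fft(c(x, rev(x)))
  k <- 0:(n - 1L)
  coef <- Re(exp(-1i * pi * k / (2 * n)) * y[1:n]) / 2
  coef * c(sqrt(1 / n), rep(sqrt(2 / n), n - 1L))
}

#' @rdname dct_ii
#' @param coef numeric vector of orthonormal DCT-II coefficients.
#' @export
idct_ii <- function(coef) {
  n <- length(coef)
  if (n == 1L) return(coef)
  k <- 0:(n - 1L)
  b <- coef * c(sqrt(1 / n), rep(sqrt(2 / n), n - 1L))
  z <- b * exp(1i * pi * k / (2 * n))
  Re(stats::fft(c(z, rep(0 + 0i, n)), inverse = TRUE)[1:n])
}

# Frequency (Hz) associated with orthonormal DCT-II coefficient index k
# (0-based): f_k = k * rate / (2N).
dct_bin_frequencies <- function(n, rate) (0:(n - 1L)) * rate / (2 * n)

# Band-limit a signal by zeroing DCT coefficients outside [lo, hi) Hz.
# Used both by the analysis filter bank and to shape synthetic noise.
dct_bandpass <- function(x, rate, lo, hi) {
  coef <- dct_ii(x)
  f <- dct_bin_frequencies(length(x), rate)
  coef[f < lo | f >= hi] <- 0
  idct_ii(coef)
}
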