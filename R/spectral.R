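# Spectral analysis via an exact DCT filter bank.
#
# Cough-type maneuvers are transient (about 0.3 s on average) and evolve too
# quickly for spectrogram-style analysis, so the spectrum is summarized by a
# small number of frequency bands instead: 0-400, 400-800, 800-1600,
# 1600-3200 Hz, and 3200 Hz up to half the sampling rate. Each DCT
# coefficient is assigned to the band containing its frequency; the inverse
# DCT of each band's coefficients yields band-limited constituent signals
# whose sum reconstructs the segment exactly and whose energies sum to the
# segment energy (Parseval, orthonormal DCT).

band_edge_defaults <- c(400, 800, 1600, 3200)

#' Decompose a segment into band-limited constituents via the DCT
#'
#' @param seg a `cough_segment` (or any list with numeric `samples` and
#'   `rate`), length >= 2.
#' @param edges interior band edges in Hz (increasing); the full edge set is
#'   `c(0, edges, rate/2)`. A coefficient whose frequency falls exactly on
#'   an edge belongs to the higher band (half-open bands).
#' @return An object of class `band_decomposition`: list with
#'   `constituents` (list of numeric vectors, one per band, same length as
#'   the segment), `rel_energy` (sums to 1), `edges_hz` (full edge vector),
#'   `band_labels`, `rate`.
#' @export
dct_band_decompose <- function(seg, edges = band_edge_defaults) {
  x <- seg$samples
  rate <- seg$rate
  n <- length(x)
  if (n < 2L) stop("segment too short to decompose (length >= 2 required)")
  if (any(diff(edges) <= 0) || any(edges <= 0) || any(edges >= rate / 2))
    stop("band edges must be increasing and inside (0, rate/2)")
  full <- c(0, edges, rate / 2)
  coef <- dct_ii(x)
  f <- dct_bin_frequencies(n, rate)
  band_of <- findInterval(f, full, rightmost.closed = FALSE, left.open = FALSE)
  nb <- length(full) - 1L
  total <- sum(coef^2)
  constituents <- vector("list", nb)
  energy <- numeric(nb)
  for (b in seq_len(nb)) {
    cb <- coef
    cb[band_of != b] <- 0
    energy[b] <- sum(cb^2)
    constituents[[b]] <- idct_ii(cb)
  }
  labels <- paste0(formatC(full[-length(full)], format = "fg"), "-",
                   formatC(full[-1], format = "fg"), "Hz")
  structure(list(
    constituents = constituents,
    rel_energy = energy / total,
    edges_hz = full,
    band_labels = labels,
    rate = rate,
    n = n
  ), class = "band_decomposition")
}

#' @export
print.band_decomposition <- function(x, ...) {
  cat("<band_decomposition>\n")
  for (b in seq_along(x$constituents))
    cat(sprintf("  %-16s rel. energy %.4f\n", x$band_labels[b], x$rel_energy[b]))
  invisible(x)
}

#' Typical frequency of a band-limited signal from unidirectional zero crossings
#'
#' Counts sign changes from negative to non-negative (zero samples treated
#' as non-negative) and divides by the duration, giving f crossings per
#' second for a sinusoid at f Hz. An all-zero or crossing-free signal
#' returns 0 Hz.
#'
#' @param constituent numeric vector, length >= 2.
#' @param rate sampling rate (Hz).
#' @return Frequency estimate in Hz, in `[0, rate/2]`.
#' @export
band_frequency <- function(constituent, rate) {
  n <- length(constituent)
  if (n < 2L) stop("constituent must have length >= 2")
  nonneg <- constituent >= 0
  crossings <- sum(!nonneg[-n] & nonneg[-1L])
  crossings / (n / rate)
}

#' Weighted frequency (spectral-centroid approximation)
#'
#' The per-band zero-crossing frequencies weighted by the relative band
#' energies and summed. Approximates the spectral centroid that splits the
#' spectrum into two halves of equal energy. Bands with zero energy
#' contribute nothing.
#'
#' @param decomp a [dct_band_decompose()] result.
#' @return Weighted frequency in Hz.
#' @export
weighted_frequency <- function(decomp) {
  stopifnot(inherits(decomp, "band_decomposition"))
  freqs <- band_frequencies(decomp)
  sum(ifelse(decomp$rel_energy > 0, decomp$rel_energy * freqs, 0))
}

#' Per-band zero-crossing frequencies of a decomposition
#' @param decomp a [dct_band_decompose()] result.
#' @return Numeric vector of band frequencies (Hz), one per band.
#' @export
band_frequencies <- function(decomp) {
  vapply(decomp$constituents, band_frequency, numeric(1), rate = decomp$rate)
}
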