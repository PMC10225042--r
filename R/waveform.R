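#' Construct a mono waveform
#'
#' A waveform is the raw-signal container used throughout the package: a
#' numeric vector of dimensionless sample amplitudes together with the
#' sampling rate in Hz. Recordings are nominally sampled at 44.1 kHz, but any
#' positive rate is accepted and propagated -- every downstream feature is
#' defined per second or per frame, so no resampling is performed.
#'
#' @param samples numeric vector of sample amplitudes (single channel).
#' @param rate sampling rate in samples per second (Hz), > 0.
#' @return An object of class `waveform` with elements `samples` and `rate`.
#' @examples
#' w <- waveform(sin(2 * pi * 100 * (0:999) / 8000), 8000)
#' duration(w)
#' @export
waveform <- function(samples, rate) {
  if (!is.numeric(samples) || length(samples) < 1L)
    stop("`samples` must be a numeric vector of length >= 1")
  if (is.matrix(samples))
    stop("`samples` must be mono (single channel); got a matrix with ",
         ncol(samples), " columns")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number (Hz)")
  structure(list(samples = as.double(samples), rate = as.double(rate)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz (%.4f s)>\n",
              length(x$samples), x$rate, duration(x)))
  invisible(x)
}

#' Duration of a waveform or segment in seconds
#' @param w a `waveform` or `cough_segment`.
#' @return Duration in seconds.
#' @export
duration <- function(w) length(w$samples) / w$rate

#' @export
length.waveform <- function(x) length(x$samples)

is_waveform <- function(x) inherits(x, "waveform")
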