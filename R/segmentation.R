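# Automatic trimming of a manually pre-split maneuver to its acoustic
# extent, and energy normalization of the result.
#
# The recordings are assumed pre-split to a single maneuver flanked by
# silence. Because the offset of a cough is drawn out without a well-defined
# boundary, trimming is done against the signal's energy envelope: the onset
# is the start of the first frame, and the offset the end of the last frame,
# whose level exceeds -30 dB relative to the envelope maximum. The trimmed
# segment is then normalized so its average signal energy equals one, which
# removes the influence of pre-amplifier gain and microphone placement on
# every downstream feature.

#' Per-frame energy envelope in dB relative to the maximum
#'
#' Frames are non-overlapping by default (hop = frame); a final partial
#' frame is kept with its true length so a drawn-out offset is never
#' silently dropped. The level of frame i is
#' `10 * log10(meansq_i / max_j meansq_j)`, so the maximum is 0 dB exactly.
#'
#' @param w a [waveform()].
#' @param frame_s frame length in seconds (default 10 ms).
#' @param hop_s hop between frame starts in seconds (default = `frame_s`).
#' @return An object of class `envelope_contour`: list with `time` (frame
#'   centers, s), `level_db` (<= 0), `start`, `end` (1-based sample index
#'   ranges per frame), `frame_s`, `hop_s`.
#' @export
envelope_contour <- function(w, frame_s = 0.01, hop_s = frame_s) {
  stopifnot(is_waveform(w))
  if (frame_s * w$rate < 2) stop("frame too short: need frame_s * rate >= 2")
  if (hop_s <= 0 || hop_s > frame_s)
    stop("need 0 < hop_s <= frame_s")
  x <- w$samples
  n <- length(x)
  if (all(x == 0)) stop("no acoustic content: signal is identically zero")

  flen <- round(frame_s * w$rate)
  hop <- round(hop_s * w$rate)
  starts <- seq.int(1L, n, by = hop)
  # drop starts that begin beyond the end (cannot happen with seq to n)
  ends <- pmin(starts + flen - 1L, n)
  msq <- vapply(seq_along(starts),
                function(i) mean(x[starts[i]:ends[i]]^2), numeric(1))
  level <- 10 * log10(msq / max(msq))
  structure(list(
    time = (starts + ends - 1) / 2 / w$rate,
    level_db = level,
    start = starts, end = ends,
    frame_s = frame_s, hop_s = hop_s, rate = w$rate, n = n
  ), class = "envelope_contour")
}

#' Trim a waveform to frames above an envelope threshold
#'
#' The onset is the first sample of the first frame, and the offset one past
#' the last sample of the last frame, whose envelope level is strictly
#' greater than `threshold_db` (default -30 dB relative to the envelope
#' maximum). Indices are 0-based and half-open, so `w$samples[(onset + 1):offset]`
#' is the trimmed signal.
#'
#' @param w the [waveform()] the contour was computed from.
#' @param contour an [envelope_contour()] of `w`.
#' @param threshold_db threshold in dB relative to the contour maximum.
#' @return list with `onset` and `offset` (0-based, half-open sample range).
#' @export
auto_trim <- function(w, contour, threshold_db = -30) {
  stopifnot(is_waveform(w), inherits(contour, "envelope_contour"))
  if (contour$n != length(w$samples) || contour$rate != w$rate)
    stop("contour was not derived from this waveform")
  keep <- which(contour$level_db > threshold_db)
  # the maximum frame is at 0 dB, so keep is never empty for finite thresholds
  first <- keep[1L]
  last <- keep[length(keep)]
  list(onset = contour$start[first] - 1L, offset = contour$end[last])
}

#' Energy-normalize a trimmed slice of a waveform
#'
#' Divides the slice by its root-mean-square so the average signal energy
#' (mean squared sample) of the segment equals one.
#'
#' @param w a [waveform()].
#' @param onset,offset 0-based half-open sample range, e.g. from
#'   [auto_trim()]; defaults to the whole waveform.
#' @return An object of class `cough_segment`: list with `samples`
#'   (mean square = 1), `rate`, `onset`, `offset`, `duration`.
#' @export
normalize_energy <- function(w, onset = 0L, offset = length(w$samples)) {
  stopifnot(is_waveform(w))
  if (onset < 0L || offset > length(w$samples) || onset >= offset)
    stop("invalid trim range [", onset, ", ", offset, ")")
  x <- w$samples[(onset + 1L):offset]
  msq <- mean(x^2)
  if (msq <= 0) stop("zero-energy slice cannot be normalized")
  structure(list(
    samples = x / sqrt(msq),
    rate = w$rate,
    onset = as.integer(onset), offset = as.integer(offset),
    duration = (offset - onset) / w$rate
  ), class = "cough_segment")
}

#' @export
print.cough_segment <- function(x, ...) {
  cat(sprintf("<cough_segment: %.4f s @ %g Hz, parent samples [%d, %d)>\n",
              x$duration, x$rate, x$onset, x$offset))
  invisible(x)
}

is_segment <- function(x) inherits(x, "cough_segment")

#' Trim and normalize in one step
#'
#' Convenience wrapper: envelope contour, threshold trim, energy
#' normalization.
#'
#' @inheritParams envelope_contour
#' @inheritParams auto_trim
#' @return A `cough_segment` (see [normalize_energy()]).
#' @export
trim_segment <- function(w, threshold_db = -30, frame_s = 0.01,
                         hop_s = frame_s) {
  contour <- envelope_contour(w, frame_s, hop_s)
  tr <- auto_trim(w, contour, threshold_db)
  normalize_energy(w, tr$onset, tr$offset)
}
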