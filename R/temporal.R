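# Temporal analysis: evolution with time of the signal amplitude, the sample
# entropy, and the kurtosis, each computed per analysis frame and summarized
# by the first three DCT coefficients of the resulting contour.
#
# - amplitude contour: per-frame mean energy (mean squared sample). Because
#   segments are energy-normalized, the duration-weighted contour average is
#   one, so the contour reports the relative strength of the signal over time.
# - sample-entropy contour: degree of randomness per frame; turbulence noise
#   is less predictable than locally periodic oscillation, so frication
#   frames score high and voiced/oscillatory frames low.
# - kurtosis contour: impulsiveness per frame; Gaussian-like frames sit near
#   3, burst-like onsets far above.

#' Split a segment into analysis frames
#'
#' Frame starts are laid out every `hop_s` from the segment onset; the frame
#' at each start extends `frame_s` or to the end of the segment, whichever
#' comes first, so the frames cover the whole segment and the last partial
#' frame keeps its true length. A segment shorter than one frame yields a
#' single frame spanning the whole segment.
#'
#' @param seg a `cough_segment` (or any list with `samples` and `rate`).
#' @param frame_s frame length (s); default 20 ms.
#' @param hop_s hop (s); default 10 ms.
#' @return list with `frames` (list of numeric vectors), `start` (1-based
#'   sample indices), `time` (frame start, s).
#' @export
frame_segment <- function(seg, frame_s = 0.02, hop_s = 0.01) {
  x <- seg$samples
  rate <- seg$rate
  if (frame_s * rate < 16) stop("frame too short: need frame_s * rate >= 16")
  if (hop_s <= 0) stop("hop_s must be > 0")
  n <- length(x)
  flen <- round(frame_s * rate)
  hop <- max(1L, round(hop_s * rate))
  starts <- seq.int(1L, n, by = hop)
  ends <- pmin(starts + flen - 1L, n)
  list(
    frames = lapply(seq_along(starts), function(i) x[starts[i]:ends[i]]),
    start = starts,
    time = (starts - 1L) / rate
  )
}

new_contour <- function(values, time, kind, frame_s, hop_s) {
  structure(list(values = values, time = time, kind = kind,
                 frame_s = frame_s, hop_s = hop_s),
            class = "feature_contour")
}

#' @export
print.feature_contour <- function(x, ...) {
  cat(sprintf("<%s contour: %d frames (%d defined), frame %g ms / hop %g ms>\n",
              x$kind, length(x$values), sum(!is.na(x$values)),
              1000 * x$frame_s, 1000 * x$hop_s))
  invisible(x)
}

#' Amplitude contour (per-frame mean energy)
#'
#' For an energy-normalized segment framed with `hop_s = frame_s` (tiling
#' frames), the frame-length-weighted mean of the contour equals one.
#'
#' @inheritParams frame_segment
#' @return A `feature_contour` with `kind = "amplitude"`.
#' @export
amplitude_contour <- function(seg, frame_s = 0.02, hop_s = 0.01) {
  fr <- frame_segment(seg, frame_s, hop_s)
  v <- vapply(fr$frames, function(f) mean(f^2), numeric(1))
  new_contour(v, fr$time, "amplitude", frame_s, hop_s)
}

#' Sample entropy of a numeric series
#'
#' `SampEn(m, r)` = `-log(A / B)` where `B` is the number of pairs of
#' distinct templates of length `m` within Chebyshev distance `r`, and `A`
#' the same count for length `m + 1`; templates start at the first
#' `n - m` positions so both counts are comparable, and self-matches are
#' excluded. A constant series is perfectly predictable and returns 0.
#' Returns `NA` (undefined) when either count is zero.
#'
#' @param x numeric vector, `length(x) > m + 1`.
#' @param m template length (default 2).
#' @param r matching tolerance (absolute units of `x`).
#' @return Nonnegative scalar, or `NA_real_` if undefined.
#' @export
sample_entropy <- function(x, m = 2L, r) {
  n <- length(x)
  if (n <= m + 1L) return(NA_real_)
  if (stats::sd(x) == 0) return(0)
  nt <- n - m                      # templates compared at both lengths
  d <- abs(outer(x, x, "-"))
  dm <- d[1:nt, 1:nt]
  if (m >= 1L) for (j in seq_len(m - 1L)) {
    dm <- pmax(dm, d[(1L + j):(nt + j), (1L + j):(nt + j)])
  }
  b_cnt <- (sum(dm <= r) - nt) / 2
  dm1 <- pmax(dm, d[(1L + m):(nt + m), (1L + m):(nt + m)])
  a_cnt <- (sum(dm1 <= r) - nt) / 2
  if (a_cnt == 0 || b_cnt == 0) return(NA_real_)
  -log(a_cnt / b_cnt)
}

# Multiscale-style coarse-graining: block means down to <= target_hz.
coarse_grain <- function(x, rate, target_hz) {
  fac <- max(1L, floor(rate / target_hz))
  if (fac == 1L) return(x)
  n <- (length(x) %/% fac) * fac
  if (n == 0L) return(x)
  colMeans(matrix(x[1:n], nrow = fac))
}

#' Sample-entropy contour
#'
#' Each frame is coarse-grained (block means) to at most `decimate_to_hz`
#' before matching, which bounds the quadratic template search; the matching
#' tolerance is `r_factor` times the standard deviation of the
#' coarse-grained frame. Frames whose entropy is undefined (no template
#' matches at either length, or too short) carry `NA` and are dropped before
#' shape fitting.
#'
#' @inheritParams frame_segment
#' @param m template length.
#' @param r_factor tolerance as a fraction of the frame standard deviation.
#' @param decimate_to_hz target rate (Hz) for per-frame coarse-graining.
#' @return A `feature_contour` with `kind = "sample_entropy"`.
#' @export
sample_entropy_contour <- function(seg, frame_s = 0.02, hop_s = 0.01,
                                   m = 2L, r_factor = 0.2,
                                   decimate_to_hz = 4410) {
  fr <- frame_segment(seg, frame_s, hop_s)
  v <- vapply(fr$frames, function(f) {
    g <- coarse_grain(f, seg$rate, decimate_to_hz)
    if (length(g) <= m + 1L) return(NA_real_)
    s <- stats::sd(g)
    if (s == 0) return(0)
    sample_entropy(g, m, r_factor * s)
  }, numeric(1))
  new_contour(v, fr$time, "sample_entropy", frame_s, hop_s)
}

#' Pearson (non-excess) kurtosis
#'
#' Fourth central moment over squared second central moment, both with `1/n`
#' normalization: 3 for a normal sample, 1.5 for a full-period sinusoid,
#' large for burst-like frames.
#'
#' @param x numeric vector, length >= 4.
#' @return Scalar >= 1, or `NA_real_` for a zero-variance frame.
#' @export
kurtosis_pearson <- function(x) {
  n <- length(x)
  if (n < 4L) return(NA_real_)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - mu)^4) / m2^2
}

#' Kurtosis contour
#'
#' @inheritParams frame_segment
#' @return A `feature_contour` with `kind = "kurtosis"`; zero-variance or
#'   too-short frames carry `NA`.
#' @export
kurtosis_contour <- function(seg, frame_s = 0.02, hop_s = 0.01) {
  fr <- frame_segment(seg, frame_s, hop_s)
  v <- vapply(fr$frames, kurtosis_pearson, numeric(1))
  new_contour(v, fr$time, "kurtosis", frame_s, hop_s)
}

#' Shape of a contour from its first three DCT coefficients
#'
#' With `x_n` the defined contour values (`NA` frames dropped) and `N` their
#' number, the descriptors are the first three type-II DCT coefficients
#' under a length-comparable scaling:
#' `average = mean(x)`,
#' `slope = (2/N) * sum x_n cos(pi (n + 1/2) / N)`,
#' `curvature = (2/N) * sum x_n cos(pi (n + 1/2) * 2 / N)`.
#' Sign conventions: a positive slope coefficient indicates a contour that
#' decreases with time; a positive curvature coefficient indicates a
#' downward-upward (convex) contour, a negative one an upward-downward
#' (concave) contour.
#'
#' @param contour a `feature_contour` (or plain numeric vector) with at
#'   least 3 defined values.
#' @return Named numeric vector `c(average=, slope=, curvature=)`.
#' @export
contour_shape <- function(contour) {
  x <- if (inherits(contour, "feature_contour")) contour$values else contour
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) stop("need at least 3 defined contour values, got ", n)
  ns <- (seq_len(n) - 0.5)
  c(average   = mean(x),
    slope     = (2 / n) * sum(x * cos(pi * ns * 1 / n)),
    curvature = (2 / n) * sum(x * cos(pi * ns * 2 / n)))
}
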