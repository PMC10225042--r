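# Minimal RIFF/WAVE reader and writer for mono recordings.
#
# Supports the encodings used for cough recordings in practice: integer PCM
# at 16/24/32 bits and IEEE float at 32/64 bits. Integer samples are scaled
# to [-1, 1) by 2^(bits-1) (asymmetric full scale), so a full-scale PCM-16
# file reads back as values in {-1, ..., +32767/32768}. Multi-channel files
# are rejected: all analyses here are defined on a single channel.

WAVE_FORMAT_PCM <- 1L
WAVE_FORMAT_IEEE_FLOAT <- 3L
WAVE_FORMAT_EXTENSIBLE <- 65534L

#' Read a mono WAV file
#'
#' @param path path to a RIFF/WAVE file, single channel, PCM 16/24/32 bit or
#'   IEEE float 32/64 bit.
#' @return A [waveform()]; integer encodings are scaled by `1 / 2^(bits-1)`
#'   so samples lie in `[-1, 1]`; float samples are returned bit-exact.
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1L, size = 4L, endian = "little")  # chunk size
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- parse_fmt_chunk(body)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size)  # skip LIST, fact, ...
    }
    if (size %% 2L == 1L) readBin(con, "raw", 1L)  # pad byte
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("no fmt chunk found in ", path)
  if (is.null(data_raw)) stop("no data chunk found in ", path)

  if (fmt$channels != 1L)
    stop("multi-channel WAV not supported: file has ", fmt$channels,
         " channels; supply a mono file")

  bytes_per <- fmt$bits %/% 8L
  n <- length(data_raw) %/% bytes_per
  samples <- decode_wav_samples(data_raw, fmt, n, bytes_per)
  waveform(samples, fmt$rate)
}

parse_fmt_chunk <- function(body) {
  u16 <- function(off) sum(as.integer(body[off + 1:2]) * c(1L, 256L))
  u32 <- function(off) sum(as.numeric(body[off + 1:4]) * 256^(0:3))
  tag <- u16(0L)
  channels <- u16(2L)
  rate <- u32(4L)
  bits <- u16(14L)
  if (tag == WAVE_FORMAT_EXTENSIBLE && length(body) >= 26L) {
    # SubFormat GUID's first two bytes carry the real format tag
    tag <- u16(24L)
  }
  if (!tag %in% c(WAVE_FORMAT_PCM, WAVE_FORMAT_IEEE_FLOAT))
    stop("unsupported WAV encoding (format tag ", tag,
         "); only integer PCM and IEEE float are supported")
  if (tag == WAVE_FORMAT_PCM && !bits %in% c(16L, 24L, 32L))
    stop("unsupported PCM bit depth: ", bits)
  if (tag == WAVE_FORMAT_IEEE_FLOAT && !bits %in% c(32L, 64L))
    stop("unsupported float bit depth: ", bits)
  list(tag = tag, channels = channels, rate = rate, bits = bits)
}

decode_wav_samples <- function(data_raw, fmt, n, bytes_per) {
  if (fmt$tag == WAVE_FORMAT_IEEE_FLOAT) {
    return(readBin(data_raw, "double", n, size = bytes_per, endian = "little"))
  }
  if (fmt$bits == 24L) {
    # assemble signed 24-bit little-endian by hand; readBin has no size-3 int
    b <- matrix(as.integer(data_raw[seq_len(n * 3L)]), nrow = 3L)
    v <- b[1L, ] + b[2L, ] * 256 + b[3L, ] * 65536
    v <- ifelse(v >= 8388608, v - 16777216, v)
    return(v / 8388608)
  }
  v <- readBin(data_raw, "integer", n, size = bytes_per, signed = TRUE,
               endian = "little")
  v / 2^(fmt$bits - 1L)
}

#' Write a mono WAV file
#'
#' @param w a [waveform()].
#' @param path output path.
#' @param encoding `"pcm16"` (samples clamped to `[-1, 1)` and quantized by
#'   `round(x * 32768)`) or `"float32"`/`"float64"` (lossless for doubles in
#'   the case of `"float64"`).
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, encoding = c("pcm16", "float32", "float64")) {
  stopifnot(is_waveform(w))
  encoding <- match.arg(encoding)
  n <- length(w$samples)
  spec <- switch(encoding,
    pcm16   = list(tag = WAVE_FORMAT_PCM, bits = 16L),
    float32 = list(tag = WAVE_FORMAT_IEEE_FLOAT, bits = 32L),
    float64 = list(tag = WAVE_FORMAT_IEEE_FLOAT, bits = 64L))
  bytes_per <- spec$bits %/% 8L
  data_size <- n * bytes_per

  con <- file(path, "wb")
  on.exit(close(con))
  wr_u32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wr_u16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")

  writeChar("RIFF", con, eos = NULL)
  wr_u32(36L + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  wr_u32(16L)
  wr_u16(spec$tag)
  wr_u16(1L)                                  # mono
  wr_u32(round(w$rate))
  wr_u32(round(w$rate) * bytes_per)           # byte rate
  wr_u16(bytes_per)                           # block align
  wr_u16(spec$bits)
  writeChar("data", con, eos = NULL)
  wr_u32(data_size)

  if (encoding == "pcm16") {
    q <- round(w$samples * 32768)
    q <- pmin(pmax(q, -32768), 32767)
    writeBin(as.integer(q), con, size = 2L, endian = "little")
  } else {
    writeBin(as.double(w$samples), con, size = bytes_per, endian = "little")
  }
  invisible(path)
}
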