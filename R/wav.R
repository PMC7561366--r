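# Minimal RIFF/WAVE reader and writer for PCM audio.
#
# Supports uncompressed integer PCM (16/24/32-bit), 8-bit unsigned PCM, and
# 32-bit IEEE float, mono or multi-channel. Samples are exchanged as doubles
# in [-1, 1]. Only the chunks needed for analysis ("fmt " and "data") are
# interpreted; others are skipped.

WAVE_FORMAT_PCM <- 1L
WAVE_FORMAT_IEEE_FLOAT <- 3L
WAVE_FORMAT_EXTENSIBLE <- 65534L

#' Read a WAV file
#'
#' Reads an uncompressed RIFF/WAVE file and returns the samples as a numeric
#' matrix scaled to \code{[-1, 1]} (one column per channel).
#'
#' @param path Path to a WAV file.
#' @return A list with \code{samples} (matrix, frames x channels),
#'   \code{sample_rate_hz}, \code{bit_depth}, and \code{n_channels}.
#' @export
read_wav <- function(path) {
  .assert(file.exists(path), "WAV file does not exist: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  u16 <- function() readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                            endian = "little")
  u32 <- function() {
    lo <- u16(); hi <- u16()
    lo + hi * 65536
  }
  tag <- function() rawToChar(readBin(con, "raw", 4L))

  .assert(identical(tag(), "RIFF"), "not a RIFF file: %s", path)
  u32()  # RIFF size, unused
  .assert(identical(tag(), "WAVE"), "not a WAVE file: %s", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id_raw <- readBin(con, "raw", 4L)
    if (length(id_raw) < 4L) break
    id <- rawToChar(id_raw)
    size <- u32()
    if (id == "fmt ") {
      fmt <- list(
        format = u16(), n_channels = u16(), sample_rate = u32(),
        byte_rate = u32(), block_align = u16(), bits = u16()
      )
      extra <- size - 16L
      if (fmt$format == WAVE_FORMAT_EXTENSIBLE && extra >= 8L) {
        u16()                      # cbSize
        u16()                      # valid bits
        u32()                      # channel mask
        fmt$format <- u16()        # subformat GUID starts with the format code
        extra <- extra - 12L
      }
      if (extra > 0L) readBin(con, "raw", extra)
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size + (size %% 2L))  # skip, chunks are word-aligned
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  .assert(!is.null(fmt), "no fmt chunk in WAV file: %s", path)
  .assert(!is.null(data_raw), "no data chunk in WAV file: %s", path)
  .assert(fmt$format %in% c(WAVE_FORMAT_PCM, WAVE_FORMAT_IEEE_FLOAT),
          "unsupported WAV format code %d in %s", fmt$format, path)
  .assert(length(data_raw) > 0L, "zero-length audio data in %s", path)

  bytes_per <- fmt$bits %/% 8L
  n_total <- length(data_raw) %/% bytes_per
  x <- if (fmt$format == WAVE_FORMAT_IEEE_FLOAT) {
    .assert(fmt$bits == 32L, "only 32-bit float WAV supported (%s)", path)
    readBin(data_raw, "double", n_total, size = 4L, endian = "little")
  } else if (fmt$bits == 8L) {
    (as.numeric(readBin(data_raw, "integer", n_total, size = 1L,
                        signed = FALSE)) - 128) / 128
  } else if (fmt$bits == 16L) {
    readBin(data_raw, "integer", n_total, size = 2L, signed = TRUE,
            endian = "little") / 32768
  } else if (fmt$bits == 24L) {
    b <- as.integer(data_raw[seq_len(n_total * 3L)])
    dim(b) <- c(3L, n_total)
    v <- b[1L, ] + b[2L, ] * 256 + b[3L, ] * 65536
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else if (fmt$bits == 32L) {
    readBin(data_raw, "integer", n_total, size = 4L, endian = "little") /
      2147483648
  } else {
    stop(sprintf("unsupported WAV bit depth %d in %s", fmt$bits, path),
         call. = FALSE)
  }

  nc <- fmt$n_channels
  n_frames <- n_total %/% nc
  samples <- matrix(x[seq_len(n_frames * nc)], ncol = nc, byrow = TRUE)
  list(samples = samples, sample_rate_hz = fmt$sample_rate,
       bit_depth = fmt$bits, n_channels = nc)
}

#' Write a WAV file
#'
#' Writes samples in \code{[-1, 1]} to an uncompressed PCM WAV file.
#'
#' @param samples Numeric vector (mono) or matrix (frames x channels).
#' @param path Output path.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param bit_depth One of 16, 24, or 32 (integer PCM).
#' @return \code{path}, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate_hz = 48000L,
                      bit_depth = 24L) {
  .assert(bit_depth %in% c(16L, 24L, 32L), "bit_depth must be 16, 24 or 32")
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1L)
  nc <- ncol(samples)
  x <- as.vector(t(samples))               # interleave channels
  x <- pmin(pmax(x, -1), 1)
  full <- 2^(bit_depth - 1L)
  v <- round(x * full)
  v <- pmin(v, full - 1)

  bytes_per <- bit_depth %/% 8L
  block_align <- nc * bytes_per
  data_size <- length(v) * bytes_per

  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(n) writeBin(as.integer(n), con, size = 2L,
                              endian = "little")
  w32 <- function(n) {
    writeBin(as.integer(c(n %% 65536, n %/% 65536)), con, size = 2L,
             endian = "little")
  }
  writeChar("RIFF", con, eos = NULL)
  w32(36 + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w32(16); w16(WAVE_FORMAT_PCM); w16(nc); w32(sample_rate_hz)
  w32(sample_rate_hz * block_align); w16(block_align); w16(bit_depth)
  writeChar("data", con, eos = NULL)
  w32(data_size)
  if (bit_depth == 24L) {
    u <- ifelse(v < 0, v + 16777216, v)
    b <- rbind(u %% 256, (u %/% 256) %% 256, u %/% 65536)
    writeBin(as.raw(as.integer(b)), con)
  } else {
    writeBin(as.integer(v), con, size = bytes_per, endian = "little")
  }
  invisible(path)
}
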