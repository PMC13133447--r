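# Minimal RIFF/WAVE PCM I/O (mono or multichannel, 16/24/32-bit integer
# PCM and 32-bit IEEE float). Only what the pipeline needs: read a stimulus
# waveform, write one for tests and examples.

#' Read a PCM WAV file
#'
#' @param path file path.
#' @param channel which channel to return for multichannel files (default
#'   averages to mono when `channel = NULL`).
#' @return an [audio_track()] with samples scaled to `[-1, 1]`.
#' @export
read_wav <- function(path, channel = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        format     = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        channels   = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        rate       = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate  = readBin(con, "integer", 1, 4, endian = "little"),
        block      = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits       = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE))
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("missing fmt/data chunk in ", path, call. = FALSE)

  bytes <- fmt$bits %/% 8
  n_tot <- length(data_raw) %/% bytes
  if (fmt$format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "numeric", n_tot, 4, endian = "little")
  } else if (fmt$format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", n_tot, 2, signed = TRUE,
                 endian = "little") / 32768
  } else if (fmt$format == 1L && fmt$bits == 24L) {
    m <- matrix(as.integer(data_raw), nrow = 3)
    v <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else if (fmt$format == 1L && fmt$bits == 32L) {
    x <- readBin(data_raw, "integer", n_tot, 4, endian = "little") / 2147483648
  } else stop("unsupported WAV encoding (format ", fmt$format, ", ",
              fmt$bits, " bit)", call. = FALSE)

  if (fmt$channels > 1L) {
    x <- matrix(x, nrow = fmt$channels)
    x <- if (is.null(channel)) colMeans(x) else x[channel, ]
  }
  audio_track(x, fmt$rate)
}

#' Write a mono PCM WAV file
#'
#' @param audio an [audio_track()] with samples in `[-1, 1]`.
#' @param path output path.
#' @param bits 16 (integer PCM) or 32 (IEEE float).
#' @export
write_wav <- function(audio, path, bits = 16) {
  stopifnot(inherits(audio, "audio_track"), bits %in% c(16, 32))
  x <- audio$samples
  con <- file(path, "wb")
  on.exit(close(con))
  bytes <- bits / 8
  data_len <- length(x) * bytes
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_len), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(if (bits == 16) 1L else 3L, 1L), con, 2, endian = "little")
  writeBin(as.integer(c(audio$rate, audio$rate * bytes)), con, 4, endian = "little")
  writeBin(as.integer(c(bytes, bits)), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_len), con, 4, endian = "little")
  if (bits == 16) {
    writeBin(as.integer(pmax(pmin(round(x * 32768), 32767), -32768)),
             con, 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, 4, endian = "little")
  }
  invisible(path)
}
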