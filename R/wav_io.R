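## Minimal RIFF/WAVE PCM reader and writer.
##
## Supports reading 8/16/24-bit integer PCM and 32-bit IEEE float, writing
## 16-bit PCM. Integer samples are scaled by the full-scale constant of the
## bit depth (2^(bits-1)), so 16-bit -32768 maps exactly to -1.0 and the
## 16-bit round trip is bit-exact.

#' Read a PCM WAV file
#'
#' @param path path to a RIFF/WAVE file (8/16/24-bit integer PCM or 32-bit
#'   float). Multi-channel input is averaged to mono with a message.
#' @return A [waveform] with `source_id` set to the file's base name.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        format    = readBin(raw[1:2],  "integer", 1L, 2L, signed = FALSE, endian = "little"),
        channels  = readBin(raw[3:4],  "integer", 1L, 2L, signed = FALSE, endian = "little"),
        rate      = readBin(raw[5:8],  "integer", 1L, 4L, endian = "little"),
        bits      = readBin(raw[15:16], "integer", 1L, 2L, signed = FALSE, endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))  # skip, honouring padding
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("corrupt WAV (missing fmt/data chunk): ", path)

  x <- switch(as.character(fmt$format),
    "1" = switch(as.character(fmt$bits),
      "8"  = (as.numeric(readBin(data_raw, "integer", length(data_raw), 1L,
                                 signed = FALSE)) - 128) / 128,
      "16" = readBin(data_raw, "integer", length(data_raw) / 2L, 2L,
                     signed = TRUE, endian = "little") / 32768,
      "24" = read_pcm24(data_raw) / 8388608,
      stop("unsupported PCM bit depth: ", fmt$bits)),
    "3" = {
      if (fmt$bits != 32L) stop("unsupported float bit depth: ", fmt$bits)
      readBin(data_raw, "double", length(data_raw) / 4L, 4L, endian = "little")
    },
    stop("unsupported WAV encoding code: ", fmt$format))

  if (fmt$channels > 1L) {
    message("averaging ", fmt$channels, " channels to mono: ", basename(path))
    x <- colMeans(matrix(x, nrow = fmt$channels))
  }
  waveform(pmin(1, pmax(-1, x)), fmt$rate, basename(path))
}

read_pcm24 <- function(raw) {
  n <- length(raw) %/% 3L
  b <- matrix(as.integer(raw[seq_len(3L * n)]), nrow = 3L)
  v <- b[1L, ] + 256 * b[2L, ] + 65536 * b[3L, ]
  ifelse(v >= 8388608, v - 16777216, v)
}

#' Write a waveform as 16-bit PCM WAV
#'
#' @param w a [waveform].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  ints <- as.integer(pmin(32767, pmax(-32768, round(w$samples * 32768))))
  n_bytes <- length(ints) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")              # PCM
  writeBin(1L, con, size = 2L, endian = "little")              # mono
  writeBin(as.integer(round(w$rate)), con, size = 4L, endian = "little")
  writeBin(as.integer(round(w$rate)) * 2L, con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")              # block align
  writeBin(16L, con, size = 2L, endian = "little")             # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4L, endian = "little")
  writeBin(ints, con, size = 2L, endian = "little")
  invisible(path)
}

#' Resample a waveform to a new rate
#'
#' Polyphase rational resampling (via `signal::resample`); a rate change is
#' reported with a message so silent mismatches cannot slip through.
#'
#' @param w a [waveform].
#' @param new_rate target rate in Hz.
#' @return A [waveform] at `new_rate`.
#' @export
resample_wave <- function(w, new_rate) {
  stopifnot(inherits(w, "waveform"))
  stopifnot_scalar(new_rate, "new_rate", positive = TRUE)
  if (new_rate == w$rate) return(w)
  message(sprintf("resampling %s: %g Hz -> %g Hz", w$source_id, w$rate, new_rate))
  frac <- as.integer(c(new_rate, w$rate) / gcd_int(new_rate, w$rate))
  y <- signal::resample(w$samples, frac[1L], frac[2L])
  waveform(pmin(1, pmax(-1, y)), new_rate, w$source_id)
}

gcd_int <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- b; b <- a %% b; a <- t }
  a
}
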