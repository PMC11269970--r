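#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader supporting 16-bit PCM and 32-bit IEEE float
#' mono files, the two encodings written by [write_wav()]. Samples are
#' returned as doubles in \[-1, 1\].
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (numeric vector) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in ", path)
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", sz)
      fmt <- list(
        format = readBin(raw_fmt[1:2], "integer", 1, 2, endian = "little", signed = FALSE),
        channels = readBin(raw_fmt[3:4], "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate = readBin(raw_fmt[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw_fmt[15:16], "integer", 1, 2, endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("data chunk before fmt chunk in ", path)
      if (fmt$channels != 1L) stop("only mono WAV supported, got ", fmt$channels, " channels")
      if (fmt$format == 1L && fmt$bits == 16L) {
        n <- sz %/% 2L
        raw <- readBin(con, "integer", n, 2, signed = TRUE, endian = "little")
        samples <- raw / 32768
      } else if (fmt$format == 3L && fmt$bits == 32L) {
        n <- sz %/% 4L
        samples <- readBin(con, "double", n, 4, endian = "little")
      } else {
        stop("unsupported WAV encoding (format ", fmt$format, ", ", fmt$bits, " bit)")
      }
      return(list(samples = samples, sample_rate = fmt$sample_rate))
    } else {
      readBin(con, "raw", sz + (sz %% 2L))  # skip, chunks are word-aligned
    }
  }
}

#' Write a mono WAV file
#'
#' @param samples Numeric vector in \[-1, 1\]; values outside are clipped
#'   for 16-bit PCM output.
#' @param path Output path.
#' @param sample_rate Sampling rate in Hz.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate = 16000L, bits = 16L) {
  stopifnot(bits %in% c(16L, 32L))
  n <- length(samples)
  bytes_per <- bits %/% 8L
  data_sz <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_sz), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  fmt_code <- if (bits == 16L) 1L else 3L
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")  # mono
  writeBin(as.integer(sample_rate), con, 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, 4, endian = "little")
  if (bits == 16L) {
    q <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
    writeBin(q, con, 2, endian = "little")
  } else {
    writeBin(as.double(samples), con, 4, endian = "little")
  }
  invisible(path)
}
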