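#' @useDynLib bowelspot, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Fixed pipeline constants: 16 kHz audio, 10-second analysis segments,
# 25 ms frame window, 10 ms frame stride.
FS <- 16000L
SEGMENT_SECONDS <- 10
SEGMENT_SAMPLES <- 160000L
FRAME_WINDOW <- 400L   # gamma = 25 ms * fs
FRAME_STRIDE <- 160L   # sigma = 10 ms * fs
N_MELS <- 128L
N_FRAMES <- 998L       # frames per full 10-s segment
PADDED_FRAMES <- 1056L

#' Wrap a waveform as a recording
#'
#' @param samples Numeric waveform at 16 kHz.
#' @param participant,channel Identifiers.
#' @param sample_rate Must be 16000; other rates are rejected rather
#'   than resampled.
#' @return A `bs_recording` list.
#' @export
bs_recording <- function(samples, participant = "P1", channel = "CH1",
                         sample_rate = 16000L) {
  if (sample_rate != FS) {
    stop("recordings must be sampled at 16 kHz, got ", sample_rate, " Hz")
  }
  structure(list(samples = as.numeric(samples),
                 participant = participant, channel = channel,
                 n_samples = length(samples)),
            class = "bs_recording")
}

#' High-pass filter a recording
#'
#' Second-order (biquad) high-pass at 60 Hz to remove signal offset and
#' low-frequency rumble before spectrogram extraction. RBJ cookbook
#' design with Q = 1/sqrt(2), applied causally.
#'
#' @param recording A `bs_recording` or plain numeric waveform.
#' @param cutoff Cutoff frequency in Hz.
#' @return Same type as the input, filtered, identical length.
#' @export
highpass_filter <- function(recording, cutoff = 60) {
  x <- if (inherits(recording, "bs_recording")) recording$samples else recording
  if (length(x) == 0) stop("cannot filter an empty waveform")
  co <- biquad_highpass_coef(cutoff, FS)
  y <- as.numeric(signal::filter(co$b, co$a, x))
  if (inherits(recording, "bs_recording")) {
    recording$samples <- y
    recording
  } else {
    y
  }
}

# RBJ audio-EQ-cookbook high-pass biquad coefficients.
biquad_highpass_coef <- function(cutoff, fs, Q = 1 / sqrt(2)) {
  w0 <- 2 * pi * cutoff / fs
  alpha <- sin(w0) / (2 * Q)
  cw <- cos(w0)
  b <- c((1 + cw) / 2, -(1 + cw), (1 + cw) / 2)
  a <- c(1 + alpha, -2 * cw, 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Split a recording into non-overlapping 10-second segments
#'
#' The final partial segment, if any, is zero-padded to the full 10 s;
#' its true length is kept so downstream predictions can be truncated
#' back to real samples.
#'
#' @param recording A `bs_recording` or numeric waveform.
#' @return List of segments, each a list with `samples` (length 160000),
#'   `start_sample` (0-based absolute offset), `index` (1-based) and
#'   `n_real` (samples before padding).
#' @export
segment_audio <- function(recording) {
  x <- if (inherits(recording, "bs_recording")) recording$samples else as.numeric(recording)
  n <- length(x)
  if (n == 0) return(list())
  n_seg <- ceiling(n / SEGMENT_SAMPLES)
  lapply(seq_len(n_seg), function(i) {
    lo <- (i - 1L) * SEGMENT_SAMPLES
    hi <- min(n, lo + SEGMENT_SAMPLES)
    s <- x[(lo + 1L):hi]
    n_real <- length(s)
    if (n_real < SEGMENT_SAMPLES) s <- c(s, numeric(SEGMENT_SAMPLES - n_real))
    list(samples = s, start_sample = lo, index = i, n_real = n_real)
  })
}

#' Read an Audacity-style label track
#'
#' Tab-separated `start_seconds<TAB>end_seconds<TAB>label` with labels
#' `bs` or `bs_tentative`. Seconds are converted to sample indices by
#' `round(t * 16000)`.
#'
#' @param path Path to the TSV file.
#' @return A sorted `bs_events` table.
#' @export
read_labels <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(bs_events())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad)) stop("malformed label lines (need 3 tab-separated fields): ",
                        paste(bad, collapse = ", "))
  start_s <- as.numeric(vapply(parts, `[[`, "", 1L))
  end_s <- as.numeric(vapply(parts, `[[`, "", 2L))
  label <- vapply(parts, `[[`, "", 3L)
  rev_lines <- which(!(end_s > start_s))
  if (length(rev_lines)) {
    stop("reversed or empty intervals at label lines: ",
         paste(rev_lines, collapse = ", "))
  }
  ev <- data.frame(onset = round(start_s * FS), offset = round(end_s * FS),
                   tentative = grepl("tentative", label, fixed = TRUE))
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  if (nrow(ev) > 1) {
    ov <- which(ev$onset[-1] < ev$offset[-nrow(ev)])
    if (length(ov)) {
      stop("overlapping events at label lines (after sorting): ",
           paste(ov, collapse = ", "))
    }
  }
  class(ev) <- c("bs_events", "data.frame")
  ev
}

#' Write an event table as an Audacity-style label track
#'
#' @param events A `bs_events` table.
#' @param path Output path.
#' @param label Base label for non-tentative events.
#' @return `path`, invisibly.
#' @export
write_labels <- function(events, path, label = "bs") {
  labels <- ifelse(events$tentative, paste0(label, "_tentative"), label)
  lines <- sprintf("%.6f\t%.6f\t%s",
                   events$onset / FS, events$offset / FS, labels)
  writeLines(lines, path)
  invisible(path)
}
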