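# Log-Mel spectrogram front end.
#
# Framing: 25 ms Hann window (400 samples), 10 ms stride (160 samples),
# so a full 10-s segment yields floor((160000 - 400)/160) + 1 = 998
# frames. The FFT size is 512 (window zero-padded), the Mel filterbank
# has 128 triangular filters on the HTK Mel scale spanning 0-8000 Hz,
# and log compression uses log(power + 1e-6). These conventions alter
# spectrogram values but not shapes; they are fixed here and documented
# in the methods vignette.

N_FFT <- 512L
LOG_OFFSET <- 1e-6

mel_hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# 128 x 257 triangular Mel filterbank, cached per session.
.mel_cache <- new.env(parent = emptyenv())

mel_filterbank <- function(n_mels = N_MELS, n_fft = N_FFT, fmin = 0, fmax = FS / 2) {
  key <- paste(n_mels, n_fft, fmin, fmax, sep = "_")
  if (!is.null(.mel_cache[[key]])) return(.mel_cache[[key]])
  n_bins <- n_fft %/% 2L + 1L
  freqs <- seq(0, FS / 2, length.out = n_bins)
  mel_pts <- seq(mel_hz_to_mel(fmin), mel_hz_to_mel(fmax), length.out = n_mels + 2L)
  hz_pts <- mel_mel_to_hz(mel_pts)
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- hz_pts[m]; mid <- hz_pts[m + 1]; hi <- hz_pts[m + 2]
    up <- (freqs - lo) / (mid - lo)
    down <- (hi - freqs) / (hi - mid)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  .mel_cache[[key]] <- fb
  fb
}

#' Log-Mel spectrogram of one 10-second segment
#'
#' @param segment A segment from [segment_audio()] or a numeric vector
#'   of exactly 160000 samples.
#' @return Matrix of 128 Mel bins x 998 frames with attributes
#'   `n_real_frames` and class `bs_spectrogram`.
#' @export
logmel_spectrogram <- function(segment) {
  x <- if (is.list(segment)) segment$samples else as.numeric(segment)
  if (length(x) != SEGMENT_SAMPLES) {
    stop("segment must have exactly ", SEGMENT_SAMPLES, " samples, got ",
         length(x))
  }
  idx <- outer(seq_len(FRAME_WINDOW), (seq_len(N_FRAMES) - 1L) * FRAME_STRIDE, "+")
  frames <- matrix(x[idx], nrow = FRAME_WINDOW)
  w <- hann_window(FRAME_WINDOW)
  frames <- frames * w
  padded <- rbind(frames, matrix(0, N_FFT - FRAME_WINDOW, N_FRAMES))
  spec <- stats::mvfft(padded)[seq_len(N_FFT %/% 2L + 1L), , drop = FALSE]
  power <- Mod(spec)^2
  mel <- mel_filterbank() %*% power
  out <- log(mel + LOG_OFFSET)
  attr(out, "n_real_frames") <- N_FRAMES
  class(out) <- c("bs_spectrogram", class(out))
  out
}

# Periodic Hann window, as used by STFT implementations.
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)

#' Zero-pad a spectrogram along the time axis to 1056 bins
#'
#' The padded width matches the input size used by 10-s-clip AudioSet
#' pretraining of the encoder. Original frames are preserved; the pad
#' value 0 equals the post-standardization mean, so standardize before
#' padding.
#'
#' @param spec A spectrogram matrix (`n_frames <= 1056`).
#' @param target Target number of time bins.
#' @return Padded matrix with `n_real_frames` attribute preserved.
#' @export
pad_time <- function(spec, target = PADDED_FRAMES) {
  nf <- ncol(spec)
  if (nf > target) stop("spectrogram has ", nf, " frames, more than the ",
                        target, "-bin target")
  n_real <- attr(spec, "n_real_frames")
  if (is.null(n_real)) n_real <- nf
  if (nf < target) {
    spec <- cbind(spec, matrix(0, nrow(spec), target - nf))
  }
  attr(spec, "n_real_frames") <- n_real
  class(spec) <- c("bs_spectrogram", "matrix", "array")
  spec
}

#' Standardize a spectrogram to zero mean and unit variance
#'
#' Statistics are computed over the unpadded region only (per
#' spectrogram, not corpus-level). A constant input returns all zeros.
#'
#' @param spec A spectrogram matrix.
#' @return Standardized matrix of the same shape.
#' @export
standardize_spectrogram <- function(spec) {
  n_real <- attr(spec, "n_real_frames")
  if (is.null(n_real)) n_real <- ncol(spec)
  region <- spec[, seq_len(n_real), drop = FALSE]
  mu <- mean(region)
  sd_ <- stats::sd(as.vector(region))
  out <- spec
  if (!is.finite(sd_) || sd_ == 0) {
    out[, seq_len(n_real)] <- 0
  } else {
    out[, seq_len(n_real)] <- (region - mu) / sd_
  }
  attr(out, "n_real_frames") <- n_real
  out
}

# Full front end: segment samples -> standardized, padded 128 x 1056.
segment_features <- function(segment) {
  pad_time(standardize_spectrogram(logmel_spectrogram(segment)))
}
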