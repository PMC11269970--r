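# Frame-mask supervision: convert sample-resolution annotations into
# per-frame binary BS/NBS labels.
#
# A frame k (0-based) spans samples [k*160, k*160 + 400). It is labeled
# BS when its total overlap with annotated events reaches at least half
# the frame length (lambda * gamma = 200 samples, frame-relative
# overlap). Every guideline-conforming event (>= 18 ms = 288 samples)
# is then guaranteed at least one positive frame: the best-aligned
# frame overlaps it by >= 15 ms, 60% of the frame.

OVERLAP_LAMBDA <- 0.5

#' Enforce the annotation guidelines on an event list
#'
#' Consecutive events with a sound-to-sound interval below 100 ms are
#' merged (iteratively, left to right) into a single event; events
#' shorter than 18 ms after merging are removed. A merged event is
#' tentative only if all of its constituents were tentative.
#'
#' @param events A sorted `bs_events` table.
#' @param min_duration Minimum duration in seconds.
#' @param max_gap Merging gap in seconds.
#' @return A guideline-conforming `bs_events` table.
#' @export
enforce_guidelines <- function(events, min_duration = 0.018, max_gap = 0.1) {
  if (nrow(events) > 1 && is.unsorted(events$onset)) {
    stop("events must be sorted by onset")
  }
  gap_samples <- round(max_gap * FS)
  min_samples <- round(min_duration * FS)
  if (nrow(events) > 0) {
    merged <- events[1, , drop = FALSE]
    for (j in seq_len(nrow(events))[-1]) {
      last <- nrow(merged)
      if (events$onset[j] - merged$offset[last] < gap_samples) {
        merged$offset[last] <- max(merged$offset[last], events$offset[j])
        merged$tentative[last] <- merged$tentative[last] && events$tentative[j]
      } else {
        merged <- rbind(merged, events[j, , drop = FALSE])
      }
    }
    merged <- merged[merged$offset - merged$onset >= min_samples, , drop = FALSE]
    rownames(merged) <- NULL
    class(merged) <- c("bs_events", "data.frame")
    merged
  } else {
    events
  }
}

#' Convert events to a per-frame binary mask for one segment
#'
#' Tentative events are treated as the NULL class and must be excluded
#' (the default drops them here). Events straddling the segment
#' boundaries contribute their in-segment part. The returned mask has
#' 998 real frames zero-padded to 1056.
#'
#' @param events A `bs_events` table in absolute sample coordinates.
#' @param segment_start Absolute start sample (0-based) of the segment.
#' @param keep_tentative Keep tentative events as positives (for
#'   sensitivity analyses); default drops them.
#' @param pad Pad the mask to 1056 frames (padding frames are 0).
#' @return Integer vector of 0/1 labels with attribute `n_real_frames`.
#' @export
events_to_mask <- function(events, segment_start = 0, keep_tentative = FALSE,
                           pad = TRUE) {
  if (!keep_tentative) events <- events[!events$tentative, , drop = FALSE]
  ev <- clip_events(events, segment_start, segment_start + SEGMENT_SAMPLES)
  mask <- integer(N_FRAMES)
  if (nrow(ev) > 0) {
    starts <- (seq_len(N_FRAMES) - 1L) * FRAME_STRIDE
    ends <- starts + FRAME_WINDOW
    overlap <- numeric(N_FRAMES)
    for (j in seq_len(nrow(ev))) {
      overlap <- overlap + pmax(0, pmin(ends, ev$offset[j]) - pmax(starts, ev$onset[j]))
    }
    mask[overlap >= OVERLAP_LAMBDA * FRAME_WINDOW] <- 1L
  }
  if (pad) mask <- c(mask, integer(PADDED_FRAMES - N_FRAMES))
  attr(mask, "n_real_frames") <- N_FRAMES
  mask
}

#' Fraction of BS frames in a set of masks
#'
#' The BS ratio over spectrogram time bins: positive frames divided by
#' total frames, counted over the unpadded region only.
#'
#' @param masks A mask vector or list of mask vectors from
#'   [events_to_mask()].
#' @return Fraction in \[0, 1\].
#' @export
mask_positive_rate <- function(masks) {
  if (!is.list(masks)) masks <- list(masks)
  if (length(masks) == 0) stop("no masks supplied")
  pos <- 0; tot <- 0
  for (m in masks) {
    n_real <- attr(m, "n_real_frames")
    if (is.null(n_real)) n_real <- length(m)
    pos <- pos + sum(m[seq_len(n_real)])
    tot <- tot + n_real
  }
  pos / tot
}
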