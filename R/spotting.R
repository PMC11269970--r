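# Decode frame-level predictions into sample-resolution events.
#
# Each maximal run of consecutive BS frames becomes one event whose
# extent is the union of the overlapping frame spans: onset at the
# first frame's start, offset at the last frame's end. A single
# positive frame therefore yields a 400-sample (25 ms) event — the
# temporal resolution of the spotter.

#' Convert a frame mask to events
#'
#' @param mask Binary frame vector for one segment with padded frames
#'   already stripped (at most 998 frames).
#' @param segment_start Absolute start sample of the segment (0-based).
#' @return A `bs_events` table in absolute sample coordinates.
#' @export
mask_to_events <- function(mask, segment_start = 0) {
  if (length(mask) > N_FRAMES) {
    stop("mask has ", length(mask), " frames; strip padding first (max ",
         N_FRAMES, ")")
  }
  decode_frame_runs(which(as.numeric(mask) > 0) - 1L, segment_start)
}

# Decode runs of 0-based frame indices (absolute within one stride
# grid) into events. Because the frame window (400 samples) exceeds
# two strides (320), spans of runs separated by a single negative
# frame can overlap; the union of spans merges them into one event.
decode_frame_runs <- function(frames, start_sample = 0) {
  if (length(frames) == 0) return(bs_events())
  breaks <- which(diff(frames) > 1L)
  run_start <- frames[c(1L, breaks + 1L)]
  run_end <- frames[c(breaks, length(frames))]
  onset <- start_sample + run_start * FRAME_STRIDE
  offset <- start_sample + run_end * FRAME_STRIDE + FRAME_WINDOW
  merged <- merge_intervals(onset, offset)
  bs_events(merged$onset, merged$offset)
}

# Union of possibly-overlapping sorted intervals.
merge_intervals <- function(onset, offset) {
  keep_on <- onset[1]; out_on <- numeric(0); out_off <- numeric(0)
  cur_off <- offset[1]
  for (i in seq_along(onset)[-1]) {
    if (onset[i] <= cur_off) {
      cur_off <- max(cur_off, offset[i])
    } else {
      out_on <- c(out_on, keep_on); out_off <- c(out_off, cur_off)
      keep_on <- onset[i]; cur_off <- offset[i]
    }
  }
  list(onset = c(out_on, keep_on), offset = c(out_off, cur_off))
}

#' Spot bowel-sound events in a whole recording
#'
#' Runs the full pipeline: high-pass filter, 10-s segmentation,
#' standardized padded log-Mel spectrograms, model forward pass,
#' argmax per frame, then decoding of the per-segment masks
#' concatenated in time order — so detections touching a 10-second
#' boundary merge into one event rather than splitting. Offsets are
#' clipped to the recording length.
#'
#' @param model An `effunet` model (or a function `mask(segment)` used
#'   as an oracle predictor in tests).
#' @param recording A `bs_recording`.
#' @param merge_across_segments Merge detections across segment
#'   boundaries (default) or decode each segment independently.
#' @return A `bs_events` table of spotted events.
#' @export
spot_recording <- function(model, recording, merge_across_segments = TRUE) {
  rec <- highpass_filter(recording)
  segments <- segment_audio(rec)
  n <- recording$n_samples
  all_frames <- integer(0)
  frame_onsets <- numeric(0)
  frame_offsets <- numeric(0)
  per_segment <- list()
  for (seg in segments) {
    if (is.function(model)) {
      mask <- model(seg)
    } else {
      spec <- segment_features(seg)
      mask <- effunet_forward(model, spec)$mask
    }
    mask <- mask[seq_len(N_FRAMES)]  # strip padded frames
    pos <- which(as.numeric(mask) > 0) - 1L
    gidx <- (seg$index - 1L) * N_FRAMES + pos
    all_frames <- c(all_frames, gidx)
    frame_onsets <- c(frame_onsets, seg$start_sample + pos * FRAME_STRIDE)
    frame_offsets <- c(frame_offsets, seg$start_sample + pos * FRAME_STRIDE + FRAME_WINDOW)
    if (!merge_across_segments) {
      per_segment[[length(per_segment) + 1L]] <-
        mask_to_events(mask, seg$start_sample)
    }
  }
  ev <- if (merge_across_segments) {
    if (length(all_frames) == 0) bs_events() else {
      o <- order(all_frames)
      decode_runs_global(all_frames[o], frame_onsets[o], frame_offsets[o])
    }
  } else {
    tmp <- if (length(per_segment)) do.call(rbind, per_segment) else bs_events()
    rownames(tmp) <- NULL
    class(tmp) <- c("bs_events", "data.frame")
    tmp
  }
  if (nrow(ev) > 0) {
    ev$offset <- pmin(ev$offset, n)
    ev <- ev[ev$offset > ev$onset, , drop = FALSE]
    class(ev) <- c("bs_events", "data.frame")
  }
  ev
}

# Runs over global frame indices; consecutive indices count as one run
# even across a segment boundary (the last frame of a segment and the
# first of the next are adjacent in time). Overlapping run spans merge.
decode_runs_global <- function(frames, onsets, offsets) {
  breaks <- which(diff(frames) > 1L)
  run_start <- c(1L, breaks + 1L)
  run_end <- c(breaks, length(frames))
  merged <- merge_intervals(onsets[run_start], offsets[run_end])
  bs_events(merged$onset, merged$offset)
}
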