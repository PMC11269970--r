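# Evaluation suite for sparse-event spotting in continuous audio:
# samplewise precision/recall, the two-class segment timing-error
# taxonomy (insertion/deletion/fragmentation/merge/overfill/underfill),
# SNR- and duration-conditioned metrics, the class-imbalance (BS-ratio)
# sweep, and the median/IQR summary conventions.

#' Samplewise precision, recall and F1
#'
#' Predictions and annotations are compared sample by sample (at
#' 16 kHz, one sample is about 0.06 ms), independently of the spotter
#' resolution. Computed with interval arithmetic; equal to the count
#' obtained by rasterizing both event sets. Tentative truth events are
#' either treated as NULL (`"null"`: any prediction overlapping them
#' counts as a false positive — the conservative default) or removed
#' from scoring altogether (`"ignore"`).
#'
#' @param truth,pred `bs_events` tables (sorted, non-overlapping).
#' @param n_samples Length of the scored stream in samples.
#' @param tentative `"null"` or `"ignore"`.
#' @return List with `tp`, `fp`, `fn` (sample counts), `precision`,
#'   `recall`, `f1` (0 when undefined, flagged by
#'   `precision_defined`).
#' @export
samplewise_prf <- function(truth, pred, n_samples,
                           tentative = c("null", "ignore")) {
  tentative <- match.arg(tentative)
  validate_events(truth, n_samples)
  validate_events(pred, n_samples)
  tent <- truth[truth$tentative, , drop = FALSE]
  truth <- truth[!truth$tentative, , drop = FALSE]
  tp <- interval_intersection(truth, pred)
  fp <- events_duration(pred) - tp
  if (tentative == "ignore" && nrow(tent) > 0) {
    fp <- fp - interval_intersection(tent, pred)
  }
  fn <- events_duration(truth) - tp
  prf_from_counts(tp, fp, fn)
}

prf_from_counts <- function(tp, fp, fn) {
  precision_defined <- (tp + fp) > 0
  precision <- if (precision_defined) tp / (tp + fp) else 0
  recall <- if ((tp + fn) > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       f1 = f1, precision_defined = precision_defined)
}

#' Two-class segment timing-error decomposition
#'
#' The timeline is cut at every truth and prediction boundary. Each
#' maximal false-positive segment is classified as a merge error if it
#' connects two consecutive truth events (true positives on both
#' sides), an overfill error if it sits at the beginning or end of one
#' event, and an insertion error otherwise. Each maximal
#' false-negative segment is a fragmentation error if it lies within
#' one event (detected on both sides), an underfill error at the
#' beginning or end of an event, and a deletion error otherwise.
#' Insertion + merge + overfill durations equal the total FP duration,
#' and deletion + fragmentation + underfill equal the total FN
#' duration.
#'
#' @param truth,pred `bs_events` tables; tentative truth events are
#'   dropped (NULL class) before scoring.
#' @param n_samples Stream length in samples.
#' @param fs Sampling rate used to convert durations to seconds.
#' @return List of the six error durations in seconds plus `tp`, `fp`,
#'   `fn` sample totals.
#' @export
segment_errors <- function(truth, pred, n_samples, fs = 16000) {
  validate_events(truth, n_samples)
  validate_events(pred, n_samples)
  truth <- truth[!truth$tentative, , drop = FALSE]
  bounds <- sort(unique(c(0, truth$onset, truth$offset,
                          pred$onset, pred$offset, n_samples)))
  in_truth <- function(s) point_in(truth, s)
  in_pred <- function(s) point_in(pred, s)
  err <- c(insertion = 0, deletion = 0, fragmentation = 0,
           merge = 0, overfill = 0, underfill = 0)
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i]; b <- bounds[i + 1L]
    if (b <= a) next
    t_in <- in_truth(a); p_in <- in_pred(a)
    len <- b - a
    if (t_in && p_in) {
      tp <- tp + len
    } else if (!t_in && p_in) {
      fp <- fp + len
      left <- a > 0 && in_truth(a - 1) && in_pred(a - 1)
      right <- b < n_samples && in_truth(b) && in_pred(b)
      kind <- if (left && right) "merge" else if (left || right) "overfill" else "insertion"
      err[kind] <- err[kind] + len
    } else if (t_in && !p_in) {
      fn <- fn + len
      # within the enclosing truth event, is there detection adjacent
      # on either side?
      ev <- truth[truth$onset <= a & truth$offset >= b, , drop = FALSE][1, ]
      left <- a > ev$onset   # segment boundary at a was cut by a pred edge
      right <- b < ev$offset
      kind <- if (left && right) "fragmentation" else if (left || right) "underfill" else "deletion"
      err[kind] <- err[kind] + len
    }
  }
  c(as.list(err / fs), list(tp = tp, fp = fp, fn = fn))
}

# Is sample s (0-based) inside any event?
point_in <- function(ev, s) {
  if (nrow(ev) == 0) return(FALSE)
  i <- findInterval(s, ev$onset)
  i >= 1 && s < ev$offset[i]
}

#' Segment SNR in decibels
#'
#' `10 * log10(P_signal / P_noise)` where `P_signal` is the mean
#' squared amplitude over in-event samples of the segment and
#' `P_noise` the mean squared amplitude over the remaining samples.
#'
#' @param segment A segment from [segment_audio()] or numeric vector.
#' @param events Truth events clipped or clippable to the segment, in
#'   absolute sample coordinates.
#' @param segment_start Absolute start sample of the segment.
#' @return SNR in dB, or `NA` if the segment contains no event samples
#'   (such segments are excluded from the SNR analysis).
#' @export
segment_snr <- function(segment, events, segment_start = NULL) {
  x <- if (is.list(segment)) segment$samples else as.numeric(segment)
  if (is.list(segment) && is.null(segment_start)) segment_start <- segment$start_sample
  if (is.null(segment_start)) segment_start <- 0
  n_real <- if (is.list(segment)) segment$n_real else length(x)
  x <- x[seq_len(n_real)]
  ev <- clip_events(events[!events$tentative, , drop = FALSE],
                    segment_start, segment_start + n_real)
  if (nrow(ev) == 0) return(NA_real_)
  in_event <- logical(n_real)
  for (j in seq_len(nrow(ev))) {
    in_event[(ev$onset[j] + 1L):ev$offset[j]] <- TRUE
  }
  if (!any(in_event) || all(in_event)) return(NA_real_)
  p_sig <- mean(x[in_event]^2)
  p_noise <- mean(x[!in_event]^2)
  10 * log10(p_sig / p_noise)
}

#' Per-segment evaluation table
#'
#' Splits a recording into 10-s segments and scores each against the
#' clipped truth and prediction events: SNR, samplewise tp/fp/fn and
#' the number of truth events overlapping the segment. This is the
#' input to [pr_vs_snr()].
#'
#' @param recording A `bs_recording` (unfiltered or filtered; SNR is
#'   measured on these samples).
#' @param truth,pred `bs_events` tables.
#' @return Data frame with one row per segment.
#' @export
segment_table <- function(recording, truth, pred) {
  segs <- segment_audio(recording)
  rows <- lapply(segs, function(seg) {
    lo <- seg$start_sample; hi <- lo + seg$n_real
    t_clip <- clip_events(truth, lo, hi)
    p_clip <- clip_events(pred, lo, hi)
    r <- samplewise_prf(t_clip, p_clip, seg$n_real)
    data.frame(segment = seg$index, start_sample = lo,
               snr = segment_snr(seg, truth),
               tp = r$tp, fp = r$fp, fn = r$fn,
               n_events = sum(!t_clip$tentative))
  })
  do.call(rbind, rows)
}

#' Precision/recall versus segment SNR
#'
#' For each threshold, pools tp/fp/fn over the segments whose SNR is
#' at or above the threshold (cumulative thresholding) and reports
#' precision, recall and the number of events retained. Segments
#' without events (undefined SNR) are excluded.
#'
#' @param seg_table Output of [segment_table()] (rows from several
#'   recordings may be concatenated).
#' @param thresholds SNR thresholds in dB.
#' @return Data frame with one row per threshold; empty bins are
#'   omitted with a warning.
#' @export
pr_vs_snr <- function(seg_table, thresholds = seq(-20, 8, by = 4)) {
  seg_table <- seg_table[!is.na(seg_table$snr), , drop = FALSE]
  rows <- list()
  for (th in thresholds) {
    sel <- seg_table$snr >= th
    if (!any(sel)) {
      warning("no segments with SNR >= ", th, " dB; point omitted")
      next
    }
    r <- prf_from_counts(sum(seg_table$tp[sel]), sum(seg_table$fp[sel]),
                         sum(seg_table$fn[sel]))
    rows[[length(rows) + 1L]] <- data.frame(
      theta_s = th, n_segments = sum(sel),
      n_events = sum(seg_table$n_events[sel]),
      precision = r$precision, recall = r$recall, f1 = r$f1)
  }
  do.call(rbind, rows)
}

#' Precision/recall restricted to events of a minimum duration
#'
#' Both the annotated and the detected event lists are filtered to
#' events of duration at least `theta_d` before samplewise scoring, so
#' fragmented predictions of long events can drop out of the analysis.
#'
#' @param truth,pred `bs_events` tables.
#' @param n_samples Stream length in samples.
#' @param theta_d Duration threshold in seconds.
#' @return As [samplewise_prf()].
#' @export
pr_vs_duration <- function(truth, pred, n_samples, theta_d = 0) {
  stopifnot(theta_d >= 0)
  min_s <- theta_d * FS
  truth <- truth[truth$offset - truth$onset >= min_s, , drop = FALSE]
  pred <- pred[pred$offset - pred$onset >= min_s, , drop = FALSE]
  samplewise_prf(truth, pred, n_samples)
}

#' Sweep the class imbalance (BS ratio) of the evaluation
#'
#' Resamples frames from one fold's ground truth so the positive
#' fraction equals each requested ratio (`ratio = K / (K + J)` with K
#' positive-truth and J negative-truth frames sampled without
#' replacement), then scores the model's frame predictions on the
#' sample. The model is not retrained; only the evaluation imbalance
#' changes. Unreachable ratios downsample the majority side; if still
#' unreachable the point is skipped with a warning.
#'
#' @param frame_truth,frame_pred Binary frame vectors for the fold.
#' @param ratios Ratios to evaluate (default: 20 log-spaced points
#'   from 1e-5 to 0.6).
#' @param seed Optional seed for the frame sampling.
#' @return Data frame with ratio, K, J, precision and recall per
#'   achieved point.
#' @export
bs_ratio_sweep <- function(frame_truth, frame_pred,
                           ratios = sweep_ratio_grid(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  frame_truth <- as.numeric(frame_truth) > 0
  frame_pred <- as.numeric(frame_pred) > 0
  pos_idx <- which(frame_truth)
  neg_idx <- which(!frame_truth)
  rows <- list()
  for (r in ratios) {
    J <- length(neg_idx)
    K <- round(r * J / (1 - r))
    if (K > length(pos_idx)) {
      K <- length(pos_idx)
      J <- round(K * (1 - r) / r)
    }
    if (K < 1 || J < 1 || J > length(neg_idx)) {
      warning("ratio ", signif(r, 3), " unreachable with ", length(pos_idx),
              " positive and ", length(neg_idx), " negative frames; skipped")
      next
    }
    ks <- if (K == length(pos_idx)) pos_idx else sample(pos_idx, K)
    js <- if (J == length(neg_idx)) neg_idx else sample(neg_idx, J)
    tp <- sum(frame_pred[ks])
    fp <- sum(frame_pred[js])
    fn <- K - tp
    pr <- prf_from_counts(tp, fp, fn)
    rows[[length(rows) + 1L]] <- data.frame(
      bs_ratio = K / (K + J), K = K, J = J,
      precision = pr$precision, recall = pr$recall)
  }
  do.call(rbind, rows)
}

#' Default log-spaced ratio grid from 1e-5 to 0.6
#' @param n Number of grid points.
#' @return Numeric vector.
#' @export
sweep_ratio_grid <- function(n = 20) {
  exp(seq(log(1e-5), log(0.6), length.out = n))
}

#' Convert a BS ratio to an event rate
#'
#' `events/hour = ratio * 3600 / mean_event_duration`; a linear
#' conversion through the mean event duration.
#'
#' @param ratio BS ratio (fraction of time covered by events).
#' @param mean_event_duration Mean event duration in seconds.
#' @return Events per hour.
#' @export
ratio_to_event_rate <- function(ratio, mean_event_duration) {
  if (any(mean_event_duration <= 0)) {
    stop("mean_event_duration must be positive")
  }
  ratio * 3600 / mean_event_duration
}

#' Median and IQR summaries
#'
#' `method = "midrange"` reproduces the reporting convention in which
#' Q1 is the mid value between the minimum and the median and Q3 the
#' mid value between the median and the maximum, so
#' IQR = Q3 - Q1 = (max - min) / 2. `method = "standard"` uses the
#' usual sample quartiles.
#'
#' @param values Numeric vector (length >= 1).
#' @param method `"midrange"` or `"standard"`.
#' @return List with `median`, `q1`, `q3`, `iqr`.
#' @export
median_iqr <- function(values, method = c("midrange", "standard")) {
  method <- match.arg(method)
  if (length(values) == 0) stop("median_iqr of an empty vector")
  med <- stats::median(values)
  if (method == "midrange") {
    q1 <- (min(values) + med) / 2
    q3 <- (max(values) + med) / 2
  } else {
    q <- stats::quantile(values, c(0.25, 0.75), names = FALSE)
    q1 <- q[1]; q3 <- q[2]
  }
  list(median = med, q1 = q1, q3 = q3, iqr = q3 - q1)
}
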