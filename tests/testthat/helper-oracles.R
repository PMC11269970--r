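# Independent brute-force reference implementations used to verify the
# interval-arithmetic code paths, plus small fixture generators. These
# deliberately rasterize everything sample-by-sample (or frame-by-frame)
# and share no code with the package internals they check.

# Random sorted, non-overlapping event layout within [0, n_samples).
random_events <- function(n_events, n_samples, min_len = 50, max_len = 2000,
                          tentative_prob = 0) {
  if (n_events == 0) return(bs_events())
  onsets <- integer(0); offsets <- integer(0)
  cursor <- 0
  for (i in seq_len(n_events)) {
    gap <- sample.int(2000, 1)
    len <- sample(min_len:max_len, 1)
    on <- cursor + gap
    off <- on + len
    if (off >= n_samples) break
    onsets <- c(onsets, on); offsets <- c(offsets, off)
    cursor <- off
  }
  if (length(onsets) == 0) return(bs_events())
  bs_events(onsets, offsets,
            tentative = stats::runif(length(onsets)) < tentative_prob)
}

# Rasterize an event table to a logical vector of length n (0-based
# sample s -> index s + 1).
rasterize_events <- function(ev, n) {
  out <- logical(n)
  for (j in seq_len(nrow(ev))) {
    out[(ev$onset[j] + 1):ev$offset[j]] <- TRUE
  }
  out
}

# Brute-force samplewise counts via rasterization.
oracle_prf <- function(truth, pred, n_samples) {
  t_vec <- rasterize_events(truth[!truth$tentative, , drop = FALSE], n_samples)
  p_vec <- rasterize_events(pred, n_samples)
  list(tp = sum(t_vec & p_vec), fp = sum(!t_vec & p_vec),
       fn = sum(t_vec & !p_vec))
}

# Brute-force frame mask: loop every frame x event pair.
oracle_mask <- function(events, segment_start, n_frames = 998,
                        stride = 160, window = 400, lambda = 0.5) {
  events <- events[!events$tentative, , drop = FALSE]
  mask <- integer(n_frames)
  for (k in seq_len(n_frames) - 1L) {
    fs <- segment_start + k * stride
    fe <- fs + window
    ov <- 0
    for (j in seq_len(nrow(events))) {
      ov <- ov + max(0, min(fe, events$offset[j]) - max(fs, events$onset[j]))
    }
    if (ov >= lambda * window) mask[k + 1L] <- 1L
  }
  mask
}

# Brute-force segment-error taxonomy on rasterized streams. An FP run
# is a merge if flanked by true positives on both sides, overfill on
# one side, insertion otherwise; an FN run is fragmentation/underfill/
# deletion by the same flanking logic restricted to its truth event.
oracle_segment_errors <- function(truth, pred, n_samples) {
  t_vec <- rasterize_events(truth[!truth$tentative, , drop = FALSE], n_samples)
  p_vec <- rasterize_events(pred, n_samples)
  runs <- function(sel) {
    r <- rle(sel)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    cbind(starts[r$values], ends[r$values])
  }
  err <- c(insertion = 0, deletion = 0, fragmentation = 0,
           merge = 0, overfill = 0, underfill = 0)
  fp_runs <- runs(!t_vec & p_vec)
  for (i in seq_len(nrow(fp_runs))) {
    a <- fp_runs[i, 1]; b <- fp_runs[i, 2]
    left <- a > 1 && t_vec[a - 1] && p_vec[a - 1]
    right <- b < n_samples && t_vec[b + 1] && p_vec[b + 1]
    kind <- if (left && right) "merge" else if (left || right) "overfill" else "insertion"
    err[kind] <- err[kind] + (b - a + 1)
  }
  fn_runs <- runs(t_vec & !p_vec)
  for (i in seq_len(nrow(fn_runs))) {
    a <- fn_runs[i, 1]; b <- fn_runs[i, 2]
    left <- a > 1 && t_vec[a - 1] && p_vec[a - 1]
    right <- b < n_samples && t_vec[b + 1] && p_vec[b + 1]
    kind <- if (left && right) "fragmentation" else if (left || right) "underfill" else "deletion"
    err[kind] <- err[kind] + (b - a + 1)
  }
  as.list(err / 16000)
}

# A 10-s segment list entry from raw samples.
make_segment <- function(samples, start_sample = 0, index = 1) {
  n_real <- length(samples)
  if (n_real < 160000) samples <- c(samples, numeric(160000 - n_real))
  list(samples = samples, start_sample = start_sample, index = index,
       n_real = n_real)
}
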