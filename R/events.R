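#' Construct an event table
#'
#' Events are stored as a data frame with 0-based, half-open sample
#' intervals `[onset, offset)` at the 16 kHz recording rate, plus a
#' `tentative` flag for annotations the raters could not confirm.
#'
#' @param onset Integer vector of onset sample indices (0-based).
#' @param offset Integer vector of offset sample indices (half-open).
#' @param tentative Logical vector (recycled).
#' @return A `bs_events` data frame, sorted by onset.
#' @export
bs_events <- function(onset = integer(), offset = integer(), tentative = FALSE) {
  onset <- as.numeric(onset)
  offset <- as.numeric(offset)
  tentative <- rep_len(as.logical(tentative), length(onset))
  ev <- data.frame(onset = onset, offset = offset, tentative = tentative)
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("bs_events", "data.frame")
  validate_events(ev)
  ev
}

#' @keywords internal
validate_events <- function(ev, n_samples = NULL) {
  if (nrow(ev) == 0) return(invisible(ev))
  bad <- which(ev$offset <= ev$onset)
  if (length(bad)) {
    stop("reversed or empty event intervals at rows: ",
         paste(bad, collapse = ", "))
  }
  if (any(ev$onset < 0)) stop("negative onset in event table")
  if (nrow(ev) > 1) {
    ov <- which(ev$onset[-1] < ev$offset[-nrow(ev)])
    if (length(ov)) {
      stop("overlapping events at rows: ", paste(ov, collapse = ", "))
    }
  }
  if (!is.null(n_samples) && any(ev$offset > n_samples)) {
    stop("event offset beyond recording end (", n_samples, " samples)")
  }
  invisible(ev)
}

#' Total duration covered by an event table, in samples
#' @param ev A `bs_events` table.
#' @return Numeric scalar.
#' @export
events_duration <- function(ev) {
  if (nrow(ev) == 0) return(0)
  sum(ev$offset - ev$onset)
}

# Clip an event table to [lo, hi) and shift so lo becomes 0.
# Events fully outside are dropped.
clip_events <- function(ev, lo, hi) {
  on <- pmax(ev$onset, lo)
  off <- pmin(ev$offset, hi)
  keep <- off > on
  out <- data.frame(onset = on[keep] - lo, offset = off[keep] - lo,
                    tentative = ev$tentative[keep])
  class(out) <- c("bs_events", "data.frame")
  out
}

# Total intersection length of two sorted non-overlapping interval sets
# (interval arithmetic; no rasterization).
interval_intersection <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  total <- 0
  i <- 1L; j <- 1L
  while (i <= nrow(a) && j <= nrow(b)) {
    lo <- max(a$onset[i], b$onset[j])
    hi <- min(a$offset[i], b$offset[j])
    if (hi > lo) total <- total + (hi - lo)
    if (a$offset[i] < b$offset[j]) i <- i + 1L else j <- j + 1L
  }
  total
}
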