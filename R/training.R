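# Training recipe: combined cross-entropy + dice objective on the
# frame masks, Adam with a step-decay learning-rate schedule,
# SpecAugment-style augmentation, leave-one-participant-out folds.

#' Training configuration
#'
#' Defaults are the published recipe: 25 epochs, imbalanced batches of
#' 32 (no class rebalancing), initial learning rate 1e-4 decayed by
#' 0.85 per epoch from the sixth epoch, Adam with beta1 = 0.95,
#' beta2 = 0.999, weight decay 5e-7; augmentation masks up to 24
#' frequency bins and up to 10% of time bins, shifts by up to +-10
#' time bins and adds white noise with magnitude below 0.1.
#'
#' @param epochs Number of epochs (every epoch runs; the final-epoch
#'   weights are returned, no early stopping or model selection).
#' @param batch_size Segments per optimizer step.
#' @param lr0 Initial learning rate.
#' @param lr_decay Multiplicative decay per epoch.
#' @param lr_decay_from First epoch at which decay applies.
#' @param beta1,beta2,weight_decay Adam hyperparameters.
#' @param max_freq_mask_bins,max_time_mask_fraction,max_time_shift_bins,noise_mag_max
#'   Augmentation bounds.
#' @param augment Enable augmentation.
#' @param seed Integer seed for the run.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 25L, batch_size = 32L, lr0 = 1e-4,
                         lr_decay = 0.85, lr_decay_from = 6L,
                         beta1 = 0.95, beta2 = 0.999, weight_decay = 5e-7,
                         max_freq_mask_bins = 24L,
                         max_time_mask_fraction = 0.10,
                         max_time_shift_bins = 10L,
                         noise_mag_max = 0.1,
                         augment = TRUE,
                         seed = 1L) {
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr0 = lr0, lr_decay = lr_decay,
                 lr_decay_from = as.integer(lr_decay_from),
                 beta1 = beta1, beta2 = beta2, weight_decay = weight_decay,
                 max_freq_mask_bins = as.integer(max_freq_mask_bins),
                 max_time_mask_fraction = max_time_mask_fraction,
                 max_time_shift_bins = as.integer(max_time_shift_bins),
                 noise_mag_max = noise_mag_max,
                 augment = isTRUE(augment),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Epoch-wise learning-rate schedule
#'
#' Constant at `lr0` for the first `decay_from - 1` epochs, then
#' multiplied by `decay` each epoch: `lr0 * decay^max(0, epoch - decay_from + 1)`.
#'
#' @param epoch Epoch number(s), 1-based.
#' @param lr0 Initial learning rate.
#' @param decay Decay factor per epoch.
#' @param decay_from First epoch with decay applied.
#' @return Learning rate(s).
#' @export
lr_schedule <- function(epoch, lr0 = 1e-4, decay = 0.85, decay_from = 6L) {
  lr0 * decay^pmax(0, epoch - decay_from + 1)
}

#' Combined cross-entropy + dice loss
#'
#' `L = L_CE + L_dice`, unweighted. `L_CE` is the mean per-frame
#' cross-entropy over the unpadded frames; `L_dice` is the soft dice
#' loss on the BS probability channel,
#' `1 - (2 * sum(p * y) + eps) / (sum(p) + sum(y) + eps)` with
#' smoothing `eps = 1`. Padded frames are excluded from both terms.
#'
#' @param prediction Output of [effunet_forward()] (or a 2 x n matrix
#'   of class probabilities with rows NBS, BS).
#' @param target A frame mask from [events_to_mask()].
#' @param n_real Number of unpadded frames scored.
#' @param eps Dice smoothing term.
#' @return List with `total`, `ce` and `dice`.
#' @export
effunet_loss <- function(prediction, target, n_real = NULL, eps = 1) {
  prob <- if (is.list(prediction)) prediction$probabilities else prediction
  if (is.null(n_real)) {
    n_real <- attr(target, "n_real_frames")
    if (is.null(n_real)) n_real <- length(target)
  }
  if (ncol(prob) < n_real || length(target) < n_real) {
    stop("prediction (", ncol(prob), ") and target (", length(target),
         ") shorter than the scored region (", n_real, " frames)")
  }
  y <- as.numeric(target[seq_len(n_real)])
  p_bs <- prob[2, seq_len(n_real)]
  p_true <- ifelse(y == 1, p_bs, prob[1, seq_len(n_real)])
  ce <- -mean(log(pmax(p_true, 1e-12)))
  dice <- 1 - (2 * sum(p_bs * y) + eps) / (sum(p_bs) + sum(y) + eps)
  list(total = ce + dice, ce = ce, dice = dice)
}

# Gradient of the combined loss with respect to the logits
# (2 x n_frames). Padded frames receive zero gradient.
loss_grad <- function(logits, target, n_real, eps = 1) {
  zmax <- pmax(logits[1, ], logits[2, ])
  ez <- exp(sweep(logits, 2, zmax))
  p <- sweep(ez, 2, colSums(ez), "/")
  n_total <- ncol(logits)
  y <- as.numeric(target[seq_len(n_real)])
  idx <- seq_len(n_real)
  p0 <- p[1, idx]; p1 <- p[2, idx]
  dce <- matrix(0, 2, n_total)
  dce[1, idx] <- (p0 - (1 - y)) / n_real
  dce[2, idx] <- (p1 - y) / n_real
  S <- sum(p1) + sum(y) + eps
  N <- 2 * sum(p1 * y) + eps
  dl_dp1 <- -(2 * y * S - N) / S^2
  ddice <- matrix(0, 2, n_total)
  ddice[2, idx] <- dl_dp1 * p1 * (1 - p1)
  ddice[1, idx] <- dl_dp1 * (-p1 * p0)
  p_true <- ifelse(y == 1, p1, p0)
  ce <- -mean(log(pmax(p_true, 1e-12)))
  dice <- 1 - N / S
  list(dlogits = dce + ddice, loss = ce + dice, ce = ce, dice = dice)
}

#' SpecAugment-style augmentation
#'
#' Applies, in order: a frequency mask of up to `max_freq_mask_bins`
#' bins and a single contiguous time mask of up to
#' `max_time_mask_fraction` of the time bins (spectrogram only, labels
#' unchanged); a time shift uniform in +-`max_time_shift_bins` applied
#' identically to spectrogram and mask (vacated bins filled with 0);
#' additive white noise with magnitude drawn below `noise_mag_max`.
#' Uses the current RNG stream, so results are reproducible under
#' `set.seed()`.
#'
#' @param spec A 128 x 1056 spectrogram.
#' @param mask The paired frame mask (length 1056).
#' @param config A [train_config()] carrying the augmentation bounds.
#' @return List with augmented `spec` and `mask`.
#' @export
augment_spectrogram <- function(spec, mask, config = train_config()) {
  nm <- nrow(spec); nt <- ncol(spec)
  # frequency mask
  fw <- sample.int(config$max_freq_mask_bins + 1L, 1L) - 1L
  if (fw > 0) {
    f0 <- sample.int(nm - fw + 1L, 1L)
    spec[f0:(f0 + fw - 1L), ] <- 0
  }
  # time mask (spectrogram only)
  tmax <- floor(config$max_time_mask_fraction * nt)
  tw <- sample.int(tmax + 1L, 1L) - 1L
  if (tw > 0) {
    t0 <- sample.int(nt - tw + 1L, 1L)
    spec[, t0:(t0 + tw - 1L)] <- 0
  }
  # time shift, same for spectrogram and mask
  k <- sample.int(2L * config$max_time_shift_bins + 1L, 1L) -
    config$max_time_shift_bins - 1L
  if (k != 0) {
    spec <- shift_cols(spec, k)
    mask_attr <- attributes(mask)
    mask <- shift_vec(as.numeric(mask), k)
    attributes(mask) <- mask_attr
  }
  # additive white noise
  mag <- stats::runif(1, 0, config$noise_mag_max)
  spec <- spec + mag * matrix(stats::rnorm(length(spec)), nm, nt)
  list(spec = spec, mask = mask)
}

shift_cols <- function(m, k) {
  out <- matrix(0, nrow(m), ncol(m))
  nt <- ncol(m)
  if (k > 0) out[, (k + 1):nt] <- m[, 1:(nt - k)]
  else out[, 1:(nt + k)] <- m[, (1 - k):nt]
  out
}

shift_vec <- function(v, k) {
  out <- numeric(length(v))
  n <- length(v)
  if (k > 0) out[(k + 1):n] <- v[1:(n - k)]
  else out[1:(n + k)] <- v[(1 - k):n]
  out
}

#' Train an Efficient-U-Net on prepared segments
#'
#' @param model An `effunet` model (modified in place).
#' @param data List of training examples, each a list with `spec`
#'   (standardized padded 128 x 1056 spectrogram) and `mask` (padded
#'   frame mask). Batches reflect the natural class imbalance; no
#'   rebalancing is applied.
#' @param config A [train_config()].
#' @param verbose Print per-epoch loss.
#' @return List with `model` and `history` (data frame epoch, lr,
#'   mean loss and its cross-entropy and dice components).
#' @export
train_effunet <- function(model, data, config = train_config(), verbose = FALSE) {
  set.seed(config$seed)
  opt <- adam_state(model$modules)
  history <- data.frame(epoch = integer(), lr = numeric(), loss = numeric(),
                        ce = numeric(), dice = numeric())
  n <- length(data)
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_schedule(epoch, config$lr0, config$lr_decay, config$lr_decay_from)
    order_idx <- sample.int(n)
    ep_loss <- 0; ep_ce <- 0; ep_dice <- 0; n_batches <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- order_idx[start:min(n, start + config$batch_size - 1L)]
      zero_grads(model$modules)
      b_loss <- 0; b_ce <- 0; b_dice <- 0
      for (i in idx) {
        ex <- data[[i]]
        spec <- ex$spec; mask <- ex$mask
        if (config$augment) {
          aug <- augment_spectrogram(spec, mask, config)
          spec <- aug$spec; mask <- aug$mask
        }
        n_real <- attr(ex$mask, "n_real_frames")
        if (is.null(n_real)) n_real <- N_FRAMES
        fw <- effunet_fwd(model, spec, train = TRUE)
        lg <- loss_grad(fw$logits, mask, n_real)
        if (!is.finite(lg$loss)) {
          stop("non-finite loss at epoch ", epoch, ", segment ", i)
        }
        effunet_bwd(model, fw$cache, lg$dlogits)
        b_loss <- b_loss + lg$loss; b_ce <- b_ce + lg$ce; b_dice <- b_dice + lg$dice
      }
      opt <- adam_step(model$modules, opt, lr, config$beta1, config$beta2,
                       config$weight_decay, grad_scale = 1 / length(idx))
      ep_loss <- ep_loss + b_loss / length(idx)
      ep_ce <- ep_ce + b_ce / length(idx)
      ep_dice <- ep_dice + b_dice / length(idx)
      n_batches <- n_batches + 1L
    }
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, loss = ep_loss / n_batches,
      ce = ep_ce / n_batches, dice = ep_dice / n_batches))
    if (verbose) {
      message(sprintf("epoch %d  lr %.3g  loss %.4f (ce %.4f, dice %.4f)",
                      epoch, lr, ep_loss / n_batches, ep_ce / n_batches,
                      ep_dice / n_batches))
    }
  }
  list(model = model, history = history)
}

#' Leave-one-participant-out folds
#'
#' One fold per participant: all of that participant's channels form
#' the test side, every other participant's recordings the train side.
#'
#' @param manifest A corpus manifest (see [read_manifest()]).
#' @return List of folds, each with `test_participant`, `train` and
#'   `test` manifest subsets.
#' @export
lopo_splits <- function(manifest) {
  participants <- unique(manifest$participant_id)
  if (length(participants) < 2) {
    stop("leave-one-participant-out needs at least 2 participants, got ",
         length(participants))
  }
  lapply(participants, function(p) {
    list(test_participant = p,
         train = manifest[manifest$participant_id != p, , drop = FALSE],
         test = manifest[manifest$participant_id == p, , drop = FALSE])
  })
}

#' Prepare training examples from recordings on disk
#'
#' Applies the preprocessing chain (high-pass filter, 10-s
#' segmentation, standardized padded log-Mel spectrograms) and pairs
#' each segment with its ground-truth frame mask. Guideline
#' enforcement (gap merging, minimum duration) runs on the labels
#' first; tentative events become the NULL class.
#'
#' @param manifest Manifest rows to load.
#' @return List of examples (`spec`, `mask`, `participant`, `channel`,
#'   `segment_start`).
#' @export
prepare_examples <- function(manifest) {
  out <- list()
  for (r in seq_len(nrow(manifest))) {
    wav <- read_wav(manifest$wav_path[r])
    rec <- bs_recording(wav$samples, manifest$participant_id[r],
                        manifest$channel_id[r], wav$sample_rate)
    rec <- highpass_filter(rec)
    events <- enforce_guidelines(read_labels(manifest$label_path[r]))
    for (seg in segment_audio(rec)) {
      out[[length(out) + 1L]] <- list(
        spec = segment_features(seg),
        mask = events_to_mask(events, seg$start_sample),
        participant = rec$participant, channel = rec$channel,
        segment_start = seg$start_sample)
    }
  }
  out
}
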