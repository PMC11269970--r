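# Efficient-U-Net: an EfficientNet encoder (inverted-bottleneck MBConv
# blocks with squeeze-excitation and residual connections) feeding a
# U-Net style decoder (2x2 transposed convolution followed by two 3x3
# convolutions per block, skip connections from each encoder
# resolution). A final 1x1 convolution maps to the two classes (BS,
# NBS); average pooling over the frequency axis and a softmax produce
# per-frame class probabilities, so the output is one prediction per
# 25 ms spectrogram frame.

#' Configure an Efficient-U-Net
#'
#' `"b2"` is the full detection model: EfficientNet-B2 encoder
#' (width 1.1, depth 1.2 compound scaling, 1-channel spectrogram
#' input) with a five-stage decoder of widths 512-32, about 18.1
#' million parameters in total. `"b0"` is the unscaled EfficientNet
#' baseline. `"tiny"` is a two-stage reduction (about 12 thousand
#' parameters) sharing all code paths, intended for CPU-speed tests
#' and smoke experiments.
#'
#' @param variant `"b2"`, `"b0"` or `"tiny"`.
#' @param decoder_channels Optional override of decoder widths; length
#'   must equal the number of downsampling stages of the encoder.
#' @return An `effunet_config` list.
#' @export
effunet_config <- function(variant = c("b2", "b0", "tiny"),
                           decoder_channels = NULL) {
  variant <- match.arg(variant)
  cfg <- switch(variant,
    b2 = list(
      stem = 32L,
      # per stage: output channels, repeats, expansion, kernel, stride
      stages = list(
        list(ch = 16L,  rep = 2L, e = 1L, k = 3L, s = 1L),
        list(ch = 24L,  rep = 3L, e = 6L, k = 3L, s = 2L),
        list(ch = 48L,  rep = 3L, e = 6L, k = 5L, s = 2L),
        list(ch = 88L,  rep = 4L, e = 6L, k = 3L, s = 2L),
        list(ch = 120L, rep = 4L, e = 6L, k = 5L, s = 1L),
        list(ch = 208L, rep = 5L, e = 6L, k = 5L, s = 2L),
        list(ch = 352L, rep = 2L, e = 6L, k = 3L, s = 1L)),
      head = 1408L,
      decoder = c(512L, 256L, 128L, 64L, 32L)),
    b0 = list(
      stem = 32L,
      stages = list(
        list(ch = 16L,  rep = 1L, e = 1L, k = 3L, s = 1L),
        list(ch = 24L,  rep = 2L, e = 6L, k = 3L, s = 2L),
        list(ch = 40L,  rep = 2L, e = 6L, k = 5L, s = 2L),
        list(ch = 80L,  rep = 3L, e = 6L, k = 3L, s = 2L),
        list(ch = 112L, rep = 3L, e = 6L, k = 5L, s = 1L),
        list(ch = 192L, rep = 4L, e = 6L, k = 5L, s = 2L),
        list(ch = 320L, rep = 1L, e = 6L, k = 3L, s = 1L)),
      head = 1280L,
      decoder = c(512L, 256L, 128L, 64L, 32L)),
    tiny = list(
      stem = 8L,
      stages = list(
        list(ch = 8L,  rep = 1L, e = 1L, k = 3L, s = 1L),
        list(ch = 16L, rep = 1L, e = 4L, k = 3L, s = 2L),
        list(ch = 24L, rep = 1L, e = 4L, k = 3L, s = 2L)),
      head = 32L,
      decoder = c(16L, 8L, 4L)))
  if (!is.null(decoder_channels)) cfg$decoder <- as.integer(decoder_channels)
  n_down <- 1L + sum(vapply(cfg$stages, function(s) s$s == 2L, logical(1)))
  if (length(cfg$decoder) != n_down) {
    stop("decoder depth (", length(cfg$decoder), ") must match the ",
         "encoder downsampling stage count (", n_down, ")")
  }
  cfg$variant <- variant
  cfg$n_classes <- 2L
  cfg$input_shape <- c(N_MELS, PADDED_FRAMES)
  class(cfg) <- "effunet_config"
  cfg
}

# One inverted-bottleneck block. SE squeeze width follows the
# EfficientNet convention: a quarter of the block input channels.
new_mbconv <- function(cin, cout, e, k, stride, prefix) {
  ce <- cin * e
  b <- new.env(parent = emptyenv())
  b$cin <- cin; b$cout <- cout; b$e <- e; b$stride <- stride
  b$use_res <- (stride == 1L && cin == cout)
  b$layers <- list()
  if (e != 1L) {
    b$layers$expand <- layer_conv(cin, ce, 1L, 1L, 0L)
    b$layers$bn_expand <- layer_bn(ce)
  }
  b$layers$dw <- layer_dwconv(ce, k, stride)
  b$layers$bn_dw <- layer_bn(ce)
  se_ch <- max(1L, as.integer(floor(0.25 * cin)))
  b$layers$se <- layer_se(ce, se_ch)
  b$layers$project <- layer_conv(ce, cout, 1L, 1L, 0L)
  b$layers$bn_project <- layer_bn(cout)
  b$prefix <- prefix
  b
}

mbconv_fwd <- function(b, x, train) {
  cache <- list()
  h <- x
  if (!is.null(b$layers$expand)) {
    r <- conv_fwd(b$layers$expand, h); cache$expand <- r$cache; h <- r$y
    r <- bn_fwd(b$layers$bn_expand, h, train); cache$bn_expand <- r$cache; h <- r$y
    r <- act_fwd(h, "silu"); cache$act_expand <- r$cache; h <- r$y
  }
  r <- dwconv_fwd(b$layers$dw, h); cache$dw <- r$cache; h <- r$y
  r <- bn_fwd(b$layers$bn_dw, h, train); cache$bn_dw <- r$cache; h <- r$y
  r <- act_fwd(h, "silu"); cache$act_dw <- r$cache; h <- r$y
  r <- se_fwd(b$layers$se, h); cache$se <- r$cache; h <- r$y
  r <- conv_fwd(b$layers$project, h); cache$project <- r$cache; h <- r$y
  r <- bn_fwd(b$layers$bn_project, h, train); cache$bn_project <- r$cache; h <- r$y
  if (b$use_res) h <- h + x
  list(y = h, cache = cache)
}

mbconv_bwd <- function(b, cache, dy) {
  dres <- if (b$use_res) dy else NULL
  dh <- bn_bwd(b$layers$bn_project, cache$bn_project, dy)
  dh <- conv_bwd(b$layers$project, cache$project, dh)
  dh <- se_bwd(b$layers$se, cache$se, dh)
  dh <- act_bwd(cache$act_dw, dh, "silu")
  dh <- bn_bwd(b$layers$bn_dw, cache$bn_dw, dh)
  dh <- dwconv_bwd(b$layers$dw, cache$dw, dh)
  if (!is.null(b$layers$expand)) {
    dh <- act_bwd(cache$act_expand, dh, "silu")
    dh <- bn_bwd(b$layers$bn_expand, cache$bn_expand, dh)
    dh <- conv_bwd(b$layers$expand, cache$expand, dh)
  }
  if (!is.null(dres)) dh <- dh + dres
  dh
}

new_decoder_block <- function(cin, skip_ch, cout, prefix) {
  b <- new.env(parent = emptyenv())
  b$cin <- cin; b$skip_ch <- skip_ch; b$cout <- cout
  b$layers <- list(
    up = layer_tconv(cin, cout),
    conv1 = layer_conv(cout + skip_ch, cout, 3L, 1L, 1L, bias = FALSE),
    bn1 = layer_bn(cout),
    conv2 = layer_conv(cout, cout, 3L, 1L, 1L, bias = FALSE),
    bn2 = layer_bn(cout))
  b$prefix <- prefix
  b
}

decoder_block_fwd <- function(b, x, skip, train) {
  cache <- list()
  r <- tconv_fwd(b$layers$up, x); cache$up <- r$cache; h <- r$y
  if (!is.null(skip)) {
    cache$up_dims <- dim(h)
    h <- array(c(h, skip), dim = c(dim(h)[1], dim(h)[2], b$cout + b$skip_ch))
  }
  r <- conv_fwd(b$layers$conv1, h); cache$conv1 <- r$cache; h <- r$y
  r <- bn_fwd(b$layers$bn1, h, train); cache$bn1 <- r$cache; h <- r$y
  r <- act_fwd(h, "relu"); cache$act1 <- r$cache; h <- r$y
  r <- conv_fwd(b$layers$conv2, h); cache$conv2 <- r$cache; h <- r$y
  r <- bn_fwd(b$layers$bn2, h, train); cache$bn2 <- r$cache; h <- r$y
  r <- act_fwd(h, "relu"); cache$act2 <- r$cache; h <- r$y
  list(y = h, cache = cache)
}

decoder_block_bwd <- function(b, cache, dy) {
  dh <- act_bwd(cache$act2, dy, "relu")
  dh <- bn_bwd(b$layers$bn2, cache$bn2, dh)
  dh <- conv_bwd(b$layers$conv2, cache$conv2, dh)
  dh <- act_bwd(cache$act1, dh, "relu")
  dh <- bn_bwd(b$layers$bn1, cache$bn1, dh)
  dh <- conv_bwd(b$layers$conv1, cache$conv1, dh)
  dskip <- NULL
  if (b$skip_ch > 0L) {
    d <- cache$up_dims
    dup <- dh[, , seq_len(b$cout), drop = FALSE]
    dskip <- dh[, , b$cout + seq_len(b$skip_ch), drop = FALSE]
    dh <- array(dup, dim = d)
  }
  dx <- tconv_bwd(b$layers$up, cache$up, dh)
  list(dx = dx, dskip = dskip)
}

#' Build an Efficient-U-Net model
#'
#' Constructs the network mapping a 1 x 128 x 1056 standardized log-Mel
#' spectrogram to per-frame class probabilities over 1056 frames.
#' All weights are He-initialized; a pretrained encoder can be loaded
#' afterwards with [load_pretrained_encoder()].
#'
#' @param config An [effunet_config()] (default: the B2 model).
#' @param seed Optional integer seed making initialization reproducible.
#' @return An `effunet` model object.
#' @export
build_effunet <- function(config = effunet_config("b2"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- new.env(parent = emptyenv())
  m$config <- config
  m$stem_conv <- layer_conv(1L, config$stem, 3L, 2L, 1L)
  m$stem_bn <- layer_bn(config$stem)
  m$blocks <- list()
  cin <- config$stem
  for (si in seq_along(config$stages)) {
    st <- config$stages[[si]]
    for (ri in seq_len(st$rep)) {
      stride <- if (ri == 1L) st$s else 1L
      prefix <- sprintf("encoder.stage%d.block%d", si, ri)
      m$blocks[[length(m$blocks) + 1L]] <-
        new_mbconv(cin, st$ch, st$e, st$k, stride, prefix)
      cin <- st$ch
    }
  }
  m$head_conv <- layer_conv(cin, config$head, 1L, 1L, 0L)
  m$head_bn <- layer_bn(config$head)
  # skip taps: encoder output just before each later downsampling block
  strides <- vapply(m$blocks, function(b) b$stride, integer(1))
  chans <- vapply(m$blocks, function(b) b$cout, integer(1))
  tap_idx <- which(strides == 2L) - 1L          # block index whose output is tapped
  tap_ch <- c(config$stem, chans)[tap_idx + 1L] # 0 means the stem output
  m$tap_idx <- rev(tap_idx)                     # deepest first for the decoder
  skip_ch <- c(rev(tap_ch), 0L)                 # last decoder block has no skip
  m$dec_blocks <- list()
  cin <- config$head
  for (di in seq_along(config$decoder)) {
    cout <- config$decoder[di]
    m$dec_blocks[[di]] <- new_decoder_block(cin, skip_ch[di], cout,
                                            sprintf("decoder.block%d", di))
    cin <- cout
  }
  m$final_conv <- layer_conv(cin, config$n_classes, 1L, 1L, 0L, bias = TRUE)
  m$modules <- effunet_modules(m)
  class(m) <- "effunet"
  m
}

# Flat named list of every parameterized layer, encoder first. Names
# are stable and used for optimizer state and pretrained-weight import.
effunet_modules <- function(m) {
  mods <- list(encoder.stem.conv = m$stem_conv, encoder.stem.bn = m$stem_bn)
  for (b in m$blocks) {
    for (nm in names(b$layers)) mods[[paste0(b$prefix, ".", nm)]] <- b$layers[[nm]]
  }
  mods$encoder.head.conv <- m$head_conv
  mods$encoder.head.bn <- m$head_bn
  for (b in m$dec_blocks) {
    for (nm in names(b$layers)) mods[[paste0(b$prefix, ".", nm)]] <- b$layers[[nm]]
  }
  mods$final.conv <- m$final_conv
  mods
}

#' Number of trainable parameters
#' @param model An `effunet` model.
#' @return Integer parameter count.
#' @export
effunet_n_params <- function(model) {
  sum(vapply(model$modules,
             function(l) sum(vapply(l$p, length, numeric(1))),
             numeric(1)))
}

# Full forward pass. Returns logits (2 x n_frames) plus caches when
# train = TRUE.
effunet_fwd <- function(m, spec, train = FALSE) {
  if (anyNA(spec)) stop("NaN/NA in input spectrogram")
  x <- array(as.numeric(spec), dim = c(nrow(spec), ncol(spec), 1L))
  cache <- list()
  r <- conv_fwd(m$stem_conv, x); cache$stem_conv <- r$cache; h <- r$y
  r <- bn_fwd(m$stem_bn, h, train); cache$stem_bn <- r$cache; h <- r$y
  r <- act_fwd(h, "silu"); cache$stem_act <- r$cache; h <- r$y
  taps <- list()
  if (0L %in% m$tap_idx) taps[["0"]] <- h
  cache$blocks <- vector("list", length(m$blocks))
  for (bi in seq_along(m$blocks)) {
    r <- mbconv_fwd(m$blocks[[bi]], h, train)
    cache$blocks[[bi]] <- r$cache
    h <- r$y
    if (bi %in% m$tap_idx) taps[[as.character(bi)]] <- h
  }
  r <- conv_fwd(m$head_conv, h); cache$head_conv <- r$cache; h <- r$y
  r <- bn_fwd(m$head_bn, h, train); cache$head_bn <- r$cache; h <- r$y
  r <- act_fwd(h, "silu"); cache$head_act <- r$cache; h <- r$y
  cache$dec <- vector("list", length(m$dec_blocks))
  for (di in seq_along(m$dec_blocks)) {
    b <- m$dec_blocks[[di]]
    skip <- if (b$skip_ch > 0L) taps[[as.character(m$tap_idx[di])]] else NULL
    r <- decoder_block_fwd(b, h, skip, train)
    cache$dec[[di]] <- r$cache
    h <- r$y
  }
  r <- conv_fwd(m$final_conv, h); cache$final <- r$cache; h <- r$y
  d <- dim(h)  # (H, W, 2)
  logits <- t(matrix(colMeans(matrix(h, d[1], d[2] * d[3])), d[2], d[3]))
  cache$out_dims <- d
  list(logits = logits, cache = if (train) cache else NULL)
}

# Backward pass from dlogits (2 x n_frames); accumulates parameter
# gradients in the layer environments.
effunet_bwd <- function(m, cache, dlogits) {
  d <- cache$out_dims
  dh <- array(rep(t(dlogits) / d[1], each = d[1]), dim = d)
  dh <- conv_bwd(m$final_conv, cache$final, dh)
  dtaps <- list()
  for (di in rev(seq_along(m$dec_blocks))) {
    b <- m$dec_blocks[[di]]
    r <- decoder_block_bwd(b, cache$dec[[di]], dh)
    dh <- r$dx
    if (!is.null(r$dskip)) dtaps[[as.character(m$tap_idx[di])]] <- r$dskip
  }
  dh <- act_bwd(cache$head_act, dh, "silu")
  dh <- bn_bwd(m$head_bn, cache$head_bn, dh)
  dh <- conv_bwd(m$head_conv, cache$head_conv, dh)
  for (bi in rev(seq_along(m$blocks))) {
    tap_grad <- dtaps[[as.character(bi)]]
    if (!is.null(tap_grad)) dh <- dh + tap_grad
    dh <- mbconv_bwd(m$blocks[[bi]], cache$blocks[[bi]], dh)
  }
  tap_grad <- dtaps[["0"]]
  if (!is.null(tap_grad)) dh <- dh + tap_grad
  dh <- act_bwd(cache$stem_act, dh, "silu")
  dh <- bn_bwd(m$stem_bn, cache$stem_bn, dh)
  dh <- conv_bwd(m$stem_conv, cache$stem_conv, dh)
  invisible(dh)
}

#' Forward pass: per-frame class probabilities
#'
#' @param model An `effunet` model.
#' @param spec A standardized, padded 128 x 1056 spectrogram (or a list
#'   of them).
#' @return For one spectrogram, a list with `probabilities`
#'   (2 x 1056 matrix, rows NBS and BS, columns summing to 1) and
#'   `mask` (integer 0/1 per frame via argmax, BS iff p_BS > p_NBS);
#'   for a list input, a list of such results.
#' @export
effunet_forward <- function(model, spec) {
  if (is.list(spec)) return(lapply(spec, function(s) effunet_forward(model, s)))
  r <- effunet_fwd(model, spec, train = FALSE)
  z <- r$logits
  zmax <- pmax(z[1, ], z[2, ])
  ez <- exp(sweep(z, 2, zmax))
  prob <- sweep(ez, 2, colSums(ez), "/")
  rownames(prob) <- c("nbs", "bs")
  list(probabilities = prob, mask = as.integer(prob[2, ] > prob[1, ]))
}

#' Load pretrained encoder weights
#'
#' Replaces encoder parameters with the supplied tensors, leaving the
#' decoder untouched (event onsets/offsets are absent from tagging
#' pretraining corpora, so only the encoder can be pretrained).
#' Weight names follow the module naming of this package,
#' `encoder.<module>.<param>`, e.g. `encoder.stem.conv.W`.
#'
#' @param model An `effunet` model.
#' @param weights Named list of arrays.
#' @return The model, modified in place (returned invisibly).
#' @export
load_pretrained_encoder <- function(model, weights) {
  bad <- character()
  for (nm in names(weights)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    param <- parts[length(parts)]
    mod_name <- paste(parts[-length(parts)], collapse = ".")
    if (!startsWith(mod_name, "encoder.")) {
      bad <- c(bad, paste0(nm, " (not an encoder tensor)"))
      next
    }
    l <- model$modules[[mod_name]]
    if (is.null(l) || is.null(l$p[[param]])) {
      bad <- c(bad, paste0(nm, " (no such tensor)"))
      next
    }
    w <- weights[[nm]]
    if (!identical(dim_or_len(l$p[[param]]), dim_or_len(w))) {
      bad <- c(bad, sprintf("%s (shape %s, expected %s)", nm,
                            paste(dim_or_len(w), collapse = "x"),
                            paste(dim_or_len(l$p[[param]]), collapse = "x")))
      next
    }
    l$p[[param]][] <- w
  }
  if (length(bad)) stop("pretrained weight import failed for:\n  ",
                        paste(bad, collapse = "\n  "))
  invisible(model)
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Export model parameters as a named list
#' @param model An `effunet` model.
#' @param encoder_only Restrict to encoder tensors.
#' @return Named list of arrays (`<module>.<param>`).
#' @export
effunet_state <- function(model, encoder_only = FALSE) {
  out <- list()
  for (mod_name in names(model$modules)) {
    if (encoder_only && !startsWith(mod_name, "encoder.")) next
    l <- model$modules[[mod_name]]
    for (param in names(l$p)) out[[paste0(mod_name, ".", param)]] <- l$p[[param]]
  }
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the configuration, all parameters and the
#' batch-norm running statistics.
#'
#' @param model An `effunet` model.
#' @param path File path.
#' @return `path` / the restored model.
#' @export
save_checkpoint <- function(model, path) {
  buffers <- list()
  for (mod_name in names(model$modules)) {
    l <- model$modules[[mod_name]]
    if (l$kind == "bn") {
      buffers[[paste0(mod_name, ".run_mean")]] <- l$run_mean
      buffers[[paste0(mod_name, ".run_var")]] <- l$run_var
    }
  }
  saveRDS(list(config = model$config, state = effunet_state(model),
               buffers = buffers), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_effunet(ck$config, seed = 0L)
  for (nm in names(ck$state)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    param <- parts[length(parts)]
    mod_name <- paste(parts[-length(parts)], collapse = ".")
    model$modules[[mod_name]]$p[[param]][] <- ck$state[[nm]]
  }
  for (nm in names(ck$buffers)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    buf <- parts[length(parts)]
    mod_name <- paste(parts[-length(parts)], collapse = ".")
    assign(buf, ck$buffers[[nm]], envir = model$modules[[mod_name]])
  }
  model
}
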