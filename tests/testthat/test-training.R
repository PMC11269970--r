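test_that("the learning-rate schedule matches its closed form", {
  expect_equal(lr_schedule(1:5), rep(1e-4, 5))
  expect_equal(lr_schedule(6), 8.5e-5)
  expect_equal(lr_schedule(7), 7.225e-5)
  expect_equal(lr_schedule(25), 1e-4 * 0.85^20)
  expect_equal(lr_schedule(1:25), 1e-4 * 0.85^pmax(0, (1:25) - 5))
})

test_that("the combined loss matches its definition on closed-form cases", {
  n <- 10L
  y <- c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0)
  attr(y, "n_real_frames") <- n
  # perfect one-hot prediction: both terms ~ 0 (dice keeps eps smoothing)
  p <- rbind(1 - y, y)
  p <- pmax(pmin(p, 1 - 1e-9), 1e-9)
  l <- effunet_loss(p, y)
  expect_lt(l$ce, 1e-6)
  expect_equal(l$dice, 1 - (2 * 2 + 1) / (2 + 2 + 1), tolerance = 1e-6)
  # uniform prediction: CE = ln 2 regardless of the target
  pu <- matrix(0.5, 2, n)
  expect_equal(effunet_loss(pu, y)$ce, log(2), tolerance = 1e-12)
  expect_error(effunet_loss(matrix(0.5, 2, 4), y), "shorter")
})

test_that("loss values match an independent summation oracle", {
  set.seed(1)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    y <- as.numeric(runif(n) > 0.7)
    attr(y, "n_real_frames") <- n
    p_bs <- runif(n, 0.01, 0.99)
    p <- rbind(1 - p_bs, p_bs)
    l <- effunet_loss(p, y)
    # naive loops
    ce <- 0
    for (k in 1:n) ce <- ce - log(if (y[k] == 1) p[2, k] else p[1, k])
    ce <- ce / n
    inter <- 0; sp <- 0; sy <- 0
    for (k in 1:n) { inter <- inter + p[2, k] * y[k]; sp <- sp + p[2, k]; sy <- sy + y[k] }
    dice <- 1 - (2 * inter + 1) / (sp + sy + 1)
    expect_equal(l$ce, unname(ce), tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(l$dice, unname(dice), tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(l$total, unname(ce + dice), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_gte(l$dice, 0); expect_lte(l$dice, 1)
    expect_gte(l$total, 0)
    # analytic logit gradient agrees with numerical differentiation
    z <- log(rbind(1 - p_bs, p_bs))
    lg <- bowelspot:::loss_grad(z, y, n)
    ii <- sample(length(z), 2)
    for (idx in ii) {
      zp <- z; zp[idx] <- zp[idx] + 1e-6
      zm <- z; zm[idx] <- zm[idx] - 1e-6
      lp <- bowelspot:::loss_grad(zp, y, n)$loss
      lm <- bowelspot:::loss_grad(zm, y, n)$loss
      expect_equal(lg$dlogits[idx], (lp - lm) / 2e-6, tolerance = 1e-4)
    }
  }
})

test_that("augmentation is reproducible and respects its bounds", {
  set.seed(10)
  spec <- matrix(rnorm(128 * 1056), 128, 1056)
  mask <- as.numeric(runif(1056) > 0.9)
  attr(mask, "n_real_frames") <- 998L
  cfg <- train_config()
  set.seed(5); a <- augment_spectrogram(spec, mask, cfg)
  set.seed(5); b <- augment_spectrogram(spec, mask, cfg)
  expect_identical(a, b)
  # frequency-mask width never exceeds 24 bins over many draws
  set.seed(6)
  for (i in 1:2000) {
    fw <- sample.int(cfg$max_freq_mask_bins + 1L, 1L) - 1L
    expect_lte(fw, 24L)
  }
  # noise magnitude below 0.1: masked-region values stay below the bound
  zero_cfg <- train_config(max_freq_mask_bins = 0, max_time_mask_fraction = 0,
                           max_time_shift_bins = 0)
  set.seed(7)
  out <- augment_spectrogram(matrix(0, 128, 1056), mask, zero_cfg)
  expect_lt(max(abs(out$spec)), 0.1 * 5)  # mag < 0.1 times N(0,1) draws
  expect_identical(out$mask, mask)
})

test_that("time shifts move the spectrogram and mask together", {
  spec <- matrix(0, 128, 1056); spec[, 500] <- 7
  mask <- numeric(1056); mask[500] <- 1
  shifted_spec <- bowelspot:::shift_cols(spec, 4)
  shifted_mask <- bowelspot:::shift_vec(mask, 4)
  expect_equal(which(shifted_spec[1, ] != 0 | shifted_spec[5, ] != 0), 504)
  expect_equal(which(shifted_mask != 0), 504)
  # shifting +k then -k restores the interior
  back <- bowelspot:::shift_cols(shifted_spec, -4)
  expect_equal(back[, 20:1000], spec[, 20:1000])
  expect_equal(bowelspot:::shift_vec(shifted_mask, -4), mask)
})

test_that("LOPO folds partition participants without channel leakage", {
  manifest <- data.frame(
    participant_id = rep(sprintf("P%02d", 1:5), each = 2),
    channel_id = rep(c("CH1", "CH2"), 5),
    wav_path = sprintf("r%02d.wav", 1:10),
    label_path = sprintf("r%02d.tsv", 1:10))
  folds <- lopo_splits(manifest)
  expect_length(folds, 5L)
  test_parts <- vapply(folds, function(f) f$test_participant, character(1))
  expect_setequal(test_parts, unique(manifest$participant_id))
  for (f in folds) {
    expect_equal(nrow(f$train), 8L)
    expect_length(intersect(f$train$wav_path, f$test$wav_path), 0L)
    expect_false(f$test_participant %in% f$train$participant_id)
  }
  expect_error(lopo_splits(manifest[1:2, ]), "at least 2")
})

test_that("a short training run decreases the loss on a separable problem", {
  set.seed(50)
  # two easily separable segment types: loud band vs silence
  data <- lapply(1:6, function(i) {
    mask <- numeric(1056)
    spec <- matrix(rnorm(128 * 1056, sd = 0.1), 128, 1056)
    if (i %% 2 == 0) {
      mask[200:400] <- 1
      spec[40:80, 200:400] <- spec[40:80, 200:400] + 3
    }
    attr(mask, "n_real_frames") <- 998L
    list(spec = spec, mask = mask)
  })
  model <- build_effunet(effunet_config("tiny"), seed = 51)
  cfg <- train_config(epochs = 5, batch_size = 2, lr0 = 1e-3,
                      augment = FALSE, seed = 52)
  tr <- train_effunet(model, data, cfg)
  expect_equal(nrow(tr$history), 5L)
  expect_lt(tail(tr$history$loss, 1), tr$history$loss[1])
  expect_equal(tr$history$lr, lr_schedule(1:5, lr0 = 1e-3))
})

test_that("training is reproducible under a fixed seed", {
  set.seed(60)
  data <- lapply(1:4, function(i) {
    mask <- numeric(1056); mask[100:150] <- 1
    attr(mask, "n_real_frames") <- 998L
    list(spec = matrix(rnorm(128 * 1056), 128, 1056), mask = mask)
  })
  cfg <- train_config(epochs = 2, batch_size = 2, seed = 61)
  t1 <- train_effunet(build_effunet(effunet_config("tiny"), seed = 62),
                      data, cfg)
  t2 <- train_effunet(build_effunet(effunet_config("tiny"), seed = 62),
                      data, cfg)
  expect_identical(t1$history, t2$history)
  expect_identical(effunet_state(t1$model), effunet_state(t2$model))
})
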