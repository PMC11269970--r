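tiny_model <- function(seed = 1) build_effunet(effunet_config("tiny"), seed = seed)

test_that("the B2 configuration lands at about 18.1 million parameters", {
  m <- build_effunet(effunet_config("b2"), seed = 1)
  n <- effunet_n_params(m)
  expect_gt(n, 18.1e6 * 0.97)
  expect_lt(n, 18.1e6 * 1.03)
})

test_that("decoder depth must match the encoder downsampling count", {
  expect_error(effunet_config("tiny", decoder_channels = c(16L, 8L)),
               "downsampling")
  expect_error(effunet_config("b2", decoder_channels = c(256L, 128L)),
               "downsampling")
})

test_that("forward pass emits one softmax distribution per frame", {
  m <- tiny_model()
  set.seed(2)
  spec <- matrix(rnorm(128 * 1056), 128, 1056)
  out <- effunet_forward(m, spec)
  expect_equal(dim(out$probabilities), c(2L, 1056L))
  expect_equal(colSums(out$probabilities), rep(1, 1056), tolerance = 1e-5)
  expect_true(all(out$mask %in% c(0L, 1L)))
  expect_equal(out$mask, as.integer(out$probabilities[2, ] > out$probabilities[1, ]))
})

test_that("NaN inputs are rejected", {
  m <- tiny_model()
  spec <- matrix(rnorm(128 * 1056), 128, 1056)
  spec[5, 7] <- NaN
  expect_error(effunet_forward(m, spec), "NaN")
})

test_that("two builds with the same seed have identical weights", {
  a <- effunet_state(tiny_model(seed = 9))
  b <- effunet_state(tiny_model(seed = 9))
  expect_identical(a, b)
  c <- effunet_state(tiny_model(seed = 10))
  expect_false(identical(a, c))
})

test_that("evaluation-mode forward is deterministic and item-independent", {
  m <- tiny_model()
  set.seed(3)
  specs <- replicate(3, matrix(rnorm(128 * 1056), 128, 1056), simplify = FALSE)
  r1 <- effunet_forward(m, specs)
  r2 <- effunet_forward(m, rev(specs))
  expect_equal(r1[[1]]$probabilities, r2[[3]]$probabilities)
  expect_equal(r1[[2]]$probabilities, r2[[2]]$probabilities)
  expect_identical(effunet_forward(m, specs[[1]])$probabilities,
                   effunet_forward(m, specs[[1]])$probabilities)
})

test_that("pretrained encoder import replaces encoder weights only", {
  donor <- tiny_model(seed = 20)
  target <- tiny_model(seed = 21)
  enc <- effunet_state(donor, encoder_only = TRUE)
  dec_before <- effunet_state(target)
  dec_before <- dec_before[!startsWith(names(dec_before), "encoder.")]
  load_pretrained_encoder(target, enc)
  expect_identical(effunet_state(target, encoder_only = TRUE), enc)
  dec_after <- effunet_state(target)
  dec_after <- dec_after[!startsWith(names(dec_after), "encoder.")]
  expect_identical(dec_after, dec_before)
})

test_that("mismatched pretrained tensors are rejected with their names", {
  target <- tiny_model()
  bad <- list("encoder.stem.conv.W" = matrix(0, 3, 3))
  expect_error(load_pretrained_encoder(target, bad), "encoder.stem.conv.W")
  expect_error(load_pretrained_encoder(target, list("decoder.block1.up.W" = 1)),
               "not an encoder tensor")
  expect_error(load_pretrained_encoder(target, list("encoder.nosuch.W" = 1)),
               "no such tensor")
})

test_that("checkpoints restore parameters and running statistics", {
  m <- tiny_model(seed = 30)
  set.seed(31)
  spec <- matrix(rnorm(128 * 1056), 128, 1056)
  # a train-mode pass moves the BN running stats away from init
  bowelspot:::effunet_fwd(m, spec, train = TRUE)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_identical(effunet_state(m2), effunet_state(m))
  expect_equal(effunet_forward(m2, spec)$probabilities,
               effunet_forward(m, spec)$probabilities)
})

test_that("a training step produces finite nonzero gradients everywhere", {
  m <- tiny_model(seed = 5)
  set.seed(6)
  spec <- matrix(rnorm(128 * 1056), 128, 1056)
  mask <- as.numeric(runif(1056) > 0.9)
  bowelspot:::zero_grads(m$modules)
  fw <- bowelspot:::effunet_fwd(m, spec, train = TRUE)
  lg <- bowelspot:::loss_grad(fw$logits, mask, 998L)
  bowelspot:::effunet_bwd(m, fw$cache, lg$dlogits)
  gnorms <- vapply(m$modules, function(l)
    sum(vapply(l$g, function(g) sum(abs(g)), numeric(1))), numeric(1))
  expect_true(all(is.finite(gnorms)))
  expect_true(all(gnorms > 0))
})

test_that("layer backward passes agree with numerical differentiation", {
  set.seed(7)
  m <- build_effunet(effunet_config("tiny"), seed = 7)
  spec <- matrix(rnorm(16 * 24), 16, 24)
  mask <- as.numeric(runif(24) > 0.6)
  loss_of <- function() {
    fw <- bowelspot:::effunet_fwd(m, spec, train = TRUE)
    bowelspot:::loss_grad(fw$logits, mask, 20L)
  }
  bowelspot:::zero_grads(m$modules)
  fw <- bowelspot:::effunet_fwd(m, spec, train = TRUE)
  lg <- loss_of()
  bowelspot:::effunet_bwd(m, fw$cache, lg$dlogits)
  eps <- 1e-5
  set.seed(8)
  for (mod_name in sample(names(m$modules), 12)) {
    l <- m$modules[[mod_name]]
    for (pn in names(l$p)) {
      ii <- sample(length(l$p[[pn]]), 1)
      orig <- l$p[[pn]][ii]
      l$p[[pn]][ii] <- orig + eps
      lp <- loss_of()$loss
      l$p[[pn]][ii] <- orig - eps
      lm <- loss_of()$loss
      l$p[[pn]][ii] <- orig
      num <- (lp - lm) / (2 * eps)
      ana <- l$g[[pn]][ii]
      expect_equal(ana, num, tolerance = 1e-3,
                   label = paste0(mod_name, ".", pn, " analytic grad"))
    }
  }
})
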