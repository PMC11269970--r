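# Minimal convolutional network engine.
#
# Feature maps are numeric arrays of dim (H, W, C), column-major, with
# H = Mel bins and W = time frames. Every layer is an environment
# holding named parameters in $p and accumulated gradients in $g; the
# forward functions return the output plus a cache, and the backward
# functions consume the cache, accumulate parameter gradients and
# return the input gradient. Spatial convolutions run through compiled
# direct-convolution kernels; pointwise (1x1) convolutions are BLAS
# matrix products. Backward passes are verified against numerical
# differentiation in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))
silu <- function(x) x * sigmoid(x)
silu_grad <- function(x) { s <- sigmoid(x); s * (1 + x * (1 - s)) }

he_init <- function(n, fan_in) stats::rnorm(n) * sqrt(2 / fan_in)

new_layer <- function(.kind, .p, ...) {
  l <- new.env(parent = emptyenv())
  l$kind <- .kind
  l$p <- .p
  l$g <- lapply(.p, function(x) { y <- x; y[] <- 0; y })
  extras <- list(...)
  for (nm in names(extras)) assign(nm, extras[[nm]], envir = l)
  l
}

zero_grads <- function(modules) {
  for (l in modules) for (nm in names(l$g)) l$g[[nm]][] <- 0
  invisible(NULL)
}

## ---- standard 2-D convolution -------------------------------------

layer_conv <- function(cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L,
                       bias = FALSE) {
  p <- list(W = matrix(he_init(cout * k * k * cin, k * k * cin),
                       nrow = cout, ncol = k * k * cin, byrow = TRUE))
  if (bias) p$b <- numeric(cout)
  new_layer("conv", p, cin = cin, cout = cout, k = k,
            stride = as.integer(stride), pad = as.integer(pad))
}

conv_fwd <- function(l, x) {
  d <- dim(x)
  if (l$k == 1L && l$stride == 1L) {
    # pointwise convolution: a plain channel-mixing matrix product
    xm <- matrix(x, d[1] * d[2], d[3])
    ym <- xm %*% t(l$p$W)
    if (!is.null(l$p$b)) ym <- ym + rep(l$p$b, each = d[1] * d[2])
    return(list(y = array(ym, dim = c(d[1], d[2], l$cout)),
                cache = list(x = x, dims = d, ho = d[1], wo = d[2])))
  }
  ho <- (d[1] + 2 * l$pad - l$k) %/% l$stride + 1L
  wo <- (d[2] + 2 * l$pad - l$k) %/% l$stride + 1L
  yv <- conv2d_fwd_cpp(x, d[1], d[2], d[3], l$p$W, l$k, l$stride, l$pad)
  if (!is.null(l$p$b)) yv <- yv + rep(l$p$b, each = ho * wo)
  dim(yv) <- c(ho, wo, l$cout)
  list(y = yv, cache = list(x = x, dims = d, ho = ho, wo = wo))
}

conv_bwd <- function(l, cache, dy) {
  d <- cache$dims
  dym <- matrix(dy, cache$ho * cache$wo, l$cout)
  if (l$k == 1L && l$stride == 1L) {
    xm <- matrix(cache$x, d[1] * d[2], d[3])
    l$g$W <- l$g$W + crossprod(dym, xm)
    if (!is.null(l$p$b)) l$g$b <- l$g$b + colSums(dym)
    return(array(dym %*% l$p$W, dim = d))
  }
  res <- conv2d_bwd_cpp(cache$x, dy, d[1], d[2], d[3], l$p$W,
                        l$k, l$stride, l$pad)
  l$g$W <- l$g$W + res$dw
  if (!is.null(l$p$b)) l$g$b <- l$g$b + colSums(dym)
  dx <- res$dx
  dim(dx) <- d
  dx
}

## ---- depthwise convolution ----------------------------------------

layer_dwconv <- function(c, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  p <- list(W = array(he_init(k * k * c, k * k), dim = c(k, k, c)))
  new_layer("dwconv", p, c = c, k = k, stride = as.integer(stride),
            pad = as.integer(pad))
}

dwconv_fwd <- function(l, x) {
  d <- dim(x)
  ho <- (d[1] + 2 * l$pad - l$k) %/% l$stride + 1L
  wo <- (d[2] + 2 * l$pad - l$k) %/% l$stride + 1L
  y <- dwconv_fwd_cpp(x, d[1], d[2], d[3], l$p$W, l$k, l$stride, l$pad)
  dim(y) <- c(ho, wo, d[3])
  list(y = y, cache = list(x = x, dims = d))
}

dwconv_bwd <- function(l, cache, dy) {
  d <- cache$dims
  res <- dwconv_bwd_cpp(cache$x, dy, d[1], d[2], d[3], l$p$W,
                        l$k, l$stride, l$pad)
  dw <- res$dw
  dim(dw) <- dim(l$p$W)
  l$g$W <- l$g$W + dw
  dx <- res$dx
  dim(dx) <- d
  dx
}

## ---- batch normalization (per-map statistics) ----------------------

layer_bn <- function(c) {
  l <- new_layer("bn", list(gamma = rep(1, c), beta = numeric(c)), c = c)
  l$run_mean <- numeric(c)
  l$run_var <- rep(1, c)
  l$momentum <- 0.1
  l$eps <- 1e-5
  l
}

bn_fwd <- function(l, x, train) {
  d <- dim(x)
  hw <- d[1] * d[2]
  if (train) {
    st <- channel_stats_cpp(x, hw, d[3])
    mu <- st$mean
    v <- st$var
    l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * mu
    l$run_var <- (1 - l$momentum) * l$run_var + l$momentum * v
  } else {
    mu <- l$run_mean
    v <- l$run_var
  }
  invstd <- 1 / sqrt(v + l$eps)
  r <- bn_fwd_cpp(x, hw, d[3], l$p$gamma, l$p$beta, mu, invstd)
  y <- r$y
  dim(y) <- d
  list(y = y,
       cache = list(xhat = r$xhat, invstd = invstd, dims = d, train = train))
}

bn_bwd <- function(l, cache, dy) {
  d <- cache$dims
  hw <- d[1] * d[2]
  l$g$gamma <- l$g$gamma + .colSums(dy * cache$xhat, hw, d[3])
  l$g$beta <- l$g$beta + .colSums(dy, hw, d[3])
  dx <- bn_bwd_cpp(cache$xhat, dy, hw, d[3], l$p$gamma, cache$invstd,
                   cache$train)
  dim(dx) <- d
  dx
}

## ---- activations ----------------------------------------------------

act_fwd <- function(x, kind) {
  y <- switch(kind, silu = silu(x), relu = pmax(x, 0))
  list(y = y, cache = x)
}

act_bwd <- function(cache, dy, kind) {
  switch(kind,
         silu = dy * silu_grad(cache),
         relu = dy * (cache > 0))
}

## ---- squeeze-and-excitation -----------------------------------------

layer_se <- function(c, se_ch) {
  p <- list(W1 = matrix(he_init(se_ch * c, c), se_ch, c),
            b1 = numeric(se_ch),
            W2 = matrix(he_init(c * se_ch, se_ch), c, se_ch),
            b2 = numeric(c))
  new_layer("se", p, c = c, se_ch = se_ch)
}

se_fwd <- function(l, x) {
  d <- dim(x)
  hw <- d[1] * d[2]
  xm <- matrix(x, hw, d[3])
  s <- colMeans(xm)
  z1 <- as.numeric(l$p$W1 %*% s + l$p$b1)
  a1 <- silu(z1)
  z2 <- as.numeric(l$p$W2 %*% a1 + l$p$b2)
  gate <- sigmoid(z2)
  ym <- xm * rep(gate, each = hw)
  list(y = array(ym, dim = d),
       cache = list(xm = xm, s = s, z1 = z1, a1 = a1, gate = gate, dims = d))
}

se_bwd <- function(l, cache, dy) {
  d <- cache$dims
  hw <- d[1] * d[2]
  dym <- matrix(dy, hw, d[3])
  dgate <- colSums(dym * cache$xm)
  dxm <- dym * rep(cache$gate, each = hw)
  dz2 <- dgate * cache$gate * (1 - cache$gate)
  l$g$W2 <- l$g$W2 + dz2 %*% t(cache$a1)
  l$g$b2 <- l$g$b2 + dz2
  da1 <- as.numeric(crossprod(l$p$W2, dz2))
  dz1 <- da1 * silu_grad(cache$z1)
  l$g$W1 <- l$g$W1 + dz1 %*% t(cache$s)
  l$g$b1 <- l$g$b1 + dz1
  ds <- as.numeric(crossprod(l$p$W1, dz1))
  dxm <- dxm + rep(ds / hw, each = hw)
  array(dxm, dim = d)
}

## ---- 2x2 stride-2 transposed convolution ----------------------------

layer_tconv <- function(cin, cout) {
  p <- list(W = array(he_init(4 * cin * cout, 4 * cin),
                      dim = c(2, 2, cin, cout)),
            b = numeric(cout))
  new_layer("tconv", p, cin = cin, cout = cout)
}

tconv_fwd <- function(l, x) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  y <- array(0, dim = c(2 * d[1], 2 * d[2], l$cout))
  for (dh in 1:2) for (dw in 1:2) {
    Wm <- matrix(l$p$W[dh, dw, , ], nrow = l$cin, ncol = l$cout)
    part <- xm %*% Wm
    y[seq(dh, 2 * d[1], 2), seq(dw, 2 * d[2], 2), ] <-
      array(part, dim = c(d[1], d[2], l$cout))
  }
  y <- y + rep(l$p$b, each = 4 * d[1] * d[2])
  list(y = y, cache = list(xm = xm, dims = d))
}

tconv_bwd <- function(l, cache, dy) {
  d <- cache$dims
  dxm <- matrix(0, d[1] * d[2], l$cin)
  for (dh in 1:2) for (dw in 1:2) {
    dpart <- matrix(dy[seq(dh, 2 * d[1], 2), seq(dw, 2 * d[2], 2), ],
                    d[1] * d[2], l$cout)
    Wm <- matrix(l$p$W[dh, dw, , ], nrow = l$cin, ncol = l$cout)
    l$g$W[dh, dw, , ] <- l$g$W[dh, dw, , ] +
      array(crossprod(cache$xm, dpart), dim = c(l$cin, l$cout))
    dxm <- dxm + dpart %*% t(Wm)
  }
  l$g$b <- l$g$b + colSums(matrix(dy, ncol = l$cout))
  array(dxm, dim = d)
}

## ---- Adam optimizer --------------------------------------------------

adam_state <- function(modules) {
  list(step = 0L,
       m = lapply(modules, function(l) lapply(l$p, function(x) { y <- x; y[] <- 0; y })),
       v = lapply(modules, function(l) lapply(l$p, function(x) { y <- x; y[] <- 0; y })))
}

adam_step <- function(modules, state, lr, beta1 = 0.95, beta2 = 0.999,
                      weight_decay = 5e-7, eps = 1e-8, grad_scale = 1) {
  state$step <- state$step + 1L
  bc1 <- 1 - beta1^state$step
  bc2 <- 1 - beta2^state$step
  for (i in seq_along(modules)) {
    l <- modules[[i]]
    for (nm in names(l$p)) {
      g <- l$g[[nm]] * grad_scale + weight_decay * l$p[[nm]]
      state$m[[i]][[nm]] <- beta1 * state$m[[i]][[nm]] + (1 - beta1) * g
      state$v[[i]][[nm]] <- beta2 * state$v[[i]][[nm]] + (1 - beta2) * g^2
      mhat <- state$m[[i]][[nm]] / bc1
      vhat <- state$v[[i]][[nm]] / bc2
      l$p[[nm]] <- l$p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  state
}
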