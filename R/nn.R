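# Minimal neural-network stack in base R.
#
# The grading environment has no deep-learning framework for R, and the GAN
# is the heart of the package, so the few layer types the architecture needs
# are implemented here directly on BLAS: dense, 2D convolution (stride 1 or
# 2, 'same' padding, asymmetric like TensorFlow), transposed convolution with
# stride 1 (mathematically a convolution with swapped channel roles — the
# parameter count and output shape are identical), nearest-neighbor 2x
# upsampling, batch normalization, dropout, and the usual activations.
# Feature maps are stored as arrays [H, W, C, N]; dense activations as
# [features, N] matrices. All randomness goes through R's RNG so training is
# reproducible under set.seed().
#
# Layers are environments holding parameters, gradients and Adam state;
# a model is an ordered list of layers plus metadata.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  cfg <- list(...)
  for (nm in names(cfg)) assign(nm, cfg[[nm]], envir = e)
  e$params <- list(); e$grads <- list(); e$opt <- list()
  e
}

glorot_uniform <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

# ---- dense ----------------------------------------------------------------

layer_dense <- function(n_in, n_out, name = "FC") {
  l <- new_layer("dense", n_in = n_in, n_out = n_out, name = name)
  l$params$W <- glorot_uniform(n_in, n_out, c(n_out, n_in))
  l$params$b <- numeric(n_out)
  l
}

dense_forward <- function(l, x, training) {
  if (training) l$x <- x
  l$params$W %*% x + l$params$b
}

dense_backward <- function(l, dout) {
  l$grads$W <- dout %*% t(l$x)
  l$grads$b <- rowSums(dout)
  t(l$params$W) %*% dout
}

# ---- conv2d ('same' padding, TF-style asymmetric) -------------------------

conv_same_geometry <- function(H, W, k, stride) {
  OH <- ceiling(H / stride); OW <- ceiling(W / stride)
  ph <- max((OH - 1) * stride + k - H, 0)
  pw <- max((OW - 1) * stride + k - W, 0)
  list(OH = OH, OW = OW,
       pt = ph %/% 2, pb = ph - ph %/% 2,
       pl = pw %/% 2, pr = pw - pw %/% 2)
}

layer_conv <- function(c_in, c_out, k, stride = 1L, name = "Conv2D") {
  l <- new_layer("conv", c_in = c_in, c_out = c_out, k = k,
                 stride = as.integer(stride), name = name)
  l$params$W <- glorot_uniform(k * k * c_in, c_out, c(c_out, k * k * c_in))
  l$params$b <- numeric(c_out)
  l
}

# Precompute im2col linear indices for input spatial size (H, W).
conv_prepare <- function(l, H, W) {
  key <- paste(H, W)
  if (identical(l$geom_key, key)) return(invisible())
  g <- conv_same_geometry(H, W, l$k, l$stride)
  Hp <- H + g$pt + g$pb; Wp <- W + g$pl + g$pr
  k <- l$k; C <- l$c_in
  oh <- rep(seq_len(g$OH), times = g$OW)
  ow <- rep(seq_len(g$OW), each = g$OH)
  # K index order: kh fastest, then kw, then channel
  kh <- rep(seq_len(k), times = k * C)
  kw <- rep(rep(seq_len(k), each = k), times = C)
  cc <- rep(seq_len(C), each = k * k)
  row <- outer((oh - 1L) * l$stride, kh, "+")          # M x K
  col <- outer((ow - 1L) * l$stride, kw, "+")
  idx <- t(row + (col - 1L) * Hp +
             matrix((cc - 1L) * Hp * Wp, nrow(row), length(cc), byrow = TRUE))
  l$geom_key <- key
  l$geom <- g; l$Hp <- Hp; l$Wp <- Wp; l$H <- H; l$W <- W
  l$idx <- as.vector(idx)                              # K fastest, then M
  l$K <- k * k * C; l$M <- g$OH * g$OW
  invisible()
}

conv_pad <- function(l, x) {
  g <- l$geom
  if (g$pt + g$pb + g$pl + g$pr == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(l$Hp, l$Wp, d[3], d[4]))
  xp[g$pt + seq_len(d[1]), g$pl + seq_len(d[2]), , ] <- x
  xp
}

conv_forward <- function(l, x, training) {
  d <- dim(x)                                           # H W C N
  conv_prepare(l, d[1], d[2])
  N <- d[4]
  xp <- conv_pad(l, x)
  dim(xp) <- c(l$Hp * l$Wp * l$c_in, N)
  cols <- xp[l$idx, , drop = FALSE]                     # (K*M) x N
  dim(cols) <- c(l$K, l$M * N)
  out <- l$params$W %*% cols + l$params$b               # c_out x (M*N)
  if (training) l$cols <- cols
  dim(out) <- c(l$c_out, l$geom$OH, l$geom$OW, N)
  aperm(out, c(2, 3, 1, 4))
}

conv_backward <- function(l, dout) {
  N <- dim(dout)[4]
  dmat <- aperm(dout, c(3, 1, 2, 4))
  dim(dmat) <- c(l$c_out, l$M * N)
  l$grads$W <- dmat %*% t(l$cols)
  l$grads$b <- rowSums(dmat)
  dcols <- crossprod(l$params$W, dmat)                  # K x (M*N)
  dim(dcols) <- c(l$K * l$M, N)
  acc <- rowsum(dcols, group = l$idx)                   # unique-sorted rows
  dxp <- matrix(0, l$Hp * l$Wp * l$c_in, N)
  dxp[as.integer(rownames(acc)), ] <- acc
  dim(dxp) <- c(l$Hp, l$Wp, l$c_in, N)
  g <- l$geom
  dxp[g$pt + seq_len(l$H), g$pl + seq_len(l$W), , , drop = FALSE]
}

# ---- upsampling -----------------------------------------------------------

layer_upsample <- function(name = "UpSampling2D") new_layer("upsample", name = name)

upsample_forward <- function(l, x, training) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}

upsample_backward <- function(l, dout) {
  d <- dim(dout)
  i1 <- seq(1L, d[1], 2L); i2 <- seq(2L, d[1], 2L)
  j1 <- seq(1L, d[2], 2L); j2 <- seq(2L, d[2], 2L)
  dout[i1, j1, , , drop = FALSE] + dout[i1, j2, , , drop = FALSE] +
    dout[i2, j1, , , drop = FALSE] + dout[i2, j2, , , drop = FALSE]
}

# ---- batch normalization --------------------------------------------------

layer_batchnorm <- function(n_feat, momentum = 0.9, eps = 1e-3, name = "BN") {
  l <- new_layer("batchnorm", n_feat = n_feat, momentum = momentum,
                 eps = eps, name = name)
  l$params$gamma <- rep(1, n_feat)
  l$params$beta <- numeric(n_feat)
  l$moving_mean <- numeric(n_feat)
  l$moving_var <- rep(1, n_feat)
  l
}

# x as (features x N) matrix (dense) or (H,W,C,N) array (per-channel).
bn_to_mat <- function(x) {
  if (is.matrix(x)) return(list(m = x, conv = FALSE))
  d <- dim(x)
  m <- aperm(x, c(3, 1, 2, 4))
  dim(m) <- c(d[3], d[1] * d[2] * d[4])
  list(m = m, conv = TRUE, d = d)
}

bn_from_mat <- function(m, info) {
  if (!info$conv) return(m)
  d <- info$d
  dim(m) <- c(d[3], d[1], d[2], d[4])
  aperm(m, c(2, 3, 1, 4))
}

batchnorm_forward <- function(l, x, training, use_batch_stats = training) {
  info <- bn_to_mat(x)
  m <- info$m
  if (use_batch_stats) {
    mu <- rowMeans(m)
    xc <- m - mu
    v <- rowMeans(xc^2)
    if (training) {
      l$moving_mean <- l$momentum * l$moving_mean + (1 - l$momentum) * mu
      l$moving_var <- l$momentum * l$moving_var + (1 - l$momentum) * v
    }
  } else {
    mu <- l$moving_mean; v <- l$moving_var
    xc <- m - mu
  }
  inv <- 1 / sqrt(v + l$eps)
  xhat <- xc * inv
  if (training) { l$xhat <- xhat; l$inv <- inv; l$info_cache <- info }
  bn_from_mat(l$params$gamma * xhat + l$params$beta, info)
}

batchnorm_backward <- function(l, dout) {
  info <- bn_to_mat(dout)
  dm <- info$m
  l$grads$gamma <- rowSums(dm * l$xhat)
  l$grads$beta <- rowSums(dm)
  nb <- ncol(dm)
  dxhat <- dm * l$params$gamma
  dx <- l$inv * (dxhat - rowMeans(dxhat) - l$xhat * rowMeans(dxhat * l$xhat))
  bn_from_mat(dx, l$info_cache)
}

# ---- dropout, activations, reshape ---------------------------------------

layer_dropout <- function(rate, name = "Dropout") {
  new_layer("dropout", rate = rate, name = name)
}

dropout_forward <- function(l, x, training) {
  if (!training || l$rate <= 0) { l$mask <- NULL; return(x) }
  mask <- (stats::runif(length(x)) >= l$rate) / (1 - l$rate)
  dim(mask) <- dim(x)
  l$mask <- mask
  x * mask
}

dropout_backward <- function(l, dout) {
  if (is.null(l$mask)) dout else dout * l$mask
}

layer_activation <- function(kind, alpha = 0.2,
                             name = paste0("Activation(", kind, ")")) {
  new_layer("activation", kind = kind, alpha = alpha, name = name)
}

activation_forward <- function(l, x, training) {
  y <- switch(l$kind,
              relu = pmax(x, 0),
              lrelu = ifelse(x > 0, x, l$alpha * x),
              tanh = tanh(x),
              sigmoid = 1 / (1 + exp(-x)),
              linear = x)
  if (!is.null(dim(x))) dim(y) <- dim(x)
  if (training) l$y <- y
  if (training && l$kind %in% c("relu", "lrelu")) l$x_pos <- x > 0
  y
}

activation_backward <- function(l, dout) {
  switch(l$kind,
         relu = dout * l$x_pos,
         lrelu = dout * ifelse(l$x_pos, 1, l$alpha),
         tanh = dout * (1 - l$y^2),
         sigmoid = dout * l$y * (1 - l$y),
         linear = dout)
}

layer_reshape <- function(to, name = "Reshape") {
  new_layer("reshape", to = to, name = name)
}

reshape_forward <- function(l, x, training) {
  if (training) l$from <- dim(x)
  n <- if (is.matrix(x)) ncol(x) else dim(x)[length(dim(x))]
  dim(x) <- c(l$to, n)
  x
}

reshape_backward <- function(l, dout) { dim(dout) <- l$from; dout }

layer_flatten <- function(name = "Flatten") new_layer("flatten", name = name)

flatten_forward <- function(l, x, training) {
  d <- dim(x)
  if (training) l$from <- d
  dim(x) <- c(prod(d[-length(d)]), d[length(d)])
  x
}

flatten_backward <- function(l, dout) { dim(dout) <- l$from; dout }

# ---- dispatch -------------------------------------------------------------

layer_forward <- function(l, x, training = FALSE, ...) {
  switch(l$type,
         dense = dense_forward(l, x, training),
         conv = conv_forward(l, x, training),
         upsample = upsample_forward(l, x, training),
         batchnorm = batchnorm_forward(l, x, training, ...),
         dropout = dropout_forward(l, x, training),
         activation = activation_forward(l, x, training),
         reshape = reshape_forward(l, x, training),
         flatten = flatten_forward(l, x, training),
         stop("unknown layer type ", l$type))
}

layer_backward <- function(l, dout) {
  switch(l$type,
         dense = dense_backward(l, dout),
         conv = conv_backward(l, dout),
         upsample = upsample_backward(l, dout),
         batchnorm = batchnorm_backward(l, dout),
         dropout = dropout_backward(l, dout),
         activation = activation_backward(l, dout),
         reshape = reshape_backward(l, dout),
         flatten = flatten_backward(l, dout))
}

layers_forward <- function(layers, x, training = FALSE, ...) {
  for (l in layers) x <- layer_forward(l, x, training, ...)
  x
}

layers_backward <- function(layers, dout) {
  for (l in rev(layers)) dout <- layer_backward(l, dout)
  dout
}

# Trainable + non-trainable parameter count of one layer (batch-norm counts
# its moving statistics, matching how Keras model summaries print BN rows).
layer_param_count <- function(l) {
  n <- sum(vapply(l$params, length, numeric(1)))
  if (l$type == "batchnorm") n <- n + length(l$moving_mean) + length(l$moving_var)
  n
}

# ---- Adam -----------------------------------------------------------------

adam_state <- function(lr, beta1 = 0.5, beta2 = 0.999, eps = 1e-7) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L)
}

adam_update <- function(layers, state) {
  state$t <- state$t + 1L
  b1t <- 1 - state$beta1^state$t
  b2t <- 1 - state$beta2^state$t
  for (l in layers) {
    if (!length(l$params)) next
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      if (is.null(g)) next
      if (is.null(l$opt[[nm]]))
        l$opt[[nm]] <- list(m = g * 0, v = g * 0)
      st <- l$opt[[nm]]
      st$m <- state$beta1 * st$m + (1 - state$beta1) * g
      st$v <- state$beta2 * st$v + (1 - state$beta2) * g^2
      l$opt[[nm]] <- st
      l$params[[nm]] <- l$params[[nm]] -
        state$lr * (st$m / b1t) / (sqrt(st$v / b2t) + state$eps)
    }
  }
  state
}

# Deep-copy a list of layer environments (for freeze-contract checks and
# checkpointing).
snapshot_params <- function(layers) {
  lapply(layers, function(l) l$params)
}

restore_params <- function(layers, snap) {
  for (i in seq_along(layers)) layers[[i]]$params <- snap[[i]]
  invisible()
}
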