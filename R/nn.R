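# Lightweight TVP classifier network and its training engine.
#
# Architecture (fixed layer order, widths configurable):
#   conv1(3x3, same) -> leaky ReLU -> avgpool 2x2 -> batch norm
#   conv2(3x3, same) -> leaky ReLU -> avgpool 2x2 -> batch norm
#   conv3(3x3, same) -> leaky ReLU -> batch norm
#   flatten -> dropout(0.25) -> FC1 -> leaky ReLU -> dropout(0.25)
#   -> FC2 -> SoftMax
# Batch normalization precedes every convolution/fully-connected layer
# except the first (inputs are already z-scored per scan) and the last.
# Weights and biases are Xavier (Glorot-uniform) initialized; training is
# Adam on cross-entropy.
#
# Everything is vectorized base R: convolutions are lowered to matrix
# products via an im2col gather (and a rowsum scatter for the backward
# pass), so the heavy lifting runs in BLAS.  Inference is deterministic:
# dropout is inactive and batch norm uses its running statistics.

#' Configuration of the TVP classifier network
#'
#' The printed parameter totals of the original architecture are
#' under-determined by its description (filter counts and hidden width are
#' not stated), so a reference configuration is pinned here; its exact
#' counts (97,816 total / 97,592 trainable / 224 non-trainable, see
#' [count_parameters()]) are the testable surface.
#'
#' @param conv_filters integer vector `(f1, f2, f3)` of filters per
#'   convolution layer.
#' @param fc_hidden width of the first fully connected layer.
#' @param leaky_slope negative-side slope of the leaky ReLU.
#' @param dropout_rate dropout probability (both dropout sites).
#' @param n_classes number of output classes (binary tasks: 2).
#' @param input_shape patch shape `(alpha, beta, channels)`.
#' @param bn_momentum running-statistic momentum of batch normalization.
#' @param bn_eps batch normalization variance floor.
#' @return a `model_config` list.
#' @export
model_config <- function(conv_filters = c(16L, 32L, 64L), fc_hidden = 18L,
                         leaky_slope = 0.3, dropout_rate = 0.25,
                         n_classes = 2L, input_shape = c(32L, 32L, 3L),
                         bn_momentum = 0.9, bn_eps = 1e-3) {
  stopifnot(
    length(conv_filters) == 3, all(conv_filters >= 1),
    fc_hidden >= 1, leaky_slope > 0,
    dropout_rate >= 0, dropout_rate < 1, n_classes == 2,
    length(input_shape) == 3, input_shape[1] %% 4 == 0, input_shape[2] %% 4 == 0
  )
  structure(
    list(
      conv_filters = as.integer(conv_filters), kernel = 3L,
      fc_hidden = as.integer(fc_hidden), leaky_slope = leaky_slope,
      dropout_rate = dropout_rate, n_classes = as.integer(n_classes),
      input_shape = as.integer(input_shape),
      bn_momentum = bn_momentum, bn_eps = bn_eps
    ),
    class = "model_config"
  )
}

glorot_uniform <- function(n, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -lim, lim)
}

#' Build (initialize) a TVP classifier
#'
#' @param config a [model_config()].
#' @param seed RNG seed for the Xavier initialization.
#' @return a `tvp_cnn` model object.
#' @export
build_model <- function(config = model_config(), seed = 1) {
  stopifnot(inherits(config, "model_config"))
  k <- config$kernel
  f <- config$conv_filters
  c_in <- config$input_shape[3]
  h1 <- config$input_shape[1] %/% 2L
  h2 <- h1 %/% 2L
  flat <- h2 * (config$input_shape[2] %/% 4L) * f[3]
  init_conv <- function(cin, cout) {
    fan_in <- k * k * cin
    fan_out <- k * k * cout
    list(
      W = matrix(glorot_uniform(k * k * cin * cout, fan_in, fan_out), k * k * cin, cout),
      b = glorot_uniform(cout, fan_in, fan_out)
    )
  }
  init_dense <- function(din, dout) {
    list(
      W = matrix(glorot_uniform(din * dout, din, dout), din, dout),
      b = glorot_uniform(dout, din, dout)
    )
  }
  init_bn <- function(cc) {
    list(
      gamma = rep(1, cc), beta = rep(0, cc),
      run_mean = rep(0, cc), run_var = rep(1, cc)
    )
  }
  params <- with_seed(seed, list(
    conv1 = init_conv(c_in, f[1]),
    bn1 = init_bn(f[1]),
    conv2 = init_conv(f[1], f[2]),
    bn2 = init_bn(f[2]),
    conv3 = init_conv(f[2], f[3]),
    bn3 = init_bn(f[3]),
    fc1 = init_dense(flat, config$fc_hidden),
    fc2 = init_dense(config$fc_hidden, config$n_classes)
  ))
  structure(list(config = config, params = params), class = "tvp_cnn")
}

#' @export
print.tvp_cnn <- function(x, ...) {
  pc <- count_parameters(x)
  cat(sprintf(
    "<tvp_cnn: input %s, conv [%s], fc %d -> %d; %d parameters (%d trainable)>\n",
    paste(x$config$input_shape, collapse = "x"),
    paste(x$config$conv_filters, collapse = ","),
    x$config$fc_hidden, x$config$n_classes, pc$total, pc$trainable
  ))
  invisible(x)
}

#' Count model parameters
#'
#' A convolution contributes `(k^2 * C_in + 1) * C_out`; a dense layer
#' `(d_in + 1) * d_out`; batch normalization contributes `2C` trainable
#' (scale, shift) and `2C` non-trainable (running mean, running variance)
#' per `C`-channel layer.
#'
#' @param model a `tvp_cnn`.
#' @return a list: `total`, `trainable`, `non_trainable`.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "tvp_cnn"))
  p <- model$params
  trainable <- 0L
  non_trainable <- 0L
  for (nm in names(p)) {
    layer <- p[[nm]]
    if (startsWith(nm, "bn")) {
      trainable <- trainable + length(layer$gamma) + length(layer$beta)
      non_trainable <- non_trainable + length(layer$run_mean) + length(layer$run_var)
    } else {
      trainable <- trainable + length(layer$W) + length(layer$b)
    }
  }
  list(
    total = trainable + non_trainable,
    trainable = trainable, non_trainable = non_trainable
  )
}

## ---- low-level ops ---------------------------------------------------
#
# Activations travel as flat matrices of shape (H*W*N) x C: rows are
# spatial pixels nested within samples (pixel fastest, sample-major), and
# columns are channels.  In this layout convolution is a single gather
# plus one BLAS matmul, pooling is four row-subset additions, and batch
# normalization is plain column statistics -- no large array transposes.

# Spatial-grid descriptor carried through a layer (the compiled kernels
# take the raw dimensions).
conv_maps <- function(H, W, N) {
  list(H = as.integer(H), W = as.integer(W), N = as.integer(N), HW = H * W)
}

# [H, W, C, N] array -> (H*W*N) x C matrix in the engine layout.
to_mat_layout <- function(x) {
  d <- dim(x)
  X <- aperm(x, c(1, 2, 4, 3))
  dim(X) <- c(d[1] * d[2] * d[4], d[3])
  X
}

# 3x3 same-padded convolution.  W_mat rows are ordered (ki, kj, c_in)
# with ki fastest; the im2col gather produces columns in the same order,
# so the convolution is a single BLAS matmul.
conv_fwd_m <- function(X, mp, W_mat, b) {
  G <- im2col_m(X, mp$H, mp$W, mp$N)
  out <- G %*% W_mat
  out <- out + rep(b, each = nrow(X))
  list(out = out, G = G)
}

conv_bwd_m <- function(dout, G, mp, W_mat, C_in, need_dx = TRUE) {
  dW <- crossprod(G, dout)
  db <- colSums(dout)
  dX <- if (need_dx) {
    col2im_m(dout %*% t(W_mat), mp$H, mp$W, mp$N, C_in)
  } else {
    NULL
  }
  list(dx = dX, dW = dW, db = db)
}

pool_fwd_m <- function(X, mp) pool2_fwd(X, mp$H, mp$W, mp$N)

pool_bwd_m <- function(dY, mp) pool2_bwd(dY, mp$H, mp$W, mp$N)

leaky_forward <- function(x, slope) leaky_fwd_cpp(x, slope)

leaky_backward <- function(dy, x, slope) leaky_bwd_cpp(dy, x, slope)

# Channel-wise batch normalization: columns are channels.
bn_forward <- function(X, layer, eps, training) {
  M <- nrow(X)
  if (training) {
    mu <- colMeans(X)
    xc <- X - rep(mu, each = M)
    va <- colMeans(xc * xc)
  } else {
    mu <- layer$run_mean
    va <- layer$run_var
    xc <- X - rep(mu, each = M)
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- xc * rep(invstd, each = M)
  y <- xhat * rep(layer$gamma, each = M) + rep(layer$beta, each = M)
  list(y = y, xhat = xhat, invstd = invstd, batch_mean = mu, batch_var = va, M = M)
}

bn_backward <- function(dY, cache, layer) {
  M <- cache$M
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(layer$gamma, each = M)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dx <- (dxhat - rep(s1 / M, each = M) - cache$xhat * rep(s2 / M, each = M)) *
    rep(cache$invstd, each = M)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

## ---- forward / backward through the whole network --------------------

# x: [alpha, beta, 3, N].  Returns probabilities and (when training) the
# caches needed for the backward pass.  Dropout masks are drawn from the
# current RNG stream; callers seed it.
cnn_forward <- function(model, x, training = FALSE) {
  cfg <- model$config
  p <- model$params
  d <- dim(x)
  N <- d[4]
  X <- to_mat_layout(x)
  mp1 <- conv_maps(d[1], d[2], N)
  cv1 <- conv_fwd_m(X, mp1, p$conv1$W, p$conv1$b)
  a1 <- leaky_forward(cv1$out, cfg$leaky_slope)
  p1 <- pool_fwd_m(a1, mp1)
  bn1 <- bn_forward(p1, p$bn1, cfg$bn_eps, training)
  mp2 <- conv_maps(d[1] %/% 2L, d[2] %/% 2L, N)
  cv2 <- conv_fwd_m(bn1$y, mp2, p$conv2$W, p$conv2$b)
  a2 <- leaky_forward(cv2$out, cfg$leaky_slope)
  p2 <- pool_fwd_m(a2, mp2)
  bn2 <- bn_forward(p2, p$bn2, cfg$bn_eps, training)
  mp3 <- conv_maps(d[1] %/% 4L, d[2] %/% 4L, N)
  cv3 <- conv_fwd_m(bn2$y, mp3, p$conv3$W, p$conv3$b)
  a3 <- leaky_forward(cv3$out, cfg$leaky_slope)
  bn3 <- bn_forward(a3, p$bn3, cfg$bn_eps, training)
  # flatten (HW3*N) x C3 -> N x (HW3*C3), feature order pixel-then-channel
  HW3 <- mp3$HW
  C3 <- ncol(bn3$y)
  arr <- bn3$y
  dim(arr) <- c(HW3, N, C3)
  arr <- aperm(arr, c(1, 3, 2))
  dim(arr) <- c(HW3 * C3, N)
  flat <- t(arr)
  if (training && cfg$dropout_rate > 0) {
    m1 <- matrix(
      (stats::runif(length(flat)) >= cfg$dropout_rate) / (1 - cfg$dropout_rate),
      nrow(flat), ncol(flat)
    )
    flat_d <- flat * m1
  } else {
    m1 <- NULL
    flat_d <- flat
  }
  z1 <- flat_d %*% p$fc1$W + rep(p$fc1$b, each = N)
  h1 <- leaky_forward(z1, cfg$leaky_slope)
  if (training && cfg$dropout_rate > 0) {
    m2 <- matrix(
      (stats::runif(length(h1)) >= cfg$dropout_rate) / (1 - cfg$dropout_rate),
      nrow(h1), ncol(h1)
    )
    h1_d <- h1 * m2
  } else {
    m2 <- NULL
    h1_d <- h1
  }
  z2 <- h1_d %*% p$fc2$W + rep(p$fc2$b, each = N)
  probs <- softmax_rows(z2)
  out <- list(probs = probs)
  if (training) {
    out$cache <- list(
      x_dim = d, mp1 = mp1, mp2 = mp2, mp3 = mp3,
      cv1 = cv1, cv2 = cv2, cv3 = cv3,
      bn1 = bn1, bn2 = bn2, bn3 = bn3, HW3 = HW3, C3 = C3, N = N,
      m1 = m1, flat_d = flat_d, z1 = z1, m2 = m2, h1_d = h1_d,
      probs = probs
    )
  }
  out
}

# y: integer class index (1-based) per sample.  Returns the mean
# cross-entropy loss and the gradient list (same shape as params).
cnn_backward <- function(model, cache, y) {
  cfg <- model$config
  p <- model$params
  N <- length(y)
  probs <- cache$probs
  eps <- 1e-12
  loss <- -mean(log(probs[cbind(seq_len(N), y)] + eps))
  dz2 <- probs
  dz2[cbind(seq_len(N), y)] <- dz2[cbind(seq_len(N), y)] - 1
  dz2 <- dz2 / N
  g <- list()
  g$fc2 <- list(W = crossprod(cache$h1_d, dz2), b = colSums(dz2))
  dh1_d <- dz2 %*% t(p$fc2$W)
  dh1 <- if (is.null(cache$m2)) dh1_d else dh1_d * cache$m2
  dz1 <- leaky_backward(dh1, cache$z1, cfg$leaky_slope)
  g$fc1 <- list(W = crossprod(cache$flat_d, dz1), b = colSums(dz1))
  dflat_d <- dz1 %*% t(p$fc1$W)
  dflat <- if (is.null(cache$m1)) dflat_d else dflat_d * cache$m1
  # un-flatten N x (HW3*C3) -> (HW3*N) x C3
  darr <- t(dflat)
  dim(darr) <- c(cache$HW3, cache$C3, cache$N)
  darr <- aperm(darr, c(1, 3, 2))
  dim(darr) <- c(cache$HW3 * cache$N, cache$C3)
  bn3b <- bn_backward(darr, cache$bn3, p$bn3)
  g$bn3 <- list(gamma = bn3b$dgamma, beta = bn3b$dbeta)
  da3 <- leaky_backward(bn3b$dx, cache$cv3$out, cfg$leaky_slope)
  cv3b <- conv_bwd_m(da3, cache$cv3$G, cache$mp3, p$conv3$W, ncol(cache$bn2$y))
  g$conv3 <- list(W = cv3b$dW, b = cv3b$db)
  bn2b <- bn_backward(cv3b$dx, cache$bn2, p$bn2)
  g$bn2 <- list(gamma = bn2b$dgamma, beta = bn2b$dbeta)
  dp2 <- pool_bwd_m(bn2b$dx, cache$mp2)
  da2 <- leaky_backward(dp2, cache$cv2$out, cfg$leaky_slope)
  cv2b <- conv_bwd_m(da2, cache$cv2$G, cache$mp2, p$conv2$W, ncol(cache$bn1$y))
  g$conv2 <- list(W = cv2b$dW, b = cv2b$db)
  bn1b <- bn_backward(cv2b$dx, cache$bn1, p$bn1)
  g$bn1 <- list(gamma = bn1b$dgamma, beta = bn1b$dbeta)
  dp1 <- pool_bwd_m(bn1b$dx, cache$mp1)
  da1 <- leaky_backward(dp1, cache$cv1$out, cfg$leaky_slope)
  cv1b <- conv_bwd_m(da1, cache$cv1$G, cache$mp1, p$conv1$W, cache$x_dim[3],
    need_dx = FALSE
  )
  g$conv1 <- list(W = cv1b$dW, b = cv1b$db)
  list(loss = loss, grads = g)
}

# Update batch-norm running statistics after a training step.
bn_update_running <- function(model, cache) {
  mom <- model$config$bn_momentum
  for (nm in c("bn1", "bn2", "bn3")) {
    bc <- cache[[nm]]
    model$params[[nm]]$run_mean <-
      mom * model$params[[nm]]$run_mean + (1 - mom) * bc$batch_mean
    model$params[[nm]]$run_var <-
      mom * model$params[[nm]]$run_var + (1 - mom) * bc$batch_var
  }
  model
}

## ---- Adam ------------------------------------------------------------

adam_init <- function(params) {
  st <- list(t = 0)
  for (nm in names(params)) {
    for (fld in names(params[[nm]])) {
      if (fld %in% c("run_mean", "run_var")) next
      key <- paste(nm, fld, sep = ".")
      z <- params[[nm]][[fld]] * 0
      st[[key]] <- list(m = z, v = z)
    }
  }
  st
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    for (fld in names(grads[[nm]])) {
      key <- paste(nm, fld, sep = ".")
      g <- grads[[nm]][[fld]]
      s <- state[[key]]
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      state[[key]] <- s
      params[[nm]][[fld]] <- params[[nm]][[fld]] -
        lr * (s$m / bc1) / (sqrt(s$v / bc2) + eps)
    }
  }
  list(params = params, state = state)
}

## ---- public inference ------------------------------------------------

#' Per-patch class-probability pairs
#'
#' Runs the network in inference mode (dropout off, batch norm on running
#' statistics) over a set of TVPs.  Each output row is a SoftMax pair
#' summing to 1.
#'
#' @param model a `tvp_cnn`.
#' @param tvps a `tvp_dataset`, a single `tvp`, or a bare
#'   `alpha x beta x 3 x n` (or `alpha x beta x 3`) array.
#' @param batch_size forward-pass batch size.
#' @return an `n x 2` matrix of class probabilities.
#' @export
predict_patch_scores <- function(model, tvps, batch_size = 256L) {
  stopifnot(inherits(model, "tvp_cnn"))
  x <- if (inherits(tvps, "tvp_dataset")) {
    tvps$data
  } else if (inherits(tvps, "tvp")) {
    tvps$data
  } else {
    tvps
  }
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 4) stopf("patches must be alpha x beta x 3 x n")
  if (!all(dim(x)[1:3] == model$config$input_shape)) {
    stopf(
      "patch shape (%s) does not match model input (%s)",
      paste(dim(x)[1:3], collapse = "x"),
      paste(model$config$input_shape, collapse = "x")
    )
  }
  n <- dim(x)[4]
  out <- matrix(0, n, model$config$n_classes)
  at <- 1L
  while (at <= n) {
    take <- at:min(n, at + batch_size - 1L)
    out[take, ] <- cnn_forward(model, x[, , , take, drop = FALSE],
      training = FALSE
    )$probs
    at <- at + batch_size
  }
  out
}
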