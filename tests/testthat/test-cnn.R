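# The TVP classifier network: construction, parameter accounting,
# forward-pass contracts, convolution correctness.

test_that("forward pass yields SoftMax rows of the right shape", {
  m <- build_model(seed = 1)
  x <- array(rnorm(32 * 32 * 3 * 5), c(32, 32, 3, 5))
  p <- predict_patch_scores(m, x)
  expect_equal(dim(p), c(5, 2))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
})

test_that("initialization is seeded and reproducible", {
  a <- build_model(seed = 7)
  b <- build_model(seed = 7)
  c <- build_model(seed = 8)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params$conv1$W, c$params$conv1$W))
})

test_that("parameter counts follow the layer formulas exactly", {
  pc <- count_parameters(build_model())
  expect_identical(pc$total, 97816L)
  expect_identical(pc$trainable, 97592L)
  expect_identical(pc$non_trainable, 224L)
  expect_identical(pc$non_trainable, 2L * (16L + 32L + 64L))
  expect_equal(pc$total, pc$trainable + pc$non_trainable)

  # minimal configuration, recounted by hand with the same formulas:
  # conv (k^2 C_in + 1) C_out; dense (d_in + 1) d_out; BN 4C (2C + 2C)
  tiny <- build_model(model_config(conv_filters = c(1, 1, 1), fc_hidden = 1))
  pt <- count_parameters(tiny)
  conv <- (9 * 3 + 1) * 1 + (9 * 1 + 1) * 1 + (9 * 1 + 1) * 1
  dense <- (8 * 8 * 1 + 1) * 1 + (1 + 1) * 2
  expect_identical(pt$trainable, as.integer(conv + dense + 3 * 2 * 1))
  expect_identical(pt$non_trainable, 6L)
})

test_that("inference is deterministic and batching-invariant", {
  m <- build_model(seed = 3)
  x1 <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  batch <- array(0, c(32, 32, 3, 4))
  for (i in 1:4) batch[, , , i] <- x1
  p <- predict_patch_scores(m, batch)
  expect_equal(p[1, ], p[2, ], tolerance = 0)
  expect_equal(p[1, ], p[4, ], tolerance = 0)
  # batch vs one-at-a-time
  set.seed(10)
  xs <- array(rnorm(32 * 32 * 3 * 6), c(32, 32, 3, 6))
  pb <- predict_patch_scores(m, xs)
  for (i in 1:6) {
    ps <- predict_patch_scores(m, xs[, , , i])
    expect_equal(unname(pb[i, ]), unname(ps[1, ]), tolerance = 1e-5)
  }
})

test_that("shape mismatches are rejected", {
  m <- build_model(seed = 1)
  expect_error(predict_patch_scores(m, array(0, c(16, 16, 3, 2))), "shape")
})

test_that("the im2col convolution equals brute-force convolution", {
  set.seed(2)
  H <- 7; W <- 6; C <- 2; Fo <- 3; N <- 3
  x <- array(rnorm(H * W * C * N), c(H, W, C, N))
  Wm <- matrix(rnorm(9 * C * Fo), 9 * C, Fo)
  b <- rnorm(Fo)
  mp <- tvpstage:::conv_maps(H, W, N)
  out_mat <- tvpstage:::conv_fwd_m(tvpstage:::to_mat_layout(x), mp, Wm, b)$out
  fast <- array(out_mat, c(H, W, N, Fo))
  fast <- aperm(fast, c(1, 2, 4, 3))
  Warr <- array(Wm, c(3, 3, C, Fo))
  xp <- array(0, c(H + 2, W + 2, C, N))
  xp[2:(H + 1), 2:(W + 1), , ] <- x
  slow <- array(0, c(H, W, Fo, N))
  for (n in 1:N) for (f in 1:Fo) for (i in 1:H) for (j in 1:W) {
    acc <- b[f]
    for (c in 1:C) for (ki in 1:3) for (kj in 1:3) {
      acc <- acc + xp[i + ki - 1, j + kj - 1, c, n] * Warr[ki, kj, c, f]
    }
    slow[i, j, f, n] <- acc
  }
  expect_equal(fast, slow, tolerance = 1e-12)
})

test_that("backpropagated gradients match numerical differentiation", {
  cfg <- model_config(conv_filters = c(2, 2, 2), fc_hidden = 3,
                      input_shape = c(8, 8, 3), dropout_rate = 0)
  m <- build_model(cfg, seed = 2)
  set.seed(4)
  xs <- array(rnorm(8 * 8 * 3 * 4), c(8, 8, 3, 4))
  ys <- c(1L, 2L, 1L, 2L)
  fwd <- tvpstage:::cnn_forward(m, xs, training = TRUE)
  bwd <- tvpstage:::cnn_backward(m, fwd$cache, ys)
  loss_at <- function(model) {
    f <- tvpstage:::cnn_forward(model, xs, training = TRUE)
    -mean(log(f$probs[cbind(1:4, ys)] + 1e-12))
  }
  for (nm in c("conv1", "conv3", "fc1", "fc2")) {
    g <- bwd$grads[[nm]]$W
    k <- which.max(abs(g))
    eps <- 1e-5
    m2 <- m
    m2$params[[nm]]$W[k] <- m2$params[[nm]]$W[k] + eps
    up <- loss_at(m2)
    m2$params[[nm]]$W[k] <- m2$params[[nm]]$W[k] - 2 * eps
    dn <- loss_at(m2)
    expect_equal(g[k], (up - dn) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("avgpool halves each spatial axis by block averaging", {
  x <- array(seq_len(4 * 4 * 1 * 1), c(4, 4, 1, 1))
  mp <- tvpstage:::conv_maps(4, 4, 1)
  y_mat <- tvpstage:::pool_fwd_m(tvpstage:::to_mat_layout(x), mp)
  y <- array(y_mat, c(2, 2, 1, 1))
  expect_equal(dim(y), c(2, 2, 1, 1))
  expect_equal(y[1, 1, 1, 1], mean(x[1:2, 1:2, 1, 1]))
  expect_equal(y[2, 2, 1, 1], mean(x[3:4, 3:4, 1, 1]))
  # backward distributes gradients evenly over each block
  d_mat <- tvpstage:::pool_bwd_m(y_mat, mp)
  expect_equal(sum(d_mat), sum(y_mat))
  expect_equal(d_mat[1, 1], y_mat[1, 1] / 4)
})
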