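# The layer primitives are validated against brute-force oracles and
# finite-difference gradients; everything downstream trusts them.

test_that("1-D convolution equals a sliding dot-product loop", {
  set.seed(1)
  for (rep in 1:3) {
    L <- sample(8:32, 1); cin <- sample(1:3, 1); cout <- sample(1:4, 1)
    k <- sample(c(3, 5), 1); B <- 2
    ly <- emofuse:::nn_conv1d(cin, cout, k)
    X <- array(rnorm(L * B * cin), c(L, B, cin))
    Y <- emofuse:::fwd_conv1d(ly, X, FALSE)
    Lo <- L - k + 1
    expect_equal(dim(Y), c(Lo, B, cout))
    for (b in 1:B) for (o in 1:cout) for (t in 1:Lo) {
      s <- ly$b[o]
      for (c in 1:cin) for (j in 1:k) {
        s <- s + X[t + j - 1, b, c] * ly$W[(j - 1) * cin + c, o]
      }
      expect_equal(Y[t, b, o], s)
    }
  }
})

test_that("max pooling (size 2, stride 2) equals a max-over-window loop", {
  set.seed(2)
  ly <- emofuse:::nn_maxpool1d(2, 2)
  X <- array(rnorm(11 * 2 * 3), c(11, 2, 3))
  Y <- emofuse:::fwd_maxpool1d(ly, X, FALSE)
  expect_equal(dim(Y), c(5, 2, 3))
  for (b in 1:2) for (c in 1:3) for (t in 1:5) {
    expect_equal(Y[t, b, c], max(X[2 * t - 1, b, c], X[2 * t, b, c]))
  }
})

test_that("the rectifier clips negatives and passes positives", {
  ly <- emofuse:::nn_relu()
  expect_equal(emofuse:::fwd_relu(ly, array(c(-3, 3), c(2, 1, 1)), FALSE),
               array(c(0, 3), c(2, 1, 1)))
})

test_that("backpropagated gradients match finite differences (1-D stack)", {
  set.seed(3)
  layers <- list(emofuse:::nn_bn(1), emofuse:::nn_conv1d(1, 4, 3),
                 emofuse:::nn_relu(), emofuse:::nn_maxpool1d(),
                 emofuse:::nn_bn(4), emofuse:::nn_conv1d(4, 3, 3),
                 emofuse:::nn_relu(), emofuse:::nn_gap1d(),
                 emofuse:::nn_dense(3, 3))
  X <- array(rnorm(20 * 4), c(20, 4, 1)); y <- c(1, 2, 3, 1)
  loss <- function() {
    emofuse:::ce_loss(emofuse:::seq_forward(layers, X, TRUE), y)$loss
  }
  l <- emofuse:::ce_loss(emofuse:::seq_forward(layers, X, TRUE), y)
  emofuse:::seq_backward(layers, l$grad)
  checks <- list(list(2, "W", "gW", 5), list(2, "b", "gb", 2),
                 list(5, "gamma", "gGamma", 3), list(5, "beta", "gBeta", 1),
                 list(6, "W", "gW", 11), list(9, "W", "gW", 4))
  for (ck in checks) {
    an <- layers[[ck[[1]]]][[ck[[3]]]][ck[[4]]]
    fd <- fd_grad(loss, layers[[ck[[1]]]], ck[[2]], ck[[4]])
    expect_rel_equal(an, fd, tol = 1e-4)
  }
})

test_that("gradients match finite differences (2-D stack with residual)", {
  set.seed(4)
  res <- emofuse:::nn_residual(
    main = list(emofuse:::nn_conv2d(3, 3, 3, stride = 1, pad = 1),
                emofuse:::nn_bn(3)),
    shortcut = list())
  layers <- list(emofuse:::nn_conv2d(1, 3, 3, stride = 1, pad = 1),
                 emofuse:::nn_relu(), emofuse:::nn_maxpool2d(2, 2),
                 res,
                 emofuse:::nn_conv2d(3, 4, 3, stride = 2, pad = 1),
                 emofuse:::nn_bn(4), emofuse:::nn_relu(),
                 emofuse:::nn_gmp2d(), emofuse:::nn_dense(4, 3))
  X <- array(rnorm(12 * 12 * 3), c(12, 12, 3, 1)); y <- c(1, 2, 3)
  loss <- function() {
    emofuse:::ce_loss(emofuse:::seq_forward(layers, X, TRUE), y)$loss
  }
  l <- emofuse:::ce_loss(emofuse:::seq_forward(layers, X, TRUE), y)
  emofuse:::seq_backward(layers, l$grad)
  expect_rel_equal(layers[[5]]$gW[7],
                   fd_grad(loss, layers[[5]], "W", 7), tol = 1e-4)
  inner <- res$main[[1]]
  expect_rel_equal(inner$gW[3], fd_grad(loss, inner, "W", 3), tol = 1e-4)
})

test_that("early stopping respects the epoch budget and patience", {
  set.seed(5)
  X <- matrix(rnorm(60 * 4), 60, 4)
  y <- rep(1:2, 30)
  X[y == 2, 1] <- X[y == 2, 1] + 3
  layers <- list(emofuse:::nn_dense(4, 2))
  h <- emofuse:::nn_train(layers, X, y,
                          train_config(learning_rate = 0.1, max_epochs = 7,
                                       early_stop_patience = Inf,
                                       batch_size = 16),
                          seed = 1)
  expect_equal(nrow(h), 7)   # patience = Inf trains exactly max_epochs
  layers2 <- list(emofuse:::nn_dense(4, 2))
  h2 <- emofuse:::nn_train(layers2, X, y,
                           train_config(learning_rate = 0, max_epochs = 9,
                                        early_stop_patience = 2,
                                        batch_size = 16),
                           seed = 1)
  expect_lte(nrow(h2), 9)
  expect_lte(nrow(h2), 3)    # frozen optimizer: stops after patience stalls
})

test_that("a zero learning rate leaves parameters untouched", {
  set.seed(6)
  layers <- list(emofuse:::nn_dense(3, 2))
  W0 <- layers[[1]]$W
  X <- matrix(rnorm(30 * 3), 30, 3)
  y <- rep(1:2, 15)
  emofuse:::nn_train(layers, X, y,
                     train_config(learning_rate = 0, max_epochs = 1,
                                  batch_size = 8), seed = 2)
  expect_identical(layers[[1]]$W, W0)
})
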