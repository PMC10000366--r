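test_that("a matrix is perfectly correlated with itself", {
  set.seed(1)
  X <- matrix(rnorm(200 * 4), 200, 4)
  cc <- cca_closed_form(X, X, k = 4, r = 1e-10)
  expect_equal(cc$cor, rep(1, 4), tolerance = 1e-6)
})

test_that("independent blocks give near-zero correlations", {
  set.seed(2)
  X <- matrix(rnorm(4000 * 3), 4000, 3)
  Y <- matrix(rnorm(4000 * 3), 4000, 3)
  cc <- cca_closed_form(X, Y, k = 3, r = 1e-8)
  expect_true(all(cc$cor < 0.1))
})

test_that("population canonical correlations are recovered from samples", {
  p <- generate_correlated_pairs(5000, 6, 5, 2, c(0.9, 0.5), seed = 3)
  cc <- cca_closed_form(p$I1, p$I2, k = 2, r = 1e-8)
  expect_lt(max(abs(cc$cor - c(0.9, 0.5))), 0.05)
  # projections reproduce the reported correlations
  Xc <- sweep(p$I1, 2, cc$center_x); Yc <- sweep(p$I2, 2, cc$center_y)
  for (i in 1:2) {
    expect_equal(abs(cor(Xc %*% cc$A[, i], Yc %*% cc$B[, i]))[1, 1],
                 cc$cor[i], tolerance = 1e-6)
  }
})

test_that("correlations are invariant to invertible affine maps", {
  set.seed(4)
  p <- generate_correlated_pairs(800, 4, 4, 2, c(0.8, 0.3), seed = 5)
  cc0 <- cca_closed_form(p$I1, p$I2, k = 2, r = 1e-12)
  A <- diag(4) + 0.2 * matrix(rnorm(16), 4)
  cc1 <- cca_closed_form(sweep(p$I1 %*% A, 2, rnorm(4), `+`), p$I2,
                         k = 2, r = 1e-12)
  expect_equal(cc0$cor, cc1$cor, tolerance = 1e-6)
  expect_true(all(cc0$cor >= 0 & cc0$cor <= 1))
})

test_that("rank deficiency without regularisation is diagnosed", {
  set.seed(5)
  X <- matrix(rnorm(50 * 2), 50, 2)
  X <- cbind(X, X[, 1])          # exactly collinear
  Y <- matrix(rnorm(50 * 2), 50, 2)
  err <- expect_error(cca_closed_form(X, Y, k = 1, r = 0),
                      class = "emofuse_rank")
  expect_match(conditionMessage(err), "r")
  expect_silent(cca_closed_form(X, Y, k = 1, r = 1e-4))
})

test_that("the batch loss agrees with the closed form and its gradient with
           finite differences", {
  set.seed(6)
  O1 <- matrix(rnorm(40), 10, 4); O2 <- matrix(rnorm(30), 10, 3)
  l <- cca_loss(O1, O2, k = 3, r = 1e-4)
  cc <- cca_closed_form(O1, O2, k = 3, r = 1e-4)
  expect_equal(l$loss, -sum(cc$cor), tolerance = 1e-8)
  # identical batches: loss is -k up to the r perturbation
  li <- cca_loss(O1, O1, k = 4, r = 1e-9)
  expect_equal(li$loss, -4, tolerance = 1e-4)
  # loss is invariant under an invertible map of one side
  M <- diag(4) + 0.1 * matrix(rnorm(16), 4)
  expect_equal(cca_loss(O1 %*% M, O2, k = 3, r = 1e-10)$loss,
               cca_loss(O1, O2, k = 3, r = 1e-10)$loss, tolerance = 1e-5)
  # finite-difference gradient agreement
  eps <- 1e-6
  for (i in c(3, 17, 31)) {
    Op <- O1; Op[i] <- Op[i] + eps
    Om <- O1; Om[i] <- Om[i] - eps
    fd <- (cca_loss(Op, O2, 3, 1e-4)$loss -
             cca_loss(Om, O2, 3, 1e-4)$loss) / (2 * eps)
    expect_rel_equal(l$grad1[i], fd, tol = 1e-4)
  }
  for (i in c(2, 22)) {
    Op <- O2; Op[i] <- Op[i] + eps
    Om <- O2; Om[i] <- Om[i] - eps
    fd <- (cca_loss(O1, Op, 3, 1e-4)$loss -
             cca_loss(O1, Om, 3, 1e-4)$loss) / (2 * eps)
    expect_rel_equal(l$grad2[i], fd, tol = 1e-4)
  }
  expect_error(cca_loss(O1[1, , drop = FALSE], O2[1, , drop = FALSE]),
               class = "emofuse_range")
})

test_that("linear transforms trained on the correlation objective match
           closed-form CCA", {
  p <- generate_correlated_pairs(600, 6, 5, 2, c(0.85, 0.4), seed = 7)
  dm <- train_dcca(p$I1, p$I2, dcca_transform_spec("linear", output_dim = 2),
                   cfg = train_config(learning_rate = 0.05, max_epochs = 200,
                                      early_stop_patience = 30),
                   seed = 2, r = 1e-5)
  O <- dcca_transform(dm, p$I1, p$I2)
  achieved <- sum(cca_loss(O$O1, O$O2, k = 2, r = 1e-5)$cor)
  oracle <- sum(cca_closed_form(p$I1, p$I2, k = 2, r = 1e-5)$cor)
  expect_lt(abs(achieved - oracle), 0.05)
})

test_that("uncorrelated data admits no spurious correlation", {
  p <- generate_correlated_pairs(2000, 4, 4, 1, 0, seed = 8)
  dm <- train_dcca(p$I1, p$I2, dcca_transform_spec("linear", output_dim = 1),
                   cfg = train_config(learning_rate = 0.05, max_epochs = 60,
                                      early_stop_patience = 15),
                   seed = 3, r = 1e-5)
  O <- dcca_transform(dm, p$I1, p$I2)
  expect_lte(sum(cca_loss(O$O1, O$O2, k = 1, r = 1e-5)$cor), 0.1)
})

test_that("DCCA fitting and transformation are deterministic and pure", {
  p <- generate_correlated_pairs(120, 4, 4, 1, 0.7, seed = 9)
  fit <- function() {
    train_dcca(p$I1, p$I2, dcca_transform_spec("linear", output_dim = 2),
               cfg = train_config(learning_rate = 0.02, max_epochs = 10),
               seed = 5, r = 1e-5)
  }
  m1 <- fit(); m2 <- fit()
  expect_identical(m1$net1[[1]]$W, m2$net1[[1]]$W)
  O1 <- dcca_transform(m1, p$I1, p$I2)
  O2 <- dcca_transform(m1, p$I1, p$I2)
  expect_identical(O1, O2)
  expect_equal(ncol(O1$O1), 2)
  expect_equal(ncol(O1$O2), 2)
  expect_error(dcca_transform(m1, p$I1[, 1:3], p$I2),
               class = "emofuse_shape")
})

test_that("the conv transform stack builds and trains on small features", {
  p <- generate_correlated_pairs(80, 32, 32, 1, 0.8, seed = 10)
  dm <- train_dcca(p$I1, p$I2,
                   dcca_transform_spec("conv", output_dim = 4),
                   cfg = train_config(learning_rate = 0.001, max_epochs = 3,
                                      early_stop_patience = 3),
                   seed = 6, r = 1e-5)
  O <- dcca_transform(dm, p$I1, p$I2)
  expect_equal(dim(O$O1), c(80, 4))
  expect_true(all(is.finite(O$O1)))
})

test_that("weighted-sum fusion follows the stated arithmetic", {
  O1 <- matrix(c(2, 4), 1); O2 <- matrix(c(0, 0), 1)
  expect_equal(fuse_features(O1, O2, 0.5, 0.5), matrix(c(1, 2), 1))
  expect_equal(fuse_features(O1, O2, 1, 0), O1)
  expect_equal(fuse_features(O1, O1, 0.5, 0.5), O1)
  # linearity in the inputs
  a <- 2.5
  expect_equal(fuse_features(a * O1, a * O2, 0.3, 0.7),
               a * fuse_features(O1, O2, 0.3, 0.7))
  expect_error(fuse_features(O1, O2, 0.6, 0.6), class = "emofuse_range")
  expect_error(fuse_features(O1, matrix(0, 1, 3)), class = "emofuse_shape")
})

test_that("the fused-feature classifier is a proper softmax and separates
           separable classes", {
  set.seed(11)
  O <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 4), 30, 2))
  labs <- rep(c("happy", "sad"), each = 30)
  clf <- classify_fused(O, labs,
                        cfg = train_config(learning_rate = 0.5,
                                           max_epochs = 40,
                                           early_stop_patience = 40),
                        seed = 1)
  P <- predict(clf, O)
  expect_equal(rowSums(P), rep(1, 60), tolerance = 1e-9)
  expect_gt(mean(c("happy", "neutral", "sad")[max.col(P)] == labs), 0.97)
  expect_error(classify_fused(O, rep("happy", 60)),
               class = "emofuse_degenerate")
})
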