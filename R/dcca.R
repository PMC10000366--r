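# Deep canonical correlation analysis fusion.
#
# Two transform networks (linear, or the three-stage 1-D convolution stack)
# are trained by gradient ascent on the total canonical correlation between
# their outputs; the closed-form linear CCA below doubles as the module's
# independent oracle.  Transformed features are fused by a convex weighted
# sum and classified with a softmax layer.

# Symmetric inverse square root with an eigenvalue floor check.
inv_sqrt_sym <- function(S, r) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < 1e-12) {
    stop_emofuse(
      "covariance is rank deficient; use a positive regularizer r",
      "emofuse_rank")
  }
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Closed-form (linear) canonical correlation analysis
#'
#' Column-centres both matrices, adds `r` to the auto-covariance diagonals,
#' and returns the top-`k` singular values of the whitened cross-covariance
#' `S11^{-1/2} S12 S22^{-1/2}` -- the canonical correlations, sorted
#' descending in `[0, 1]` -- together with the projection bases that attain
#' them.
#'
#' @param X,Y Paired feature matrices sharing rows.
#' @param k Number of canonical pairs, `k <= min(ncol(X), ncol(Y))`.
#' @param r Non-negative regularizer added to the auto-covariance diagonal;
#'   required strictly positive when either block is rank deficient.
#' @return List with `cor` (length-`k` correlations), `A`, `B` (projection
#'   matrices), and the column means used for centring.
#' @export
cca_closed_form <- function(X, Y, k = min(ncol(X), ncol(Y)), r = 1e-8) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  M <- nrow(X)
  assert_that(nrow(Y) == M, "X and Y must share rows", "emofuse_shape")
  assert_that(M >= 2, "need at least 2 rows", "emofuse_range")
  assert_that(k >= 1 && k <= min(ncol(X), ncol(Y)),
              "k must not exceed the smaller feature dimension",
              "emofuse_range")
  assert_that(r >= 0, "r must be non-negative")
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  S11 <- crossprod(Xc) / (M - 1) + r * diag(ncol(X))
  S22 <- crossprod(Yc) / (M - 1) + r * diag(ncol(Y))
  S12 <- crossprod(Xc, Yc) / (M - 1)
  W1 <- inv_sqrt_sym(S11, r)
  W2 <- inv_sqrt_sym(S22, r)
  sv <- svd(W1 %*% S12 %*% W2)
  list(cor = pmin(sv$d[seq_len(k)], 1),
       A = W1 %*% sv$u[, seq_len(k), drop = FALSE],
       B = W2 %*% sv$v[, seq_len(k), drop = FALSE],
       center_x = mx, center_y = my)
}

#' Canonical-correlation loss and its gradient
#'
#' The loss is the negative total correlation (sum of the top-`k` singular
#' values of the whitened cross-covariance of the batch), the quantity the
#' DCCA transforms minimise; the analytic gradient with respect to both
#' batches follows the classic DCCA derivation and is validated against
#' finite differences in the test-suite.
#'
#' @param O1,O2 Transformed feature batches (rows paired).
#' @param k Number of directions (default: all).
#' @param r Auto-covariance regularizer.
#' @return List with `loss` (scalar), `grad1`, `grad2` (matrices matching
#'   `O1`, `O2`).
#' @export
cca_loss <- function(O1, O2, k = min(ncol(O1), ncol(O2)), r = 1e-5) {
  O1 <- as.matrix(O1); O2 <- as.matrix(O2)
  m <- nrow(O1)
  assert_that(m >= 2, "batch must contain at least 2 rows", "emofuse_range")
  assert_that(nrow(O2) == m, "O1 and O2 must share rows", "emofuse_shape")
  Xc <- sweep(O1, 2, colMeans(O1))
  Yc <- sweep(O2, 2, colMeans(O2))
  S11 <- crossprod(Xc) / (m - 1) + r * diag(ncol(O1))
  S22 <- crossprod(Yc) / (m - 1) + r * diag(ncol(O2))
  S12 <- crossprod(Xc, Yc) / (m - 1)
  W1 <- inv_sqrt_sym(S11, r)
  W2 <- inv_sqrt_sym(S22, r)
  Tm <- W1 %*% S12 %*% W2
  sv <- svd(Tm)
  kk <- seq_len(k)
  U <- sv$u[, kk, drop = FALSE]
  V <- sv$v[, kk, drop = FALSE]
  D <- sv$d[kk]
  corr <- sum(D)
  # gradients of +corr (Andrew et al. form), then negated for the loss
  G12 <- W1 %*% U %*% t(V) %*% W2
  G11 <- -0.5 * W1 %*% U %*% (D * t(U)) %*% W1
  G22 <- -0.5 * W2 %*% V %*% (D * t(V)) %*% W2
  d1 <- (2 * Xc %*% G11 + Yc %*% t(G12)) / (m - 1)
  d2 <- (2 * Yc %*% G22 + Xc %*% G12) / (m - 1)
  list(loss = -corr, grad1 = -d1, grad2 = -d2, cor = D)
}

#' DCCA transform architecture
#'
#' @param arch `"linear"` (a single projection, the closed-form-comparable
#'   setting) or `"conv"` (the three-stage 1-D convolution stack: 128, 256,
#'   512 kernels of sizes 3, 5, 3, each followed by 2x max pooling, then
#'   dropout and a linear projection to `output_dim`).
#' @param output_dim Dimension `n` of the transformed space.
#' @param conv_filters,kernel_sizes,dropout Conv-stack settings.
#' @return A `dcca_transform_spec` list.
#' @export
dcca_transform_spec <- function(arch = c("conv", "linear"), output_dim = 32,
                                conv_filters = c(128, 256, 512),
                                kernel_sizes = c(3, 5, 3), dropout = 0.4) {
  arch <- match.arg(arch)
  assert_that(output_dim >= 1, "output_dim must be >= 1")
  assert_that(length(conv_filters) == 3 && length(kernel_sizes) == 3,
              "three transform stages expected")
  structure(list(arch = arch, output_dim = as.integer(output_dim),
                 conv_filters = as.integer(conv_filters),
                 kernel_sizes = as.integer(kernel_sizes), dropout = dropout),
            class = "dcca_transform_spec")
}

# Length remaining after a valid conv of kernel k and a 2x pool.
conv_pool_len <- function(len, k) (len - k + 1L) %/% 2L

build_dcca_transform <- function(spec, input_dim) {
  if (spec$arch == "linear") {
    return(list(nn_dense(input_dim, spec$output_dim)))
  }
  f <- spec$conv_filters; ks <- spec$kernel_sizes
  l1 <- conv_pool_len(input_dim, ks[1])
  l2 <- conv_pool_len(l1, ks[2])
  l3 <- conv_pool_len(l2, ks[3])
  assert_that(l3 >= 1, "input_dim too small for the conv transform",
              "emofuse_shape")
  list(
    nn_conv1d(1, f[1], ks[1]), nn_relu(), nn_maxpool1d(2, 2),
    nn_conv1d(f[1], f[2], ks[2]), nn_relu(), nn_maxpool1d(2, 2),
    nn_conv1d(f[2], f[3], ks[3]), nn_relu(), nn_maxpool1d(2, 2),
    nn_dropout(spec$dropout),
    nn_flatten(),
    nn_dense(l3 * f[3], spec$output_dim)
  )
}

dcca_input <- function(arch, M) {
  if (arch == "linear") as.matrix(M)
  else array(t(as.matrix(M)), dim = c(ncol(M), nrow(M), 1L))
}

#' Train a DCCA fusion model
#'
#' Fits the two transform networks by full-batch gradient descent on
#' [cca_loss()] (i.e. gradient ascent on the total canonical correlation),
#' with Xavier initialisation, zero biases, and early stopping after
#' `cfg$early_stop_patience` non-improving validation evaluations.
#'
#' @param I1,I2 Feature matrices of the two modalities, rows paired.
#' @param spec A [dcca_transform_spec()] shared by both transforms.
#' @param cfg A [train_config()] (`batch_size` is ignored: the correlation
#'   objective is evaluated on the full training split each step, which
#'   stabilises the singular-value objective at desk scale).
#' @param seed Integer seed.
#' @param r Auto-covariance regularizer of the CCA objective.
#' @param alpha,beta Fusion weights, `alpha + beta = 1`.
#' @return A `dcca_model` with the fitted transforms, `$history`, and the
#'   fusion weights.
#' @export
train_dcca <- function(I1, I2, spec = dcca_transform_spec(),
                       cfg = train_config(), seed = 1L, r = 1e-5,
                       alpha = 0.5, beta = 0.5) {
  I1 <- as.matrix(I1); I2 <- as.matrix(I2)
  M <- nrow(I1)
  assert_that(nrow(I2) == M, "I1 and I2 must share rows", "emofuse_shape")
  assert_that(abs(alpha + beta - 1) < 1e-9 && alpha >= 0 && beta >= 0,
              "fusion weights must be non-negative and sum to 1",
              "emofuse_range")
  set.seed(child_seed(seed, 211L))
  net1 <- build_dcca_transform(spec, ncol(I1))
  net2 <- build_dcca_transform(spec, ncol(I2))
  n_val <- max(2L, floor(M * cfg$val_fraction))
  val <- sample.int(M, n_val)
  tr <- setdiff(seq_len(M), val)
  X1 <- dcca_input(spec$arch, I1[tr, , drop = FALSE])
  X2 <- dcca_input(spec$arch, I2[tr, , drop = FALSE])
  X1v <- dcca_input(spec$arch, I1[val, , drop = FALSE])
  X2v <- dcca_input(spec$arch, I2[val, , drop = FALSE])
  k <- spec$output_dim
  best <- Inf; snap1 <- snapshot_params(net1); snap2 <- snapshot_params(net2)
  stall <- 0L; hist <- list()
  for (step in seq_len(cfg$max_epochs)) {
    O1 <- seq_forward(net1, X1, training = TRUE)
    O2 <- seq_forward(net2, X2, training = TRUE)
    l <- cca_loss(O1, O2, k = k, r = r)
    if (!is.finite(l$loss)) {
      restore_params(net1, snap1); restore_params(net2, snap2)
      stop_emofuse(paste0("DCCA training diverged (non-finite loss) at step ",
                          step, "; transforms reverted to the last finite ",
                          "state -- lower the learning rate"),
                   "emofuse_diverged")
    }
    seq_backward(net1, l$grad1)
    seq_backward(net2, l$grad2)
    sgd_step_layers(net1, cfg$learning_rate)
    sgd_step_layers(net2, cfg$learning_rate)
    O1v <- seq_forward(net1, X1v, training = FALSE)
    O2v <- seq_forward(net2, X2v, training = FALSE)
    lv <- tryCatch(cca_loss(O1v, O2v, k = k, r = r)$loss,
                   error = function(e) Inf)
    hist[[step]] <- c(epoch = step, train_loss = l$loss, val_loss = lv)
    if (lv < best - 1e-9) {
      best <- lv
      snap1 <- snapshot_params(net1); snap2 <- snapshot_params(net2)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$early_stop_patience) break
    }
  }
  restore_params(net1, snap1); restore_params(net2, snap2)
  clear_caches(net1); clear_caches(net2)
  history <- tibble::as_tibble(do.call(rbind, hist))
  class(history) <- c("train_history", class(history))
  structure(list(net1 = net1, net2 = net2, spec = spec,
                 input_dims = c(ncol(I1), ncol(I2)),
                 output_dim = spec$output_dim, r = r,
                 alpha = alpha, beta = beta, history = history),
            class = "dcca_model")
}

#' Transform both modalities into the joint space
#'
#' @param model A fitted [train_dcca()] model.
#' @param I1,I2 Feature matrices with the training-time dimensions.
#' @return List with `O1`, `O2` (`M x output_dim` each); deterministic
#'   (dropout off).
#' @export
dcca_transform <- function(model, I1, I2) {
  assert_that(inherits(model, "dcca_model"), "model must be a dcca_model")
  I1 <- as.matrix(I1); I2 <- as.matrix(I2)
  assert_that(ncol(I1) == model$input_dims[1] &&
                ncol(I2) == model$input_dims[2],
              "feature dimensions do not match the fitted model",
              "emofuse_shape")
  list(O1 = seq_forward(model$net1, dcca_input(model$spec$arch, I1),
                        training = FALSE),
       O2 = seq_forward(model$net2, dcca_input(model$spec$arch, I2),
                        training = FALSE))
}

#' Weighted-sum fusion of transformed features
#'
#' @param O1,O2 Equal-shape transformed feature matrices.
#' @param alpha,beta Non-negative weights with `alpha + beta = 1`.
#' @return The element-wise weighted sum `alpha * O1 + beta * O2`.
#' @export
fuse_features <- function(O1, O2, alpha = 0.5, beta = 0.5) {
  assert_that(abs(alpha + beta - 1) < 1e-9 && alpha >= 0 && beta >= 0,
              "fusion weights must be non-negative and sum to 1",
              "emofuse_range")
  assert_that(identical(dim(as.matrix(O1)), dim(as.matrix(O2))),
              "O1 and O2 must have equal shape", "emofuse_shape")
  alpha * O1 + beta * O2
}

#' Softmax classifier on fused features
#'
#' A single linear layer trained by SGD on cross-entropy.  Because the
#' canonical-correlation objective is scale-invariant, transformed features
#' carry an arbitrary scale; the classifier therefore z-normalises each
#' column with training statistics (stored and reapplied at prediction).
#'
#' @param O Fused feature matrix (rows are windows/trials).
#' @param labels Emotion label per row.
#' @param cfg A [train_config()].
#' @param seed Integer seed.
#' @param standardize Z-normalise columns with training statistics.
#' @return A `softmax_classifier` with `$history`; use [predict()] for
#'   per-class probabilities.
#' @export
classify_fused <- function(O, labels, cfg = train_config(), seed = 1L,
                           standardize = TRUE) {
  O <- as.matrix(O)
  y <- label_codes(labels)
  if (standardize) {
    mu <- colMeans(O)
    sg <- apply(O, 2, sd)
    sg[sg == 0] <- 1
    O <- sweep(sweep(O, 2, mu), 2, sg, `/`)
  } else {
    mu <- rep(0, ncol(O)); sg <- rep(1, ncol(O))
  }
  set.seed(child_seed(seed, 307L))
  layers <- list(nn_dense(ncol(O), length(emotion_levels())))
  history <- nn_train(layers, O, y, cfg, seed)
  structure(list(layers = layers, history = history, input_dim = ncol(O),
                 center = mu, scale = sg),
            class = "softmax_classifier")
}

#' @export
predict.softmax_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  assert_that(ncol(newdata) == object$input_dim,
              "feature dimension mismatch", "emofuse_shape")
  newdata <- sweep(sweep(newdata, 2, object$center), 2, object$scale, `/`)
  P <- nn_predict_probs(object$layers, newdata)
  colnames(P) <- emotion_levels()
  P
}
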