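# Minimal neural-network engine.
#
# No deep-learning framework ships with this stack, and the convolutional
# feature extractors and DCCA transforms are the heart of the method, so the
# layers and their gradients are authored here directly.  Convolutions are
# evaluated as shift-and-add matrix products through BLAS: with the batch
# dimension kept in the middle of the activation arrays, folding an
# activation to a (positions x channels) matrix is a zero-copy `dim` change,
# which keeps desk-scale training tractable in plain R.
#
# Activation layouts (batch in the middle, channels last):
#   1-D streams : array (L, B, C)   -- length x batch x channels
#   2-D images  : array (H, W, B, C)
#   vectors     : matrix (B, F)
#
# Layers are environments (mutable caches/grads); a network is a list of
# layers evaluated in order by seq_forward()/seq_backward().

new_layer <- function(type, ...) {
  e <- list2env(list(type = type, ...), parent = emptyenv())
  class(e) <- "emofuse_layer"
  e
}

# Xavier/Glorot uniform initialisation; biases start at zero.
xavier <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  runif(n, -lim, lim)
}

# Convolution weights are stored as a (k*cin) x cout matrix whose rows are
# offset-major: rows (j-1)*cin + (1:cin) hold the kernel tap at offset j.
nn_conv1d <- function(cin, cout, k) {
  new_layer("conv1d",
    cin = cin, cout = cout, k = k,
    W = matrix(xavier(k * cin, k * cout, k * cin * cout), k * cin, cout),
    b = numeric(cout)
  )
}

nn_conv2d <- function(cin, cout, kh, kw = kh, stride = 1L, pad = 0L) {
  new_layer("conv2d",
    cin = cin, cout = cout, kh = kh, kw = kw,
    stride = as.integer(stride), pad = as.integer(pad),
    W = matrix(xavier(kh * kw * cin, kh * kw * cout, kh * kw * cin * cout),
               kh * kw * cin, cout),
    b = numeric(cout)
  )
}

nn_bn <- function(channels, eps = 1e-5, momentum = 0.1) {
  new_layer("bn",
    channels = channels, eps = eps, momentum = momentum,
    gamma = rep(1, channels), beta = numeric(channels),
    run_mean = numeric(channels), run_var = rep(1, channels)
  )
}

nn_relu    <- function() new_layer("relu")
nn_dropout <- function(p) new_layer("dropout", p = p)
nn_maxpool1d <- function(size = 2L, stride = 2L) {
  new_layer("maxpool1d", size = as.integer(size), stride = as.integer(stride))
}
nn_maxpool2d <- function(size = 2L, stride = 2L, pad = 0L) {
  new_layer("maxpool2d", size = as.integer(size), stride = as.integer(stride),
            pad = as.integer(pad))
}
nn_gap1d <- function() new_layer("gap1d")
nn_gap2d <- function() new_layer("gap2d")
nn_gmp2d <- function() new_layer("gmp2d")
nn_flatten <- function() new_layer("flatten")
nn_dense <- function(nin, nout) {
  new_layer("dense", nin = nin, nout = nout,
            W = matrix(xavier(nin, nout, nin * nout), nin, nout),
            b = matrix(0, 1, nout))
}
nn_residual <- function(main, shortcut = list()) {
  new_layer("residual", main = main, shortcut = shortcut)
}

# ---- 1-D convolution: shift-and-add ----------------------------------------

fwd_conv1d <- function(ly, X, training) {
  d <- dim(X); L <- d[1]; B <- d[2]; C <- d[3]
  k <- ly$k; Lo <- L - k + 1L
  if (Lo < 1L) stop_emofuse("input too short for convolution kernel",
                            "emofuse_shape")
  shifts <- vector("list", k)
  Y <- matrix(rep(ly$b, each = Lo * B), Lo * B, ly$cout)
  for (j in seq_len(k)) {
    Xj <- X[j:(j + Lo - 1L), , , drop = FALSE]
    dim(Xj) <- c(Lo * B, C)
    shifts[[j]] <- Xj
    Y <- Y + Xj %*% ly$W[((j - 1L) * C + 1L):(j * C), , drop = FALSE]
  }
  ly$cache <- list(shifts = shifts, L = L, B = B, C = C, Lo = Lo)
  dim(Y) <- c(Lo, B, ly$cout)
  Y
}

bwd_conv1d <- function(ly, dY) {
  cc <- ly$cache; k <- ly$k; C <- cc$C
  dYm <- dY
  dim(dYm) <- c(cc$Lo * cc$B, ly$cout)
  gW <- matrix(0, k * C, ly$cout)
  dX <- array(0, c(cc$L, cc$B, C))
  for (j in seq_len(k)) {
    rows <- ((j - 1L) * C + 1L):(j * C)
    gW[rows, ] <- crossprod(cc$shifts[[j]], dYm)
    dPj <- dYm %*% t(ly$W[rows, , drop = FALSE])
    dim(dPj) <- c(cc$Lo, cc$B, C)
    idx <- j:(j + cc$Lo - 1L)
    dX[idx, , ] <- dX[idx, , , drop = FALSE] + dPj
  }
  ly$gW <- gW
  ly$gb <- colSums(dYm)
  dX
}

# ---- 2-D convolution: shift-and-add over kernel offsets --------------------

pad2d <- function(X, p, value = 0) {
  if (p == 0L) return(X)
  d <- dim(X)
  Xp <- array(value, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  Xp[(p + 1):(p + d[1]), (p + 1):(p + d[2]), , ] <- X
  Xp
}

fwd_conv2d <- function(ly, X, training) {
  Xp <- pad2d(X, ly$pad)
  d <- dim(Xp); H <- d[1]; W <- d[2]; B <- d[3]; C <- d[4]
  kh <- ly$kh; kw <- ly$kw; s <- ly$stride
  Ho <- (H - kh) %/% s + 1L; Wo <- (W - kw) %/% s + 1L
  if (Ho < 1L || Wo < 1L) stop_emofuse("input too small for convolution",
                                       "emofuse_shape")
  hs <- (0:(Ho - 1L)) * s; ws <- (0:(Wo - 1L)) * s
  n_off <- kh * kw
  shifts <- vector("list", n_off)
  Y <- matrix(rep(ly$b, each = Ho * Wo * B), Ho * Wo * B, ly$cout)
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    off <- (i - 1L) * kw + j
    Xij <- Xp[hs + i, ws + j, , , drop = FALSE]
    dim(Xij) <- c(Ho * Wo * B, C)
    shifts[[off]] <- Xij
    rows <- ((off - 1L) * C + 1L):(off * C)
    Y <- Y + Xij %*% ly$W[rows, , drop = FALSE]
  }
  ly$cache <- list(shifts = shifts, H = H, W = W, B = B, C = C,
                   Ho = Ho, Wo = Wo, hs = hs, ws = ws,
                   in_dim = dim(X))
  dim(Y) <- c(Ho, Wo, B, ly$cout)
  Y
}

bwd_conv2d <- function(ly, dY) {
  cc <- ly$cache; kh <- ly$kh; kw <- ly$kw; p <- ly$pad; C <- cc$C
  dYm <- dY
  dim(dYm) <- c(cc$Ho * cc$Wo * cc$B, ly$cout)
  gW <- matrix(0, kh * kw * C, ly$cout)
  dXp <- array(0, c(cc$H, cc$W, cc$B, C))
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    off <- (i - 1L) * kw + j
    rows <- ((off - 1L) * C + 1L):(off * C)
    gW[rows, ] <- crossprod(cc$shifts[[off]], dYm)
    dPij <- dYm %*% t(ly$W[rows, , drop = FALSE])
    dim(dPij) <- c(cc$Ho, cc$Wo, cc$B, C)
    dXp[cc$hs + i, cc$ws + j, , ] <-
      dXp[cc$hs + i, cc$ws + j, , , drop = FALSE] + dPij
  }
  ly$gW <- gW
  ly$gb <- colSums(dYm)
  if (p > 0L) {
    d0 <- cc$in_dim
    dXp <- dXp[(p + 1):(p + d0[1]), (p + 1):(p + d0[2]), , , drop = FALSE]
  }
  dXp
}

# ---- batch norm (channel-last layouts fold for free) -----------------------

fwd_bn <- function(ly, X, training) {
  d <- dim(X)
  C <- d[length(d)]
  M <- X
  dim(M) <- c(prod(d[-length(d)]), C)
  if (training) {
    mu <- colMeans(M)
    v <- colMeans(M^2) - mu^2
    ly$run_mean <- (1 - ly$momentum) * ly$run_mean + ly$momentum * mu
    ly$run_var  <- (1 - ly$momentum) * ly$run_var  + ly$momentum * v
  } else {
    mu <- ly$run_mean
    v <- ly$run_var
  }
  invstd <- 1 / sqrt(v + ly$eps)
  n <- nrow(M)
  xhat <- M * rep(invstd, each = n) - rep(mu * invstd, each = n)
  Y <- xhat * rep(ly$gamma, each = n) + rep(ly$beta, each = n)
  ly$cache <- list(xhat = xhat, invstd = invstd, d = d,
                   training = training)
  dim(Y) <- d
  Y
}

bwd_bn <- function(ly, dY) {
  cc <- ly$cache
  d <- cc$d
  dM <- dY
  dim(dM) <- c(prod(d[-length(d)]), d[length(d)])
  xhat <- cc$xhat
  ly$gGamma <- colSums(dM * xhat)
  ly$gBeta <- colSums(dM)
  n <- nrow(dM)
  dxhat <- dM * rep(ly$gamma, each = n)
  if (cc$training) {
    t1 <- dxhat - rep(colMeans(dxhat), each = n)
    t2 <- xhat * rep(colMeans(dxhat * xhat), each = n)
    dX <- (t1 - t2) * rep(cc$invstd, each = n)
  } else {
    dX <- dxhat * rep(cc$invstd, each = n)
  }
  dim(dX) <- d
  dX
}

fwd_relu <- function(ly, X, training) {
  ly$cache <- X > 0
  X * ly$cache
}
bwd_relu <- function(ly, dY) dY * ly$cache

fwd_dropout <- function(ly, X, training) {
  if (!training || ly$p <= 0) { ly$cache <- NULL; return(X) }
  mask <- array((runif(length(X)) >= ly$p) / (1 - ly$p), dim(X))
  ly$cache <- mask
  X * mask
}
bwd_dropout <- function(ly, dY) {
  if (is.null(ly$cache)) dY else dY * ly$cache
}

fwd_maxpool1d <- function(ly, X, training) {
  d <- dim(X); L <- d[1]
  s <- ly$size; st <- ly$stride
  Lo <- (L - s) %/% st + 1L
  pos <- (0:(Lo - 1L)) * st
  Y <- X[pos + 1L, , , drop = FALSE]
  win <- array(1L, dim(Y))
  if (s > 1L) for (j in 2:s) {
    cand <- X[pos + j, , , drop = FALSE]
    upd <- cand > Y
    Y[upd] <- cand[upd]
    win[upd] <- j
  }
  ly$cache <- list(win = win, d = d, pos = pos)
  Y
}

bwd_maxpool1d <- function(ly, dY) {
  cc <- ly$cache
  dX <- array(0, cc$d)
  for (j in seq_len(ly$size)) {
    sel <- (cc$win == j) * dY
    idx <- cc$pos + j
    dX[idx, , ] <- dX[idx, , , drop = FALSE] + sel
  }
  dX
}

fwd_maxpool2d <- function(ly, X, training) {
  Xp <- pad2d(X, ly$pad, value = -Inf)
  d <- dim(Xp)
  s <- ly$size; st <- ly$stride
  Ho <- (d[1] - s) %/% st + 1L; Wo <- (d[2] - s) %/% st + 1L
  hs <- (0:(Ho - 1L)) * st; ws <- (0:(Wo - 1L)) * st
  Y <- NULL; win <- NULL
  for (i in seq_len(s)) for (j in seq_len(s)) {
    cand <- Xp[hs + i, ws + j, , , drop = FALSE]
    off <- (i - 1L) * s + j
    if (is.null(Y)) {
      Y <- cand; win <- array(off, dim(cand))
    } else {
      upd <- cand > Y
      Y[upd] <- cand[upd]
      win[upd] <- off
    }
  }
  ly$cache <- list(win = win, d = d, hs = hs, ws = ws, dx_dim = dim(X))
  Y
}

bwd_maxpool2d <- function(ly, dY) {
  cc <- ly$cache; s <- ly$size; p <- ly$pad
  dXp <- array(0, cc$d)
  for (i in seq_len(s)) for (j in seq_len(s)) {
    off <- (i - 1L) * s + j
    sel <- (cc$win == off) * dY
    dXp[cc$hs + i, cc$ws + j, , ] <-
      dXp[cc$hs + i, cc$ws + j, , , drop = FALSE] + sel
  }
  if (p > 0L) {
    d0 <- cc$dx_dim
    dXp <- dXp[(p + 1):(p + d0[1]), (p + 1):(p + d0[2]), , , drop = FALSE]
  }
  dXp
}

# global average pool over time: (L, B, C) -> (B, C)
fwd_gap1d <- function(ly, X, training) {
  d <- dim(X)
  ly$cache <- d
  colMeans(X)
}
bwd_gap1d <- function(ly, dY) {
  d <- ly$cache
  array(rep(dY / d[1], each = d[1]), d)
}

fwd_gap2d <- function(ly, X, training) {
  d <- dim(X)
  ly$cache <- d
  M <- X
  dim(M) <- c(d[1] * d[2], d[3] * d[4])
  matrix(colMeans(M), d[3], d[4])
}
bwd_gap2d <- function(ly, dY) {
  d <- ly$cache
  array(rep(as.vector(dY) / (d[1] * d[2]), each = d[1] * d[2]), d)
}

fwd_gmp2d <- function(ly, X, training) {
  d <- dim(X)
  M <- X
  dim(M) <- c(d[1] * d[2], d[3] * d[4])
  wmax <- max.col(t(M), ties.method = "first")
  Y <- M[cbind(wmax, seq_along(wmax))]
  ly$cache <- list(d = d, wmax = wmax)
  matrix(Y, d[3], d[4])
}
bwd_gmp2d <- function(ly, dY) {
  cc <- ly$cache; d <- cc$d
  dM <- matrix(0, d[1] * d[2], d[3] * d[4])
  dM[cbind(cc$wmax, seq_along(cc$wmax))] <- as.vector(dY)
  array(dM, d)
}

# (L, B, C) -> (B, L*C): per-sample features ordered position-fastest.
fwd_flatten <- function(ly, X, training) {
  d <- dim(X)
  ly$cache <- d
  M <- aperm(X, c(1, 3, 2))
  dim(M) <- c(d[1] * d[3], d[2])
  t(M)
}
bwd_flatten <- function(ly, dY) {
  d <- ly$cache
  M <- t(dY)
  dim(M) <- c(d[1], d[3], d[2])
  aperm(M, c(1, 3, 2))
}

fwd_dense <- function(ly, X, training) {
  ly$cache <- X
  sweep(X %*% ly$W, 2, as.vector(ly$b), `+`)
}
bwd_dense <- function(ly, dY) {
  ly$gW <- crossprod(ly$cache, dY)
  ly$gb <- matrix(colSums(dY), 1)
  dY %*% t(ly$W)
}

fwd_residual <- function(ly, X, training) {
  Ym <- seq_forward(ly$main, X, training)
  Ys <- if (length(ly$shortcut)) seq_forward(ly$shortcut, X, training) else X
  S <- Ym + Ys
  ly$cache <- S > 0
  S * ly$cache
}
bwd_residual <- function(ly, dY) {
  dS <- dY * ly$cache
  dXm <- seq_backward(ly$main, dS)
  dXs <- if (length(ly$shortcut)) seq_backward(ly$shortcut, dS) else dS
  dXm + dXs
}

# ---- dispatch --------------------------------------------------------------

layer_forward <- function(ly, X, training) {
  switch(ly$type,
    conv1d    = fwd_conv1d(ly, X, training),
    conv2d    = fwd_conv2d(ly, X, training),
    bn        = fwd_bn(ly, X, training),
    relu      = fwd_relu(ly, X, training),
    dropout   = fwd_dropout(ly, X, training),
    maxpool1d = fwd_maxpool1d(ly, X, training),
    maxpool2d = fwd_maxpool2d(ly, X, training),
    gap1d     = fwd_gap1d(ly, X, training),
    gap2d     = fwd_gap2d(ly, X, training),
    gmp2d     = fwd_gmp2d(ly, X, training),
    flatten   = fwd_flatten(ly, X, training),
    dense     = fwd_dense(ly, X, training),
    residual  = fwd_residual(ly, X, training),
    stop_emofuse(paste("unknown layer type", ly$type), "emofuse_internal")
  )
}

layer_backward <- function(ly, dY) {
  switch(ly$type,
    conv1d    = bwd_conv1d(ly, dY),
    conv2d    = bwd_conv2d(ly, dY),
    bn        = bwd_bn(ly, dY),
    relu      = bwd_relu(ly, dY),
    dropout   = bwd_dropout(ly, dY),
    maxpool1d = bwd_maxpool1d(ly, dY),
    maxpool2d = bwd_maxpool2d(ly, dY),
    gap1d     = bwd_gap1d(ly, dY),
    gap2d     = bwd_gap2d(ly, dY),
    gmp2d     = bwd_gmp2d(ly, dY),
    flatten   = bwd_flatten(ly, dY),
    dense     = bwd_dense(ly, dY),
    residual  = bwd_residual(ly, dY),
    stop_emofuse(paste("unknown layer type", ly$type), "emofuse_internal")
  )
}

seq_forward <- function(layers, X, training = FALSE) {
  for (ly in layers) X <- layer_forward(ly, X, training)
  X
}

seq_backward <- function(layers, dY) {
  for (ly in rev(layers)) dY <- layer_backward(ly, dY)
  dY
}

# ---- parameter access ------------------------------------------------------

walk_layers <- function(layers, fn) {
  for (ly in layers) {
    fn(ly)
    if (ly$type == "residual") {
      walk_layers(ly$main, fn)
      walk_layers(ly$shortcut, fn)
    }
  }
  invisible(NULL)
}

layer_param_names <- function(ly) {
  switch(ly$type,
    conv1d = , conv2d = , dense = c("W", "b"),
    bn = c("gamma", "beta"),
    character(0)
  )
}

layer_grad_names <- function(ly) {
  switch(ly$type,
    conv1d = , conv2d = , dense = c("gW", "gb"),
    bn = c("gGamma", "gBeta"),
    character(0)
  )
}

n_params_layers <- function(layers) {
  total <- 0
  walk_layers(layers, function(ly) {
    for (p in layer_param_names(ly)) total <<- total + length(ly[[p]])
  })
  total
}

sgd_step_layers <- function(layers, lr, momentum = 0) {
  walk_layers(layers, function(ly) {
    ps <- layer_param_names(ly)
    gs <- layer_grad_names(ly)
    for (i in seq_along(ps)) {
      g <- ly[[gs[i]]]
      if (is.null(g)) next
      if (momentum > 0) {
        vn <- paste0("v_", ps[i])
        v <- ly[[vn]]
        v <- if (is.null(v)) g else momentum * v + g
        ly[[vn]] <- v
        ly[[ps[i]]] <- ly[[ps[i]]] - lr * v
      } else {
        ly[[ps[i]]] <- ly[[ps[i]]] - lr * g
      }
    }
  })
  invisible(NULL)
}

snapshot_params <- function(layers) {
  snap <- list()
  i <- 0
  walk_layers(layers, function(ly) {
    i <<- i + 1
    keep <- c(layer_param_names(ly),
              if (ly$type == "bn") c("run_mean", "run_var"))
    snap[[i]] <<- mget(keep, envir = ly)
  })
  snap
}

restore_params <- function(layers, snap) {
  i <- 0
  walk_layers(layers, function(ly) {
    i <<- i + 1
    for (nm in names(snap[[i]])) ly[[nm]] <- snap[[i]][[nm]]
  })
  invisible(NULL)
}

clear_caches <- function(layers) {
  walk_layers(layers, function(ly) {
    ly$cache <- NULL
    for (g in layer_grad_names(ly)) if (!is.null(ly[[g]])) ly[[g]] <- NULL
  })
  invisible(NULL)
}

# ---- classification loss ---------------------------------------------------

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Mean cross-entropy and its gradient w.r.t. the logits.
ce_loss <- function(logits, y) {
  P <- softmax_rows(logits)
  B <- nrow(P)
  idx <- cbind(seq_len(B), y)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  G <- P
  G[idx] <- G[idx] - 1
  list(loss = loss, grad = G / B, probs = P)
}

batch_slice <- function(X, idx) {
  d <- dim(X)
  switch(as.character(length(d)),
    "2" = X[idx, , drop = FALSE],
    "3" = X[, idx, , drop = FALSE],
    "4" = X[, , idx, , drop = FALSE],
    stop_emofuse("unsupported input rank", "emofuse_internal")
  )
}

batch_count <- function(X) {
  d <- dim(X)
  switch(as.character(length(d)),
    "2" = d[1], "3" = d[2], "4" = d[3],
    stop_emofuse("unsupported input rank", "emofuse_internal")
  )
}

#' Training configuration
#'
#' Optimisation settings shared by all the trainable networks: plain
#' stochastic gradient descent on cross-entropy (or the canonical-correlation
#' objective), Xavier weight initialisation with zero biases, and early
#' stopping on the validation loss.
#'
#' @param learning_rate SGD step size.
#' @param max_epochs Upper bound on training epochs.
#' @param batch_size Mini-batch size.
#' @param early_stop_patience Number of consecutive validation evaluations
#'   without improvement tolerated before stopping (one evaluation per epoch).
#'   Use `Inf` to disable early stopping.
#' @param val_fraction Fraction of the training rows held out for validation
#'   when the caller does not pass an explicit validation set.
#' @param momentum Classical momentum coefficient; 0 (the default) is plain
#'   SGD.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, max_epochs = 40,
                         batch_size = 32, early_stop_patience = 15,
                         val_fraction = 0.10, momentum = 0) {
  assert_that(learning_rate >= 0, "learning_rate must be >= 0")
  assert_that(max_epochs >= 1, "max_epochs must be >= 1")
  assert_that(early_stop_patience >= 1, "early_stop_patience must be >= 1")
  assert_that(val_fraction > 0 && val_fraction < 1,
              "val_fraction must be in (0,1)")
  assert_that(momentum >= 0 && momentum < 1, "momentum must be in [0, 1)")
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 early_stop_patience = early_stop_patience,
                 val_fraction = val_fraction, momentum = momentum),
            class = "train_config")
}

# Stratified split of integer class labels into train/validation index sets.
stratified_val_split <- function(y, val_fraction) {
  val <- integer(0)
  for (k in sort(unique(y))) {
    idx <- which(y == k)
    if (length(idx) < 2L) next
    n_val <- max(1L, floor(length(idx) * val_fraction))
    val <- c(val, sample(idx, n_val))
  }
  list(train = setdiff(seq_along(y), val), val = sort(val))
}

# Core SGD classifier training loop, shared by the EEG net, the video nets
# and the softmax classifiers.  `X` uses the engine layout with the batch in
# the middle dimension (or rows for plain matrices); `y` are integer class
# codes in 1..K.
nn_train <- function(layers, X, y, cfg, seed,
                     X_val = NULL, y_val = NULL) {
  assert_that(length(unique(y)) >= 2, "training labels contain a single class",
              "emofuse_degenerate")
  set.seed(child_seed(seed, 101L))
  if (is.null(X_val)) {
    sp <- stratified_val_split(y, cfg$val_fraction)
    assert_that(length(sp$val) > 0, "empty validation split",
                "emofuse_degenerate")
    X_val <- batch_slice(X, sp$val); y_val <- y[sp$val]
    X <- batch_slice(X, sp$train);  y <- y[sp$train]
  }
  n <- batch_count(X)
  best <- Inf; best_snap <- snapshot_params(layers); stall <- 0L
  hist <- vector("list", cfg$max_epochs)
  epochs_run <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    tr_loss <- 0; tr_hit <- 0
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      logits <- seq_forward(layers, batch_slice(X, idx), training = TRUE)
      l <- ce_loss(logits, y[idx])
      tr_loss <- tr_loss + l$loss * length(idx)
      tr_hit <- tr_hit + sum(max.col(l$probs, ties.method = "first") == y[idx])
      seq_backward(layers, l$grad)
      sgd_step_layers(layers, cfg$learning_rate, cfg$momentum %||% 0)
    }
    val_logits <- seq_forward(layers, X_val, training = FALSE)
    lv <- ce_loss(val_logits, y_val)
    val_acc <- mean(max.col(lv$probs, ties.method = "first") == y_val)
    hist[[epoch]] <- c(epoch = epoch, train_loss = tr_loss / n,
                       train_acc = tr_hit / n,
                       val_loss = lv$loss, val_acc = val_acc)
    epochs_run <- epoch
    if (lv$loss < best - 1e-9) {
      best <- lv$loss
      best_snap <- snapshot_params(layers)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$early_stop_patience) break
    }
  }
  restore_params(layers, best_snap)
  clear_caches(layers)
  history <- tibble::as_tibble(do.call(rbind, hist[seq_len(epochs_run)]))
  class(history) <- c("train_history", class(history))
  history
}

nn_predict_probs <- function(layers, X, batch_size = 64L) {
  n <- batch_count(X)
  out <- vector("list", ceiling(n / batch_size))
  j <- 0L
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    j <- j + 1L
    out[[j]] <- softmax_rows(seq_forward(layers, batch_slice(X, idx),
                                         training = FALSE))
  }
  do.call(rbind, out)
}
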