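# Lightweight 1D-CNN feature extractor and classifier for windowed EEG.
#
# The flattened channels-x-samples window passes through three stages of
# (batch norm, valid 1-D convolution, ReLU), the last two with 2x max
# pooling, then a global average pool replaces fully connected feature
# layers, giving a 32-dimensional embedding whose learnable-parameter count
# is independent of the input length: 19,042 scalars in the feature
# extractor (convolution weights and biases plus the normalisation scale
# and shift pairs), with a separate linear softmax head.

#' Architecture of the EEG 1D-CNN
#'
#' @param conv_filters Filters of the three convolution stages.
#' @param kernel_size Convolution kernel length (odd).
#' @param pool_size,pool_stride Max-pooling window and stride (stages 2-3).
#' @param dropout Dropout probability after the pooled feature.
#' @param n_classes Number of emotion classes.
#' @return An `eeg_net_spec` list.
#' @export
eeg_net_spec <- function(conv_filters = c(64, 64, 32), kernel_size = 3,
                         pool_size = 2, pool_stride = 2, dropout = 0.5,
                         n_classes = 3) {
  assert_that(length(conv_filters) == 3, "three convolution stages expected")
  assert_that(kernel_size %% 2 == 1, "kernel size must be odd")
  assert_that(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)")
  structure(list(conv_filters = as.integer(conv_filters),
                 kernel_size = as.integer(kernel_size),
                 pool_size = as.integer(pool_size),
                 pool_stride = as.integer(pool_stride),
                 dropout = dropout, n_classes = as.integer(n_classes)),
            class = "eeg_net_spec")
}

#' Build the EEG 1D-CNN
#'
#' Topology (on the flattened 1-channel window): BN + Conv1D(1 to f1) + ReLU;
#' BN + Conv1D(f1 to f2) + ReLU + MaxPool(2, 2); BN + Conv1D(f2 to f3) +
#' ReLU + MaxPool(2, 2); global average pool over time (the feature tap);
#' dropout; linear softmax head.  Convolutions are valid (no zero padding),
#' stride 1.
#'
#' @param spec An [eeg_net_spec()].
#' @param input_length Flattened window length in samples (channels x
#'   window samples); only used to validate the receptive field, the
#'   parameter count does not depend on it.
#' @param seed Seed for Xavier initialisation.
#' @return An `eeg_net` model object.
#' @export
build_eeg_network <- function(spec = eeg_net_spec(), input_length,
                              seed = 1L) {
  assert_that(inherits(spec, "eeg_net_spec"), "spec must be an eeg_net_spec")
  k <- spec$kernel_size
  # receptive-field check: three valid convs and two 2x pools
  min_len <- ((k + k - 1) * 2 + k - 1) * 2 + k - 1
  assert_that(input_length > min_len,
              "input too short for the network's receptive field",
              "emofuse_shape")
  f <- spec$conv_filters
  with_seed(seed, {
    feature <- list(
      nn_bn(1), nn_conv1d(1, f[1], k), nn_relu(),
      nn_bn(f[1]), nn_conv1d(f[1], f[2], k), nn_relu(),
      nn_maxpool1d(spec$pool_size, spec$pool_stride),
      nn_bn(f[2]), nn_conv1d(f[2], f[3], k), nn_relu(),
      nn_maxpool1d(spec$pool_size, spec$pool_stride),
      nn_gap1d()
    )
    head <- list(nn_dropout(spec$dropout),
                 nn_dense(f[3], spec$n_classes))
    structure(list(feature = feature, head = head, spec = spec,
                   input_length = as.integer(input_length),
                   feature_dim = f[3]),
              class = c("eeg_net", "emofuse_net"))
  })
}

#' Count learnable parameters
#'
#' Counts every learnable scalar: convolution weights and biases, dense
#' weights and biases, and the normalisation scale/shift pairs (running
#' statistics are buffers, not parameters).  With `include_head = FALSE`
#' only the feature extractor is counted.
#'
#' @param model A model built by [build_eeg_network()],
#'   [build_video_network()] or a DCCA transform.
#' @param include_head Also count the classifier head.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model, include_head = FALSE) {
  assert_that(inherits(model, "emofuse_net"), "model must be a built network")
  n <- n_params_layers(model$feature)
  if (include_head) n <- n + n_params_layers(model$head)
  as.integer(n)
}

#' Train the EEG network
#'
#' Minimises cross-entropy by plain SGD with early stopping on the
#' validation loss; training is deterministic given `seed`.
#'
#' @param model A built [build_eeg_network()] model.
#' @param segments List of `eeg_segment` windows (see [segment_eeg()]).
#' @param labels Emotion label per segment (`happy`/`neutral`/`sad`).
#' @param cfg A [train_config()].
#' @param seed Integer seed covering batching, dropout and the validation
#'   split.
#' @param val_segments,val_labels Optional explicit validation set; when
#'   omitted a stratified `cfg$val_fraction` split is drawn.
#' @return The model, with `$history` (per-epoch train/val loss and
#'   accuracy tibble) attached.
#' @export
train_eeg <- function(model, segments, labels, cfg = train_config(),
                      seed = 1L, val_segments = NULL, val_labels = NULL) {
  assert_that(inherits(model, "eeg_net"), "model must be a built eeg_net")
  X <- segments_to_input(segments)
  assert_that(dim(X)[1] == model$input_length,
              "segment length does not match the build-time input_length",
              "emofuse_shape")
  y <- label_codes(labels)
  layers <- c(model$feature, model$head)
  Xv <- NULL; yv <- NULL
  if (!is.null(val_segments)) {
    Xv <- segments_to_input(val_segments)
    yv <- label_codes(val_labels)
  }
  model$history <- nn_train(layers, X, y, cfg, seed, Xv, yv)
  model
}

#' Extract pooled EEG features
#'
#' Runs windows through the feature extractor in evaluation mode and returns
#' the globally pooled activations (before dropout and the head).
#'
#' @param model A built (optionally trained) [build_eeg_network()] model.
#' @param segments List of `eeg_segment` windows.
#' @return Numeric matrix, one row per segment, `model$feature_dim` columns.
#' @export
extract_eeg_features <- function(model, segments) {
  assert_that(inherits(model, "eeg_net"), "model must be a built eeg_net")
  X <- segments_to_input(segments)
  assert_that(dim(X)[1] == model$input_length,
              "segment length does not match the build-time input_length",
              "emofuse_shape")
  net_features(model$feature, X)
}

#' Per-segment class probabilities from the EEG network
#'
#' @inheritParams extract_eeg_features
#' @return Matrix of per-class probabilities (rows sum to 1), columns in
#'   [emotion_levels()] order.
#' @export
predict_eeg_probs <- function(model, segments) {
  X <- segments_to_input(segments)
  P <- nn_predict_probs(c(model$feature, model$head), X)
  colnames(P) <- emotion_levels()
  P
}

# shared helpers ------------------------------------------------------------

label_codes <- function(labels) {
  y <- match(as.character(labels), emotion_levels())
  assert_that(!anyNA(y), "labels must be happy/neutral/sad", "emofuse_range")
  y
}

net_features <- function(feature_layers, X, batch_size = 64L) {
  n <- batch_count(X)
  out <- vector("list", ceiling(n / batch_size))
  j <- 0L
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    j <- j + 1L
    out[[j]] <- seq_forward(feature_layers, batch_slice(X, idx),
                            training = FALSE)
  }
  do.call(rbind, out)
}
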