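# Facial feature extractors: an adapted ResNet-50 (terminal global average
# pool replaced by a global max pool, classification layer replaced by
# dropout + 3-class softmax) and an interchangeable tiny 3-stage backbone
# used at desk scale.  Both expose a feature tap before dropout.

#' Architecture of the video backbone
#'
#' @param backbone `"tiny"` (3-stage small convolutional network) or
#'   `"resnet50"` (adapted ResNet-50).
#' @param in_channels Input channels (1 grayscale, 3 colour).
#' @param dropout Dropout probability before the head.
#' @param n_classes Number of emotion classes.
#' @param input_size Expected conditioned-frame side length (informational;
#'   both backbones are fully convolutional and accept any size above their
#'   receptive field).
#' @param tiny_filters Filters of the tiny backbone's three stages.
#' @return A `video_net_spec` list.
#' @export
video_net_spec <- function(backbone = c("tiny", "resnet50"),
                           in_channels = 1, dropout = 0.5, n_classes = 3,
                           input_size = if (backbone[1] == "resnet50") 224 else 64,
                           tiny_filters = c(8, 16, 32)) {
  backbone <- match.arg(backbone)
  assert_that(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)")
  structure(list(backbone = backbone, in_channels = as.integer(in_channels),
                 dropout = dropout, n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size),
                 tiny_filters = as.integer(tiny_filters)),
            class = "video_net_spec")
}

# ResNet-50 bottleneck: 1x1 reduce, 3x3 (carries the stride), 1x1 expand,
# each with batch norm; projection shortcut when the shape changes.
bottleneck_block <- function(cin, width, stride) {
  cout <- 4L * width
  main <- list(
    nn_conv2d(cin, width, 1, stride = 1, pad = 0), nn_bn(width), nn_relu(),
    nn_conv2d(width, width, 3, stride = stride, pad = 1), nn_bn(width),
    nn_relu(),
    nn_conv2d(width, cout, 1, stride = 1, pad = 0), nn_bn(cout)
  )
  shortcut <- if (stride != 1L || cin != cout) {
    list(nn_conv2d(cin, cout, 1, stride = stride, pad = 0), nn_bn(cout))
  } else list()
  nn_residual(main, shortcut)
}

resnet50_feature_layers <- function(in_channels) {
  layers <- list(
    nn_conv2d(in_channels, 64, 7, stride = 2, pad = 3), nn_bn(64), nn_relu(),
    nn_maxpool2d(3, 2, pad = 1)
  )
  widths <- c(64, 128, 256, 512)
  depths <- c(3, 4, 6, 3)
  cin <- 64L
  for (s in 1:4) {
    for (b in seq_len(depths[s])) {
      stride <- if (b == 1L && s > 1L) 2L else 1L
      layers <- c(layers, list(bottleneck_block(cin, widths[s], stride)))
      cin <- 4L * widths[s]
    }
  }
  # adaptation: global max pool instead of the usual global average pool
  c(layers, list(nn_gmp2d()))
}

tiny_feature_layers <- function(in_channels, filters) {
  f <- filters
  list(
    nn_conv2d(in_channels, f[1], 3, stride = 1, pad = 1), nn_bn(f[1]),
    nn_relu(), nn_maxpool2d(2, 2),
    nn_conv2d(f[1], f[2], 3, stride = 1, pad = 1), nn_bn(f[2]),
    nn_relu(), nn_maxpool2d(2, 2),
    nn_conv2d(f[2], f[3], 3, stride = 1, pad = 1), nn_bn(f[3]),
    nn_relu(), nn_maxpool2d(2, 2),
    nn_gap2d()
  )
}

#' Build the video feature network
#'
#' @param spec A [video_net_spec()].
#' @param seed Seed for Xavier initialisation.
#' @return A `video_net` model with `$feature_dim` 2048 (resnet50) or the
#'   last tiny stage width.
#' @export
build_video_network <- function(spec = video_net_spec(), seed = 1L) {
  assert_that(inherits(spec, "video_net_spec"),
              "spec must be a video_net_spec")
  with_seed(seed, {
    if (spec$backbone == "resnet50") {
      feature <- resnet50_feature_layers(spec$in_channels)
      fdim <- 2048L
    } else {
      feature <- tiny_feature_layers(spec$in_channels, spec$tiny_filters)
      fdim <- spec$tiny_filters[3]
    }
    head <- list(nn_dropout(spec$dropout), nn_dense(fdim, spec$n_classes))
    structure(list(feature = feature, head = head, spec = spec,
                   feature_dim = fdim),
              class = c("video_net", "emofuse_net"))
  })
}

# Stack frames (each H x W or H x W x C) into the engine layout (H, W, B, C).
frames_to_input <- function(frames, in_channels) {
  d <- dim(frames[[1]])
  gray <- length(d) == 2L
  assert_that((gray && in_channels == 1L) || (!gray && d[3] == in_channels),
              "frame channels do not match the network's in_channels",
              "emofuse_shape")
  if (gray) {
    array(unlist(frames), dim = c(d[1], d[2], length(frames), 1L))
  } else {
    arr <- array(unlist(frames), dim = c(d[1], d[2], d[3], length(frames)))
    aperm(arr, c(1, 2, 4, 3))
  }
}

#' Train the video network on labelled frames
#'
#' Per-frame training with the trial label, by SGD on cross-entropy with
#' early stopping (same contract as [train_eeg()]).
#'
#' @param model A built [build_video_network()] model.
#' @param frames List of conditioned frames.
#' @param labels Emotion label per frame.
#' @param cfg A [train_config()].
#' @param seed Integer seed.
#' @param val_frames,val_labels Optional explicit validation set.
#' @return The model with `$history` attached.
#' @export
train_video <- function(model, frames, labels, cfg = train_config(),
                        seed = 1L, val_frames = NULL, val_labels = NULL) {
  assert_that(inherits(model, "video_net"), "model must be a built video_net")
  X <- frames_to_input(frames, model$spec$in_channels)
  y <- label_codes(labels)
  Xv <- NULL; yv <- NULL
  if (!is.null(val_frames)) {
    Xv <- frames_to_input(val_frames, model$spec$in_channels)
    yv <- label_codes(val_labels)
  }
  model$history <- nn_train(c(model$feature, model$head), X, y, cfg, seed,
                            Xv, yv)
  model
}

# Window id of each retained frame, from its source index.
frame_windows <- function(seq, window_seconds) {
  ceiling(seq$source_index / (seq$fps * window_seconds))
}

#' Per-window video features aligned with the EEG segments
#'
#' Frames (already selected and conditioned) are grouped by the same
#' non-overlapping windows as the EEG segmentation, using each frame's
#' source index so that selection does not shift window boundaries; the
#' window feature is the mean of the per-frame feature vectors, an
#' order-invariant aggregate.
#'
#' @param model A built [build_video_network()] model.
#' @param seq A [frame_sequence()] (output of [select_frames()] /
#'   [condition_frames()]).
#' @param window_seconds Window length in seconds (must match the EEG
#'   segmentation).
#' @param n_windows Number of windows expected; defaults to the count
#'   implied by the source sequence duration.
#' @return Matrix of per-window features (`n_windows` x `feature_dim`).
#' @export
extract_video_features <- function(model, seq, window_seconds = 5,
                                   n_windows = NULL) {
  assert_that(inherits(model, "video_net"), "model must be a built video_net")
  assert_that(inherits(seq, "frame_sequence"), "seq must be a frame_sequence")
  wins <- frame_windows(seq, window_seconds)
  n_windows <- n_windows %||% max(wins)
  X <- frames_to_input(seq$frames, model$spec$in_channels)
  F <- net_features(model$feature, X)
  out <- matrix(0, n_windows, ncol(F))
  for (w in seq_len(n_windows)) {
    rows <- which(wins == w)
    if (length(rows) == 0L) {
      stop_emofuse(sprintf(
        "window %d of trial %s has no surviving frames", w,
        seq$trial_ref %||% "?"), "emofuse_empty_window")
    }
    out[w, ] <- colMeans(F[rows, , drop = FALSE])
  }
  out
}

#' Per-window class probabilities from the video network
#'
#' Per-frame head probabilities averaged within each window.
#'
#' @inheritParams extract_video_features
#' @return Matrix (`n_windows` x classes), columns in [emotion_levels()]
#'   order.
#' @export
predict_video_probs <- function(model, seq, window_seconds = 5,
                                n_windows = NULL) {
  wins <- frame_windows(seq, window_seconds)
  n_windows <- n_windows %||% max(wins)
  X <- frames_to_input(seq$frames, model$spec$in_channels)
  P <- nn_predict_probs(c(model$feature, model$head), X)
  out <- matrix(0, n_windows, ncol(P))
  for (w in seq_len(n_windows)) {
    rows <- which(wins == w)
    if (length(rows) == 0L) {
      stop_emofuse(sprintf(
        "window %d of trial %s has no surviving frames", w,
        seq$trial_ref %||% "?"), "emofuse_empty_window")
    }
    out[w, ] <- colMeans(P[rows, , drop = FALSE])
  }
  colnames(out) <- emotion_levels()
  out
}
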