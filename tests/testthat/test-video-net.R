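test_that("the tiny backbone declares and delivers its feature dimension", {
  m <- build_video_network(video_net_spec("tiny", in_channels = 1,
                                          input_size = 16), seed = 2)
  expect_equal(m$feature_dim, 32)
  f <- random_frames(3, 16, 16, seed = 1)
  X <- emofuse:::frames_to_input(f, 1L)
  F <- emofuse:::net_features(m$feature, X)
  expect_equal(dim(F), c(3, 32))
  P <- emofuse:::nn_predict_probs(c(m$feature, m$head), X)
  expect_equal(rowSums(P), rep(1, 3), tolerance = 1e-9)
})

test_that("the adapted residual backbone ends in a 2048-wide feature tap", {
  m <- build_video_network(video_net_spec("resnet50", in_channels = 3),
                           seed = 1)
  expect_equal(m$feature_dim, 2048)
  # independent symbolic tally of the stage layout (conv + norm parameters)
  widths <- c(64, 128, 256, 512); depths <- c(3, 4, 6, 3)
  tally <- 3 * 64 * 7 * 7 + 64 + 2 * 64          # stem conv + bias + norm
  cin <- 64
  for (s in 1:4) {
    w <- widths[s]
    for (b in seq_len(depths[s])) {
      tally <- tally +
        (cin * w + w) + 2 * w +                  # 1x1 reduce + norm
        (w * w * 9 + w) + 2 * w +                # 3x3 + norm
        (w * 4 * w + 4 * w) + 2 * 4 * w          # 1x1 expand + norm
      if (b == 1) {
        tally <- tally + (cin * 4 * w + 4 * w) + 2 * 4 * w   # projection
      }
      cin <- 4 * w
    }
  }
  expect_identical(count_parameters(m), as.integer(tally))
  # the global max pool makes the tap width input-size independent
  f <- lapply(1:2, function(i) array(runif(64 * 64 * 3), c(64, 64, 3)))
  F <- emofuse:::net_features(m$feature, emofuse:::frames_to_input(f, 3L))
  expect_equal(dim(F), c(2, 2048))
  expect_error(build_video_network(video_net_spec("unknown")),
               regexp = "arg")
})

test_that("per-window features align with the EEG segmentation", {
  cfg <- synthetic_config(n_subjects = 1, trials_per_subject = 1,
                          trial_seconds = 60, eeg_fs = 128, fps = 4,
                          frame_size = 12, seed = 6)
  tr <- generate_dataset(cfg)[[1]]
  sel <- select_frames(tr$video, 0.4)
  m <- build_video_network(video_net_spec("tiny", in_channels = 1,
                                          input_size = 12), seed = 3)
  F <- extract_video_features(m, sel, window_seconds = 5)
  expect_equal(nrow(F), 12)   # matches the 5-s EEG windows of a 60-s trial
  expect_equal(nrow(F), length(segment_eeg(select_channels(tr$eeg), 5)))
})

test_that("window features are order-invariant means of frame features", {
  m <- build_video_network(video_net_spec("tiny", in_channels = 1,
                                          input_size = 8), seed = 4)
  f <- random_frames(6, 8, 8, seed = 9)
  seq1 <- frame_sequence(f, fps = 6)
  F1 <- extract_video_features(m, seq1, window_seconds = 1)
  # permuting frames within the window leaves the mean unchanged
  seq2 <- frame_sequence(f[c(3, 1, 6, 2, 5, 4)], fps = 6)
  seq2$source_index <- seq_along(f)
  F2 <- extract_video_features(m, seq2, window_seconds = 1)
  expect_equal(F1, F2, tolerance = 1e-12)
  # a window of identical frames equals the single-frame feature
  same <- frame_sequence(f[c(1, 1, 1)], fps = 3)
  F3 <- extract_video_features(m, same, window_seconds = 1)
  single <- emofuse:::net_features(m$feature,
                                   emofuse:::frames_to_input(f[1], 1L))
  expect_equal(F3[1, ], single[1, ], tolerance = 1e-12)
})

test_that("a window with no surviving frames is reported", {
  m <- build_video_network(video_net_spec("tiny", in_channels = 1,
                                          input_size = 8), seed = 5)
  seq <- frame_sequence(random_frames(4, 8, 8), fps = 4)
  seq$source_index <- c(1, 2, 3, 4)
  expect_error(extract_video_features(m, seq, window_seconds = 1,
                                      n_windows = 3),
               class = "emofuse_empty_window")
})

test_that("video training is deterministic for a fixed seed", {
  set.seed(10)
  f <- random_frames(24, 8, 8, seed = 10)
  labs <- rep(c("happy", "sad"), each = 12)
  for (i in 13:24) f[[i]] <- f[[i]] + 0.5
  fit_once <- function() {
    m <- build_video_network(video_net_spec("tiny", in_channels = 1,
                                            input_size = 8), seed = 6)
    m <- train_video(m, f, labs,
                     cfg = train_config(learning_rate = 0.05,
                                        max_epochs = 3, batch_size = 8,
                                        val_fraction = 0.25),
                     seed = 6)
    m$feature[[1]]$W
  }
  expect_identical(fit_once(), fit_once())
})
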