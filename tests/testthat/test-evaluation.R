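test_that("one fold per subject, partitioning the dataset without leakage", {
  man <- tibble::tibble(
    subject_id = rep(1:5, each = 6), trial_id = rep(1:6, 5),
    label = rep(c("happy", "neutral", "sad"), 10))
  folds <- loso_folds(man, seed = 3)
  expect_equal(nrow(folds), 5)
  for (f in seq_len(nrow(folds))) {
    tr <- folds$train[[f]]; va <- folds$val[[f]]; te <- folds$test[[f]]
    expect_setequal(c(tr, va, te), seq_len(nrow(man)))
    expect_length(intersect(tr, va), 0)
    expect_length(intersect(c(tr, va), te), 0)
    expect_true(all(man$subject_id[te] == folds$test_subject[f]))
    expect_false(folds$test_subject[f] %in% man$subject_id[c(tr, va)])
    expect_gt(length(va), 0)
  }
  # every subject is the test subject exactly once
  expect_setequal(folds$test_subject, 1:5)
})

test_that("the minimal two-subject design trains on exactly one subject", {
  man <- tibble::tibble(subject_id = rep(1:2, each = 4), trial_id = rep(1:4, 2),
                        label = rep(c("happy", "sad"), 4))
  folds <- loso_folds(man, seed = 1)
  expect_equal(nrow(folds), 2)
  for (f in 1:2) {
    expect_equal(unique(man$subject_id[c(folds$train[[f]], folds$val[[f]])]),
                 setdiff(1:2, folds$test_subject[f]))
  }
  expect_error(loso_folds(man[man$subject_id == 1, ]),
               class = "emofuse_range")
})

test_that("metrics match hand-computed confusion arithmetic", {
  # class 'happy': TP = 8, FN = 2, FP = 2 out of n = 30
  labels <- c(rep("happy", 10), rep("sad", 10), rep("neutral", 10))
  preds <- c(rep("happy", 8), rep("sad", 2),
             rep("happy", 2), rep("sad", 8),
             rep("neutral", 10))
  rep_ <- compute_metrics(preds, labels)
  happy <- rep_$per_class[rep_$per_class$class == "happy", ]
  expect_equal(happy$precision, 80)
  expect_equal(happy$recall, 80)
  expect_equal(happy$f1, 0.80)
  expect_equal(rep_$overall$accuracy, 100 * 26 / 30)
  # F1 is the harmonic mean of its own precision and recall
  for (i in seq_len(nrow(rep_$per_class))) {
    p <- rep_$per_class$precision[i] / 100
    r <- rep_$per_class$recall[i] / 100
    expect_equal(rep_$per_class$f1[i],
                 ifelse(p + r > 0, 2 * p * r / (p + r), 0), tolerance = 1e-9)
  }
})

test_that("perfect and constant predictors hit the closed-form rates", {
  labels <- rep(c("happy", "neutral", "sad"), 8)
  perfect <- compute_metrics(labels, labels)
  expect_equal(perfect$overall$accuracy, 100)
  expect_equal(perfect$overall$f1, 1)
  constant <- compute_metrics(rep("happy", 24), labels)
  expect_equal(constant$overall$accuracy, 100 / 3, tolerance = 1e-9)
  expect_error(compute_metrics(character(0), character(0)),
               class = "emofuse_shape")
  expect_error(compute_metrics("angry", "happy"), class = "emofuse_range")
})

test_that("tidiers expose per-class and overall metric tables", {
  labels <- rep(c("happy", "neutral", "sad"), 5)
  rep_ <- compute_metrics(labels, labels)
  expect_s3_class(tidy(rep_), "tbl_df")
  expect_equal(nrow(tidy(rep_)), 3)
  expect_equal(glance(rep_)$n, 15)
})

test_that("a small pipeline run is reproducible and internally consistent", {
  cfg <- synthetic_config(n_subjects = 2, trials_per_subject = 6,
                          trial_seconds = 5, eeg_fs = 128, fps = 4,
                          frame_size = 12, effect_size = 2,
                          cross_modal_corr = 0.7, seed = 21)
  trials <- generate_dataset(cfg)
  pc <- pipeline_config(
    video_input_size = 12, dcca_dim = 4,
    methods = c("eeg", "video", "dcca", "max"),
    eeg_cfg = train_config(learning_rate = 0.05, momentum = 0.9,
                           batch_size = 8, max_epochs = 2,
                           early_stop_patience = 2),
    video_cfg = train_config(learning_rate = 0.02, momentum = 0.9,
                             batch_size = 16, max_epochs = 2,
                             early_stop_patience = 2),
    dcca_cfg = train_config(learning_rate = 0.01, max_epochs = 5),
    classifier_cfg = train_config(learning_rate = 0.1, max_epochs = 10,
                                  early_stop_patience = 10))
  r1 <- suppressWarnings(run_pipeline(trials, pc, seed = 4))
  r2 <- suppressWarnings(run_pipeline(trials, pc, seed = 4))
  expect_identical(r1$per_fold, r2$per_fold)
  # summary rows average the per-fold rows
  for (m in pc$methods) {
    for (lv in c("window", "trial")) {
      rows <- dplyr::filter(r1$per_fold, .data$method == m,
                            .data$level == lv)
      s <- dplyr::filter(r1$summary, .data$method == m, .data$level == lv)
      expect_equal(s$accuracy, mean(rows$accuracy))
    }
  }
  expect_setequal(unique(r1$per_fold$method), pc$methods)
  expect_equal(nrow(r1$folds), 2)
  expect_true(all(r1$per_fold$accuracy >= 0 & r1$per_fold$accuracy <= 100))
})
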