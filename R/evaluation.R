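# Leave-one-subject-out protocol, metric computation, and the end-to-end
# pipeline driver: preprocess -> per-modality training -> feature
# extraction -> fusion -> classification, evaluated per fold.

#' Leave-one-subject-out folds
#'
#' One fold per subject: that subject's trials form the test set and the
#' remaining subjects' trials are split 90/10 into training and validation,
#' stratified by class at the trial level (windows of one trial never
#' straddle the split).
#'
#' @param manifest Tibble with `subject_id`, `trial_id`, `label` (one row
#'   per trial), e.g. from [dataset_manifest()].
#' @param seed Integer seed for the stratified validation draw.
#' @param val_fraction Validation share of the non-test trials.
#' @return Tibble with one row per fold: `fold`, `test_subject`, and
#'   list-columns `train`, `val`, `test` of manifest row indices.
#' @export
loso_folds <- function(manifest, seed = 1L, val_fraction = 0.10) {
  subjects <- sort(unique(manifest$subject_id))
  assert_that(length(subjects) >= 2, "need at least 2 subjects",
              "emofuse_range")
  counts <- table(manifest$subject_id)
  assert_that(all(counts > 0), "every subject needs at least one trial")
  folds <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    test_rows <- which(manifest$subject_id == subjects[i])
    rest <- which(manifest$subject_id != subjects[i])
    sp <- with_seed(child_seed(seed, i), {
      y <- match(manifest$label[rest], emotion_levels())
      stratified_val_split(y, val_fraction)
    })
    folds[[i]] <- tibble::tibble(
      fold = i, test_subject = subjects[i],
      train = list(rest[sp$train]), val = list(rest[sp$val]),
      test = list(test_rows))
  }
  dplyr::bind_rows(folds)
}

#' Classification metrics report
#'
#' Overall accuracy, macro recall and precision on the 0-100 scale, macro F1
#' on the 0-1 scale, plus per-class one-vs-rest metrics.  A class never
#' predicted gets precision 0 by convention.
#'
#' @param predictions,labels Aligned label vectors
#'   (`happy`/`neutral`/`sad`).
#' @return A `metrics_report` (list with `$overall`, `$per_class` tibbles
#'   and the `$confusion` matrix).
#' @export
compute_metrics <- function(predictions, labels) {
  predictions <- as.character(predictions)
  labels <- as.character(labels)
  assert_that(length(predictions) == length(labels) && length(labels) > 0,
              "predictions and labels must align and be non-empty",
              "emofuse_shape")
  lv <- emotion_levels()
  assert_that(all(labels %in% lv) && all(predictions %in% lv),
              "unknown label", "emofuse_range")
  conf <- table(factor(labels, lv), factor(predictions, lv))
  n <- length(labels)
  per <- lapply(lv, function(cl) {
    tp <- conf[cl, cl]
    fp <- sum(conf[, cl]) - tp
    fn <- sum(conf[cl, ]) - tp
    tn <- n - tp - fp - fn
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    tibble::tibble(class = cl, accuracy = 100 * (tp + tn) / n,
                   precision = 100 * prec, recall = 100 * rec, f1 = f1)
  })
  per_class <- dplyr::bind_rows(per)
  overall <- tibble::tibble(
    accuracy = 100 * sum(diag(conf)) / n,
    recall = mean(per_class$recall),
    precision = mean(per_class$precision),
    f1 = mean(per_class$f1))
  structure(list(overall = overall, per_class = per_class,
                 confusion = conf, n = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> n=%d  accuracy %.2f%%  recall %.2f%%  precision %.2f%%  F1 %.4f\n",
    x$n, x$overall$accuracy, x$overall$recall, x$overall$precision,
    x$overall$f1))
  invisible(x)
}

#' Pipeline configuration
#'
#' Study settings for [run_pipeline()].  The defaults follow the method's
#' published operating point (4-45 Hz band, ten frontal/temporal
#' electrodes, 5-s windows, 40% per-second frame retention, equal fusion
#' weights); the network sizes and epoch budgets are desk-scale.
#'
#' @param window_seconds EEG/video window length, s.
#' @param band Band-pass edges, Hz.
#' @param channels Electrode subset for the EEG branch.
#' @param keep_fraction Per-second frame retention.
#' @param video_input_size Side length frames are conditioned to before the
#'   video backbone.
#' @param video_backbone `"tiny"` or `"resnet50"`.
#' @param train_frames_per_window Frames per window used for video
#'   training (evenly subsampled; extraction uses all retained frames).
#' @param dcca_arch,dcca_dim DCCA transform architecture and output
#'   dimension.
#' @param alpha,beta DCCA fusion weights (`alpha + beta = 1`).
#' @param dcca_r DCCA covariance regularizer.
#' @param methods Methods to evaluate, a subset of `eeg`, `video`, `dcca`,
#'   `concat`, `max`, `choquet`, `adaptive`.
#' @param eeg_cfg,video_cfg,dcca_cfg,classifier_cfg [train_config()]s of
#'   the four trainable components.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(window_seconds = 5, band = c(4, 45),
                            channels = selected_electrodes(),
                            keep_fraction = 0.40, video_input_size = 24,
                            video_backbone = "tiny",
                            train_frames_per_window = 6,
                            dcca_arch = "linear", dcca_dim = 8,
                            alpha = 0.5, beta = 1 - alpha, dcca_r = 1e-5,
                            methods = c("eeg", "video", "dcca", "concat",
                                        "max", "choquet", "adaptive"),
                            eeg_cfg = train_config(learning_rate = 0.05,
                                                   max_epochs = 8,
                                                   batch_size = 8,
                                                   early_stop_patience = 8,
                                                   momentum = 0.9),
                            video_cfg = train_config(learning_rate = 0.02,
                                                     max_epochs = 8,
                                                     batch_size = 16,
                                                     early_stop_patience = 8,
                                                     momentum = 0.9),
                            dcca_cfg = train_config(learning_rate = 0.01,
                                                    max_epochs = 40),
                            classifier_cfg = train_config(
                              learning_rate = 0.1, max_epochs = 60,
                              early_stop_patience = 20)) {
  assert_that(keep_fraction > 0 && keep_fraction <= 1,
              "keep_fraction must lie in (0, 1]", "emofuse_range")
  assert_that(abs(alpha + beta - 1) < 1e-9 && alpha >= 0 && beta >= 0,
              "fusion weights must be non-negative and sum to 1",
              "emofuse_range")
  known <- c("eeg", "video", "dcca", "concat", "max", "choquet", "adaptive")
  assert_that(all(methods %in% known),
              paste("unknown method(s):",
                    paste(setdiff(methods, known), collapse = ", ")),
              "emofuse_range")
  structure(list(window_seconds = window_seconds, band = band,
                 channels = channels, keep_fraction = keep_fraction,
                 video_input_size = as.integer(video_input_size),
                 video_backbone = video_backbone,
                 train_frames_per_window = as.integer(train_frames_per_window),
                 dcca_arch = dcca_arch, dcca_dim = as.integer(dcca_dim),
                 alpha = alpha, beta = beta, dcca_r = dcca_r,
                 methods = methods, eeg_cfg = eeg_cfg, video_cfg = video_cfg,
                 dcca_cfg = dcca_cfg, classifier_cfg = classifier_cfg),
            class = "pipeline_config")
}

# Majority vote over a trial's window predictions; ties break to the class
# with the highest mean score (falling back to canonical order).
aggregate_windows <- function(pred_idx, scores = NULL) {
  tab <- tabulate(pred_idx, nbins = length(emotion_levels()))
  winners <- which(tab == max(tab))
  if (length(winners) == 1L || is.null(scores)) return(winners[1])
  winners[which.max(colMeans(scores)[winners])]
}

# Evenly subsample up to k frame positions.
subsample_idx <- function(n, k) {
  if (n <= k) seq_len(n) else unique(round(seq(1, n, length.out = k)))
}

#' Run the full leave-one-subject-out pipeline
#'
#' Executes, for every fold: EEG preprocessing (band-pass, electrode
#' selection, windowing) and network training; frame selection,
#' conditioning and video network training; per-window feature extraction;
#' DCCA fusion plus the requested baseline fusion rules; and per-trial
#' classification by majority vote over window decisions.  Normalisation
#' statistics, DCCA fitting and all classifier training see only
#' train/validation rows, never the held-out subject.
#'
#' @param trials Trial list from [generate_dataset()] (or assembled with
#'   the same fields).
#' @param config A [pipeline_config()].
#' @param seed Integer seed governing every stochastic stage.
#' @return An `emofuse_result`: list with `$per_fold` (fold x method x
#'   level metric rows), `$summary` (method x level averages), `$folds`,
#'   and the echoed `$config` and `$seed`.
#' @export
run_pipeline <- function(trials, config = pipeline_config(), seed = 1L) {
  assert_that(inherits(config, "pipeline_config"),
              "config must come from pipeline_config()")
  manifest <- dataset_manifest(trials)
  ws <- config$window_seconds

  # ---- shared preprocessing (deterministic, no fitted statistics) ----
  prep <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    rec <- eeg_bandpass(tr$eeg, config$band[1], config$band[2])
    rec <- select_channels(rec, config$channels)
    segs <- segment_eeg(rec, ws)
    vid <- select_frames(tr$video, config$keep_fraction)
    vid$trial_ref <- paste(tr$subject_id, tr$trial_id, sep = "/")
    vid <- condition_frames(vid, out_size = config$video_input_size)
    n_win <- length(segs)
    wins <- frame_windows(vid, ws)
    keep <- wins <= n_win
    vid$frames <- vid$frames[keep]
    vid$source_index <- vid$source_index[keep]
    prep[[i]] <- list(segs = segs, vid = vid, n_win = n_win,
                      label = tr$label, subject = tr$subject_id)
  }
  n_win_all <- vapply(prep, `[[`, 0L, "n_win")

  folds <- loso_folds(manifest, seed = seed)
  input_len <- nrow(prep[[1]]$segs[[1]]$data) * ncol(prep[[1]]$segs[[1]]$data)

  seg_pool <- function(rows) {
    list(segs = unlist(lapply(prep[rows], `[[`, "segs"), recursive = FALSE),
         labels = rep(vapply(prep[rows], `[[`, "", "label"),
                      n_win_all[rows]),
         trial = rep(rows, n_win_all[rows]))
  }
  frame_pool <- function(rows, cap) {
    fr <- list(); lb <- character(0)
    for (i in rows) {
      v <- prep[[i]]$vid
      wins <- frame_windows(v, ws)
      pick <- unlist(lapply(unique(wins), function(w) {
        at <- which(wins == w)
        at[subsample_idx(length(at), cap)]
      }))
      fr <- c(fr, v$frames[pick])
      lb <- c(lb, rep(prep[[i]]$label, length(pick)))
    }
    list(frames = fr, labels = lb)
  }

  per_fold <- list()
  for (f in seq_len(nrow(folds))) {
    tr_rows <- folds$train[[f]]; va_rows <- folds$val[[f]]
    te_rows <- folds$test[[f]]
    fseed <- child_seed(seed, 1000L + f)

    p_tr <- seg_pool(tr_rows); p_va <- seg_pool(va_rows)
    p_te <- seg_pool(te_rows)

    # EEG branch
    eeg_model <- build_eeg_network(eeg_net_spec(), input_len, seed = fseed)
    eeg_model <- train_eeg(eeg_model, p_tr$segs, p_tr$labels,
                           cfg = config$eeg_cfg, seed = fseed,
                           val_segments = p_va$segs, val_labels = p_va$labels)
    eeg_probs <- lapply(prep, function(p) predict_eeg_probs(eeg_model, p$segs))
    eeg_feats <- lapply(prep, function(p)
      extract_eeg_features(eeg_model, p$segs))

    # video branch
    fp_tr <- frame_pool(tr_rows, config$train_frames_per_window)
    fp_va <- frame_pool(va_rows, config$train_frames_per_window)
    vid_model <- build_video_network(
      video_net_spec(config$video_backbone, in_channels = 1,
                     input_size = config$video_input_size),
      seed = fseed)
    vid_model <- train_video(vid_model, fp_tr$frames, fp_tr$labels,
                             cfg = config$video_cfg, seed = fseed,
                             val_frames = fp_va$frames,
                             val_labels = fp_va$labels)
    vid_probs <- lapply(seq_along(prep), function(i)
      predict_video_probs(vid_model, prep[[i]]$vid, ws,
                          n_windows = prep[[i]]$n_win))
    vid_feats <- lapply(seq_along(prep), function(i)
      extract_video_features(vid_model, prep[[i]]$vid, ws,
                             n_windows = prep[[i]]$n_win))

    stack_rows <- function(lst, rows) do.call(rbind, lst[rows])
    I1_tr <- stack_rows(eeg_feats, c(tr_rows, va_rows))
    I2_tr <- stack_rows(vid_feats, c(tr_rows, va_rows))
    y_trval <- rep(vapply(prep[c(tr_rows, va_rows)], `[[`, "", "label"),
                   n_win_all[c(tr_rows, va_rows)])
    I1_te <- stack_rows(eeg_feats, te_rows)
    I2_te <- stack_rows(vid_feats, te_rows)

    # validation accuracies feed the Choquet densities
    val_idx_pool <- seg_pool(va_rows)
    eeg_val_pred <- max.col(do.call(rbind, eeg_probs[va_rows]),
                            ties.method = "first")
    vid_val_pred <- max.col(do.call(rbind, vid_probs[va_rows]),
                            ties.method = "first")
    y_val <- label_codes(val_idx_pool$labels)
    dens <- pmin(pmax(c(mean(eeg_val_pred == y_val),
                        mean(vid_val_pred == y_val)), 0.05), 0.95)

    fitted <- list()
    if ("dcca" %in% config$methods) {
      dm <- train_dcca(I1_tr, I2_tr,
                       dcca_transform_spec(config$dcca_arch,
                                           output_dim = config$dcca_dim),
                       cfg = config$dcca_cfg, seed = fseed, r = config$dcca_r,
                       alpha = config$alpha, beta = config$beta)
      Otr <- dcca_transform(dm, I1_tr, I2_tr)
      fused_tr <- fuse_features(Otr$O1, Otr$O2, dm$alpha, dm$beta)
      fitted$dcca_clf <- classify_fused(fused_tr, y_trval,
                                        cfg = config$classifier_cfg,
                                        seed = fseed)
      fitted$dcca <- dm
    }
    if ("concat" %in% config$methods) {
      cat_tr <- concat_fuse(I1_tr, I2_tr)
      fitted$concat_stats <- attr(cat_tr, "stats")
      fitted$concat_clf <- classify_fused(cat_tr, y_trval,
                                          cfg = config$classifier_cfg,
                                          seed = child_seed(fseed, 2L))
    }

    # ---- test-subject predictions, per window then per trial ----
    level_rows <- list()
    trial_pred <- list()
    win_pred <- list()
    for (m in config$methods) win_pred[[m]] <- integer(0)
    te_labels_trial <- vapply(prep[te_rows], `[[`, "", "label")

    for (i in te_rows) {
      Pe <- eeg_probs[[i]]; Pv <- vid_probs[[i]]
      preds <- list()
      scores <- list()
      if ("eeg" %in% config$methods) {
        preds$eeg <- max.col(Pe, ties.method = "first"); scores$eeg <- Pe
      }
      if ("video" %in% config$methods) {
        preds$video <- max.col(Pv, ties.method = "first"); scores$video <- Pv
      }
      if ("dcca" %in% config$methods) {
        Ot <- dcca_transform(fitted$dcca, eeg_feats[[i]], vid_feats[[i]])
        Pf <- predict(fitted$dcca_clf,
                      fuse_features(Ot$O1, Ot$O2, fitted$dcca$alpha,
                                    fitted$dcca$beta))
        preds$dcca <- max.col(Pf, ties.method = "first"); scores$dcca <- Pf
      }
      if ("concat" %in% config$methods) {
        Pc <- predict(fitted$concat_clf,
                      concat_fuse(eeg_feats[[i]], vid_feats[[i]],
                                  stats = fitted$concat_stats))
        preds$concat <- max.col(Pc, ties.method = "first"); scores$concat <- Pc
      }
      if ("max" %in% config$methods) {
        preds$max <- max_fuse(list(Pe, Pv))
        scores$max <- pmax(Pe, Pv)
      }
      if ("choquet" %in% config$methods) {
        meas <- sugeno_lambda_measure(dens)
        preds$choquet <- choquet_label(list(Pe, Pv), meas)
        scores$choquet <- (Pe * dens[1] + Pv * dens[2]) / sum(dens)
      }
      if ("adaptive" %in% config$methods) {
        preds$adaptive <- adaptive_label(Pe, Pv)
        scores$adaptive <- matrix(
          adaptive_fuse(as.vector(Pe), as.vector(Pv)), nrow(Pe), ncol(Pe))
      }
      for (m in names(preds)) {
        win_pred[[m]] <- c(win_pred[[m]], preds[[m]])
        trial_pred[[m]] <- c(trial_pred[[m]],
                             aggregate_windows(preds[[m]], scores[[m]]))
      }
    }

    te_labels_win <- p_te$labels
    for (m in config$methods) {
      mw <- compute_metrics(emotion_levels()[win_pred[[m]]], te_labels_win)
      mt <- compute_metrics(emotion_levels()[trial_pred[[m]]],
                            te_labels_trial)
      level_rows[[length(level_rows) + 1L]] <- dplyr::bind_rows(
        dplyr::mutate(mw$overall, level = "window"),
        dplyr::mutate(mt$overall, level = "trial")) |>
        dplyr::mutate(method = m, fold = f,
                      test_subject = folds$test_subject[f])
    }
    per_fold[[f]] <- dplyr::bind_rows(level_rows)
  }

  per_fold <- dplyr::bind_rows(per_fold)
  summary <- per_fold |>
    dplyr::group_by(.data$method, .data$level) |>
    dplyr::summarise(dplyr::across(c("accuracy", "recall", "precision",
                                     "f1"), mean),
                     n_folds = dplyr::n(), .groups = "drop")
  structure(list(per_fold = per_fold, summary = summary, folds = folds,
                 config = config, seed = seed),
            class = "emofuse_result")
}

#' @export
print.emofuse_result <- function(x, ...) {
  cat(sprintf("<emofuse_result> %d folds, seed %d\n", nrow(x$folds), x$seed))
  s <- dplyr::filter(x$summary, .data$level == "trial")
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-8s trial accuracy %6.2f%%  F1 %.4f\n",
                s$method[i], s$accuracy[i], s$f1[i]))
  }
  invisible(x)
}
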