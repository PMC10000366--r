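# Synthetic paired EEG / facial-video trials with a known latent emotion
# class, so that every downstream stage (preprocessing, the feature
# extractors, DCCA fusion, the LOSO driver) can be exercised and audited
# without access to gated recording corpora.

# 32-channel 10-20 montage superset containing the ten selected electrodes.
montage_32 <- function() {
  c("FP1", "FP2", "AF3", "AF4", "F7", "F3", "FZ", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "T7", "C3", "CZ", "C4", "T8",
    "CP5", "CP1", "CP2", "CP6", "P7", "P3", "PZ", "P4", "P8",
    "PO3", "PO4", "O1", "OZ", "O2")
}

#' Electrodes used for emotion recognition
#'
#' The five frontal/temporal electrode pairs retained for EEG feature
#' extraction: FP1/FP2, AF3/AF4, F3/F4, F7/F8, T7/T8.
#'
#' @return Character vector of ten 10-20 electrode names.
#' @export
selected_electrodes <- function() {
  c("FP1", "FP2", "AF3", "AF4", "F3", "F4", "F7", "F8", "T7", "T8")
}

#' Configuration of the synthetic paired-trial generator
#'
#' Defines the simulated study: paired 60-s trials of multichannel EEG (class
#' dependent band-limited oscillations on the frontal/temporal channels over
#' a 1/f background) and facial frame sequences (a face-sized canvas whose
#' appearance dynamics depend on the class, with runs of near-duplicate
#' frames), sharing one latent three-class label per trial.
#'
#' @param n_subjects,trials_per_subject Number of subjects and trials each.
#' @param trial_seconds Trial duration in seconds.
#' @param eeg_fs EEG sampling rate in Hz.
#' @param eeg_channels Channel names of the simulated montage; must contain
#'   the ten selected electrodes.
#' @param fps Video frame rate (frames per second).
#' @param frame_size Height/width of the square grayscale frames, pixels.
#' @param class_probs Probabilities of the happy/neutral/sad latent classes;
#'   must sum to 1.
#' @param effect_size Dimensionless separation of the class-dependent signal
#'   amplitudes; 0 removes all class information from both modalities.
#' @param cross_modal_corr Fraction (in \[0,1\]) of the trial-level signal
#'   modulation shared between the modalities rather than modality-private.
#' @param noise_sd Per-modality additive noise scale.
#' @param duplicate_run_length Length of injected runs of near-identical
#'   consecutive frames (0 disables injection).
#' @param complementary_noise If `TRUE`, each trial randomly attenuates the
#'   class signal in one modality, so the two modalities err on different
#'   trials and fusion has headroom over either alone.
#' @param label_policy `"mean"` thresholds the mean of valence and arousal;
#'   `"valence"` thresholds valence only.
#' @param seed Integer seed; fixed seed gives bit-identical datasets.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_subjects = 27, trials_per_subject = 20,
                             trial_seconds = 60, eeg_fs = 128,
                             eeg_channels = montage_32(),
                             fps = 20, frame_size = 64,
                             class_probs = c(happy = 1, neutral = 1, sad = 1) / 3,
                             effect_size = 2, cross_modal_corr = 0.7,
                             noise_sd = 1, duplicate_run_length = 3,
                             complementary_noise = FALSE,
                             label_policy = c("mean", "valence"),
                             seed = 1L) {
  label_policy <- match.arg(label_policy)
  assert_that(n_subjects >= 1 && trials_per_subject >= 1 &&
                trial_seconds > 0 && eeg_fs > 0 && fps > 0 && frame_size >= 4,
              "all counts and rates must be positive")
  assert_that(length(class_probs) == 3 && all(class_probs >= 0),
              "class_probs must be a 3-vector of probabilities")
  assert_that(abs(sum(class_probs) - 1) < 1e-12,
              "class_probs must sum to 1")
  assert_that(cross_modal_corr >= 0 && cross_modal_corr <= 1,
              "cross_modal_corr must lie in [0, 1]")
  missing_el <- setdiff(selected_electrodes(), toupper(eeg_channels))
  assert_that(length(missing_el) == 0,
              paste("eeg_channels must contain the selected electrodes;",
                    "missing:", paste(missing_el, collapse = ", ")))
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_subject = as.integer(trials_per_subject),
                 trial_seconds = trial_seconds, eeg_fs = eeg_fs,
                 eeg_channels = eeg_channels, fps = fps,
                 frame_size = as.integer(frame_size),
                 class_probs = unname(class_probs),
                 effect_size = effect_size,
                 cross_modal_corr = cross_modal_corr,
                 noise_sd = noise_sd,
                 duplicate_run_length = as.integer(duplicate_run_length),
                 complementary_noise = isTRUE(complementary_noise),
                 label_policy = label_policy,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Map SAM ratings to a discrete emotion label
#'
#' Ratings at or above 5 map to `happy`, at or below 4 to `sad`, and strictly
#' between 4 and 5 to `neutral`.  The deciding rating is either the mean of
#' valence and arousal (default) or valence alone.
#'
#' @param valence,arousal SAM ratings on the 1-9 scale.
#' @param policy `"mean"` or `"valence"`.
#' @return One of `"happy"`, `"neutral"`, `"sad"` (vectorised).
#' @export
label_from_ratings <- function(valence, arousal,
                               policy = c("mean", "valence")) {
  policy <- match.arg(policy)
  assert_that(all(valence >= 1 & valence <= 9) &&
                all(arousal >= 1 & arousal <= 9),
              "ratings must lie in [1, 9]", "emofuse_range")
  r <- if (policy == "mean") (valence + arousal) / 2 else valence
  ifelse(r >= 5, "happy", ifelse(r <= 4, "sad", "neutral"))
}

# Draw (valence, arousal) whose label reproduces `cls` under both policies.
draw_ratings <- function(cls) {
  base <- switch(cls,
    happy   = runif(1, 5.5, 8.5),
    sad     = runif(1, 1.5, 3.8),
    neutral = runif(1, 4.25, 4.75)
  )
  jit <- runif(1, -0.2, 0.2)
  valence <- min(9, max(1, base + jit))
  arousal <- min(9, max(1, 2 * base - valence))
  c(valence = valence, arousal = arousal)
}

# Pink-ish 1/f background: AR(1)-filtered white noise, unit-variance scaled.
pink_noise <- function(n, sd = 1) {
  x <- as.numeric(stats::filter(rnorm(n), 0.9, method = "recursive"))
  x / sd(x) * sd
}

# Class-dependent oscillation amplitude profiles over (theta, alpha, beta).
class_band_profile <- function(cls) {
  switch(cls,
    happy   = c(0.2, 0.4, 1.0),
    neutral = c(0.4, 1.0, 0.4),
    sad     = c(1.0, 0.4, 0.2)
  )
}

synth_eeg_trial <- function(cfg, cls, subject_offset, gain) {
  n <- round(cfg$trial_seconds * cfg$eeg_fs)
  tt <- seq_len(n) / cfg$eeg_fs
  chans <- cfg$eeg_channels
  sel <- toupper(chans) %in% selected_electrodes()
  X <- matrix(0, length(chans), n)
  freqs <- c(6, 10, 22)                       # theta / alpha / beta, Hz (4-45)
  amp <- 1 + cfg$effect_size * class_band_profile(cls) * gain
  for (ci in seq_along(chans)) {
    bg <- pink_noise(n, sd = cfg$noise_sd) + subject_offset
    if (sel[ci]) {
      ph <- runif(3, 0, 2 * pi)
      osc <- amp[1] * sin(2 * pi * freqs[1] * tt + ph[1]) +
             amp[2] * sin(2 * pi * freqs[2] * tt + ph[2]) +
             amp[3] * sin(2 * pi * freqs[3] * tt + ph[3])
      X[ci, ] <- osc + bg
    } else {
      X[ci, ] <- bg
    }
  }
  eeg_recording(chans, cfg$eeg_fs, X)
}

# Gaussian blob on a square canvas; the blob's position/intensity dynamics
# carry the class signal.
blob_frame <- function(size, cx, cy, intensity, width, noise_sd) {
  gx <- seq_len(size)
  g <- exp(-outer((gx - cx)^2, (gx - cy)^2, `+`) / (2 * width^2))
  f <- 0.3 + intensity * g + rnorm(size * size, 0, noise_sd)
  matrix(pmin(pmax(f, 0), 1), size, size)
}

synth_video_trial <- function(cfg, cls, gain) {
  n_frames <- round(cfg$trial_seconds * cfg$fps)
  size <- cfg$frame_size
  # class-dependent appearance dynamics: oscillation speed and intensity
  speed <- switch(cls, happy = 1.2, neutral = 0.5, sad = 0.15)
  base_int <- 0.25 + 0.15 * cfg$effect_size *
    switch(cls, happy = 1, neutral = 0.5, sad = 0) * gain
  tt <- seq_len(n_frames) / cfg$fps
  cx <- size / 2 + size / 6 * sin(2 * pi * speed * tt)
  cy <- size / 2 + size / 6 * cos(2 * pi * speed * tt)
  frames <- vector("list", n_frames)
  i <- 1L
  while (i <= n_frames) {
    frames[[i]] <- blob_frame(size, cx[i], cy[i], base_int, size / 5,
                              cfg$noise_sd * 0.02)
    if (cfg$duplicate_run_length > 0L && runif(1) < 0.1 && i < n_frames) {
      run <- min(cfg$duplicate_run_length, n_frames - i)
      for (j in seq_len(run)) {
        # near-duplicate: same appearance plus low-amplitude sensor noise
        frames[[i + j]] <- pmin(pmax(frames[[i]] +
          rnorm(size * size, 0, 0.002), 0), 1)
      }
      i <- i + run + 1L
    } else {
      i <- i + 1L
    }
  }
  frame_sequence(frames, cfg$fps)
}

#' Generate a synthetic paired bimodal dataset
#'
#' Draws one latent class per trial from `class_probs`; the class sets the
#' EEG oscillation amplitude profile on the selected frontal/temporal
#' channels and the appearance dynamics of the facial canvas, with
#' `cross_modal_corr` controlling how much of the trial-level signal
#' modulation is shared between the modalities.  SAM ratings are drawn so
#' that [label_from_ratings()] reproduces the latent class.
#'
#' @param config A [synthetic_config()].
#' @return A list of trials; each trial is a list with `subject_id`,
#'   `trial_id`, `eeg` ([eeg_recording()]), `video` ([frame_sequence()]),
#'   `valence_rating`, `arousal_rating`, and `label`.
#' @export
generate_dataset <- function(config) {
  assert_that(inherits(config, "synthetic_config"),
              "config must come from synthetic_config()")
  with_seed(config$seed, {
    trials <- vector("list", config$n_subjects * config$trials_per_subject)
    k <- 0L
    for (s in seq_len(config$n_subjects)) {
      subject_offset <- rnorm(1, 0, 0.3)
      for (t in seq_len(config$trials_per_subject)) {
        cls <- sample(emotion_levels(), 1, prob = config$class_probs)
        # trial-level modulation: shared latent vs modality-private parts
        g <- rnorm(1, 0, 0.15)
        rho <- config$cross_modal_corr
        g_eeg <- 1 + sqrt(rho) * g + sqrt(1 - rho) * rnorm(1, 0, 0.15)
        g_vid <- 1 + sqrt(rho) * g + sqrt(1 - rho) * rnorm(1, 0, 0.15)
        if (config$complementary_noise) {
          if (runif(1) < 0.5) g_eeg <- 0.25 * g_eeg else g_vid <- 0.25 * g_vid
        }
        ratings <- draw_ratings(cls)
        k <- k + 1L
        trials[[k]] <- list(
          subject_id = s, trial_id = t,
          eeg = synth_eeg_trial(config, cls, subject_offset, g_eeg),
          video = synth_video_trial(config, cls, g_vid),
          valence_rating = unname(ratings["valence"]),
          arousal_rating = unname(ratings["arousal"]),
          label = cls
        )
      }
    }
    trials
  })
}

#' Manifest table of a trial list
#'
#' @param trials Output of [generate_dataset()].
#' @return A tibble with one row per trial: subject, trial, ratings, label.
#' @export
dataset_manifest <- function(trials) {
  tibble::tibble(
    subject_id = vapply(trials, `[[`, 0, "subject_id"),
    trial_id = vapply(trials, `[[`, 0, "trial_id"),
    valence = vapply(trials, `[[`, 0, "valence_rating"),
    arousal = vapply(trials, `[[`, 0, "arousal_rating"),
    label = vapply(trials, `[[`, "", "label")
  )
}

#' Generate paired feature matrices with known canonical correlations
#'
#' Gaussian construction with `k` shared latent variables so the population
#' canonical correlations between the two blocks equal `rho`; each block is
#' then mixed by a random invertible matrix (canonical correlations are
#' invariant to invertible linear maps, so the population spectrum is
#' preserved while the construction stays non-trivial).
#'
#' @param n Number of paired rows.
#' @param d1,d2 Feature dimensions of the two blocks.
#' @param k Number of correlated directions, `k <= min(d1, d2)`.
#' @param rho Strictly decreasing vector of `k` target canonical
#'   correlations in `[0, 1)`.
#' @param seed Integer seed.
#' @return List with matrices `I1` (`n x d1`) and `I2` (`n x d2`).
#' @export
generate_correlated_pairs <- function(n, d1, d2, k, rho, seed = 1L) {
  assert_that(k <= min(d1, d2), "k must not exceed min(d1, d2)",
              "emofuse_range")
  assert_that(length(rho) == k, "rho must have length k", "emofuse_range")
  assert_that(all(rho >= 0 & rho < 1), "rho values must lie in [0, 1)",
              "emofuse_range")
  assert_that(k < 2 || all(diff(rho) < 0), "rho must be strictly decreasing",
              "emofuse_range")
  with_seed(seed, {
    Z <- matrix(rnorm(n * k), n, k)
    a <- sqrt(rho)
    X <- matrix(rnorm(n * d1), n, d1)
    Y <- matrix(rnorm(n * d2), n, d2)
    X[, seq_len(k)] <- sweep(Z, 2, a, `*`) +
      sweep(matrix(rnorm(n * k), n, k), 2, sqrt(1 - rho), `*`)
    Y[, seq_len(k)] <- sweep(Z, 2, a, `*`) +
      sweep(matrix(rnorm(n * k), n, k), 2, sqrt(1 - rho), `*`)
    # random well-conditioned mixing (invertible by construction)
    A1 <- diag(d1) + 0.3 * matrix(rnorm(d1 * d1, 0, 1 / sqrt(d1)), d1)
    A2 <- diag(d2) + 0.3 * matrix(rnorm(d2 * d2, 0, 1 / sqrt(d2)), d2)
    list(I1 = X %*% A1, I2 = Y %*% A2)
  })
}
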