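# Readers and writers for the on-disk dataset layout: a CSV manifest, EEG
# arrays as CSV with a JSON sidecar carrying channel names and sampling
# rate, and frames as PNG directories.  The array format is the canonical
# interchange format of this package; EDF/BDF containers are not parsed
# (no reader is bundled) and are rejected with a clear error.

#' Write an EEG recording to an array file with a JSON sidecar
#'
#' @param rec An [eeg_recording()].
#' @param path Output path (`.csv`); a `.json` sidecar with `channel_names`
#'   and `fs` is written next to it.
#' @return `path`, invisibly.
#' @export
write_eeg <- function(rec, path) {
  assert_that(inherits(rec, "eeg_recording"), "rec must be an eeg_recording")
  utils::write.table(rec$data, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(channel_names = rec$channel_names, fs = rec$fs),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an EEG recording
#'
#' @param path Path to the recording.
#' @param format `"array"` (CSV + JSON sidecar, the canonical format) or
#'   `"edf"`/`"bdf"` (not supported by this build; a clear error is
#'   raised).
#' @return An [eeg_recording()].
#' @export
read_eeg <- function(path, format = c("array", "edf", "bdf")) {
  format <- match.arg(format)
  if (format != "array") {
    stop_emofuse(paste0(format, " containers are not supported by this ",
                        "build; convert to the array format (CSV + JSON ",
                        "sidecar) documented in ?write_eeg"),
                 "emofuse_format")
  }
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop_emofuse(paste("missing JSON sidecar with channel_names and fs:",
                       sidecar), "emofuse_format")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  assert_that(!is.null(meta$channel_names) && !is.null(meta$fs),
              "sidecar must carry channel_names and fs", "emofuse_format")
  data <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(data) <- NULL
  eeg_recording(meta$channel_names, meta$fs, data)
}

#' Write a frame sequence as a PNG directory
#'
#' Frames are written as zero-padded `frame_000001.png` files plus a
#' `frames.json` sidecar with the fps.  Pixel values are clamped to
#' `[0, 1]`.
#'
#' @param seq A [frame_sequence()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_frames <- function(seq, dir) {
  assert_that(inherits(seq, "frame_sequence"), "seq must be a frame_sequence")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(seq$frames)) {
    png::writePNG(pmin(pmax(seq$frames[[i]], 0), 1),
                  file.path(dir, sprintf("frame_%06d.png", i)))
  }
  jsonlite::write_json(list(fps = seq$fps, n_frames = length(seq$frames)),
                       file.path(dir, "frames.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a frame sequence from a PNG directory
#'
#' @param dir Directory of `frame_*.png` files.
#' @param fps Frames per second; defaults to the `frames.json` sidecar.
#' @return A [frame_sequence()].
#' @export
read_frames <- function(dir, fps = NULL) {
  files <- sort(list.files(dir, pattern = "^frame_.*\\.png$",
                           full.names = TRUE))
  assert_that(length(files) >= 1, paste("no frames found in", dir),
              "emofuse_format")
  if (is.null(fps)) {
    sidecar <- file.path(dir, "frames.json")
    assert_that(file.exists(sidecar),
                "fps not given and no frames.json sidecar present",
                "emofuse_format")
    fps <- jsonlite::read_json(sidecar)$fps
  }
  frames <- lapply(files, png::readPNG)
  d1 <- dim(frames[[1]])
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]), d1)) {
      stop_emofuse(paste("frame size differs from the first frame:",
                         files[i]), "emofuse_shape")
    }
  }
  frame_sequence(frames, fps)
}

#' Write a generated dataset to a directory layout
#'
#' Produces `manifest.csv` (subject, trial, ratings, label, paths), one EEG
#' array per trial under `eeg/`, and one PNG frame directory per trial
#' under `frames/`.
#'
#' @param trials Trial list from [generate_dataset()].
#' @param dir Output directory.
#' @return The manifest tibble, invisibly.
#' @export
write_dataset <- function(trials, dir) {
  dir.create(file.path(dir, "eeg"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "frames"), recursive = TRUE,
             showWarnings = FALSE)
  man <- dataset_manifest(trials)
  man$eeg_path <- sprintf("eeg/s%02d_t%03d.csv", man$subject_id,
                          man$trial_id)
  man$video_path <- sprintf("frames/s%02d_t%03d", man$subject_id,
                            man$trial_id)
  for (i in seq_along(trials)) {
    write_eeg(trials[[i]]$eeg, file.path(dir, man$eeg_path[i]))
    write_frames(trials[[i]]$video, file.path(dir, man$video_path[i]))
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Dataset directory containing `manifest.csv`.
#' @return A trial list in the [generate_dataset()] shape.
#' @export
read_dataset <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  assert_that(file.exists(man_path), paste("no manifest.csv under", dir),
              "emofuse_format")
  man <- utils::read.csv(man_path)
  assert_that(!anyDuplicated(man[c("subject_id", "trial_id")]),
              "duplicate (subject, trial) pairs in the manifest",
              "emofuse_format")
  assert_that(all(man$valence >= 1 & man$valence <= 9) &&
                all(man$arousal >= 1 & man$arousal <= 9),
              "manifest ratings must lie in [1, 9]", "emofuse_range")
  lapply(seq_len(nrow(man)), function(i) {
    list(subject_id = man$subject_id[i], trial_id = man$trial_id[i],
         eeg = read_eeg(file.path(dir, man$eeg_path[i])),
         video = read_frames(file.path(dir, man$video_path[i])),
         valence_rating = man$valence[i], arousal_rating = man$arousal[i],
         label = man$label[i])
  })
}

# Allowed keys of the run-configuration file and their defaults.
config_defaults <- function() {
  list(window_seconds = 5, band_low = 4, band_high = 45,
       channels = selected_electrodes(), keep_fraction = 0.40,
       video_input_size = 24, video_backbone = "tiny",
       train_frames_per_window = 6, dcca_arch = "linear", dcca_dim = 8,
       alpha = 0.5, beta = 0.5, dcca_r = 1e-5,
       methods = c("eeg", "video", "dcca", "concat", "max", "choquet",
                   "adaptive"),
       learning_rate = 0.001, max_epochs = 40, batch_size = 32,
       early_stop_patience = 15, seed = 1)
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON file, fills every omitted key with the method's
#' published defaults (4-45 Hz band, ten electrodes, 5-s windows, 40%
#' retention, equal fusion weights, learning rate 0.001, batch 32, 40
#' epochs, patience 15), closes `alpha + beta = 1` when only one weight is
#' given, and rejects unknown keys.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` configuration file.
#' @return Named list of resolved settings.
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  raw <- raw %||% list()
  defaults <- config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  assert_that(length(unknown) == 0,
              paste("unknown configuration key(s):",
                    paste(unknown, collapse = ", ")), "emofuse_config")
  if (!is.null(raw$alpha) && is.null(raw$beta)) raw$beta <- 1 - raw$alpha
  if (!is.null(raw$beta) && is.null(raw$alpha)) raw$alpha <- 1 - raw$beta
  cfg <- utils::modifyList(defaults, raw)
  assert_that(cfg$keep_fraction > 0 && cfg$keep_fraction <= 1,
              "keep_fraction must lie in (0, 1]", "emofuse_config")
  assert_that(cfg$band_low > 0 && cfg$band_high > cfg$band_low,
              "band edges must satisfy 0 < low < high", "emofuse_config")
  assert_that(abs(cfg$alpha + cfg$beta - 1) < 1e-9 &&
                cfg$alpha >= 0 && cfg$beta >= 0,
              "alpha and beta must be non-negative and sum to 1",
              "emofuse_config")
  cfg
}

# Resolve a loaded flat config into the pipeline_config shape.
as_pipeline_config <- function(cfg) {
  shared <- train_config(learning_rate = cfg$learning_rate,
                         max_epochs = cfg$max_epochs,
                         batch_size = cfg$batch_size,
                         early_stop_patience = cfg$early_stop_patience)
  pipeline_config(window_seconds = cfg$window_seconds,
                  band = c(cfg$band_low, cfg$band_high),
                  channels = cfg$channels,
                  keep_fraction = cfg$keep_fraction,
                  video_input_size = cfg$video_input_size,
                  video_backbone = cfg$video_backbone,
                  train_frames_per_window = cfg$train_frames_per_window,
                  dcca_arch = cfg$dcca_arch, dcca_dim = cfg$dcca_dim,
                  alpha = cfg$alpha, beta = cfg$beta, dcca_r = cfg$dcca_r,
                  methods = cfg$methods,
                  eeg_cfg = shared, video_cfg = shared, dcca_cfg = shared,
                  classifier_cfg = shared)
}
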