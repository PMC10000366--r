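# EEG containers and conditioning: band-pass filtering, frontal/temporal
# electrode selection, and non-overlapping 5-s windowing for augmentation.

#' EEG recording container
#'
#' @param channel_names Ordered channel names.
#' @param fs Sampling rate, Hz.
#' @param data Channels x samples numeric matrix (microvolt scale assumed).
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(channel_names, fs, data) {
  data <- as.matrix(data)
  assert_that(fs > 0, "fs must be positive")
  assert_that(length(channel_names) == nrow(data),
              "channel_names must match the matrix's channel dimension")
  assert_that(ncol(data) > 0, "recording must contain samples")
  structure(list(channel_names = as.character(channel_names), fs = fs,
                 data = data),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Zero-phase band-pass filter
#'
#' Butterworth design applied forward and backward (`signal::filtfilt`), so
#' the pass band is phase-neutral and no latency skew is introduced between
#' the EEG and video modalities.  The default band 4-45 Hz suppresses both
#' slow ocular drift and utility-frequency artifacts.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Band edges in Hz; requires `0 < low < high < fs/2`.
#' @param order Butterworth order per band edge.
#' @return A filtered [eeg_recording()].
#' @export
eeg_bandpass <- function(rec, low = 4, high = 45, order = 5) {
  assert_that(inherits(rec, "eeg_recording"), "rec must be an eeg_recording")
  assert_that(low > 0 && high > low, "need 0 < low < high")
  assert_that(high < rec$fs / 2, "high edge must be below the Nyquist rate",
              "emofuse_range")
  bf <- signal::butter(order, c(low, high) / (rec$fs / 2), type = "pass")
  out <- t(apply(rec$data, 1, function(ch) signal::filtfilt(bf, ch)))
  eeg_recording(rec$channel_names, rec$fs, out)
}

#' Select and reorder EEG channels
#'
#' Keeps the requested channels in the requested order (case-insensitive
#' name match); defaults to the ten frontal/temporal electrodes of
#' [selected_electrodes()].
#'
#' @param rec An [eeg_recording()].
#' @param wanted Channel names to keep, in output order.
#' @return An [eeg_recording()] restricted to `wanted`.
#' @export
select_channels <- function(rec, wanted = selected_electrodes()) {
  assert_that(inherits(rec, "eeg_recording"), "rec must be an eeg_recording")
  pos <- match(toupper(wanted), toupper(rec$channel_names))
  if (anyNA(pos)) {
    stop_emofuse(paste("channels not present in the montage:",
                       paste(wanted[is.na(pos)], collapse = ", ")),
                 "emofuse_missing_channel")
  }
  eeg_recording(rec$channel_names[pos], rec$fs,
                rec$data[pos, , drop = FALSE])
}

#' Segment a recording into fixed windows
#'
#' Cuts the recording into non-overlapping consecutive windows of
#' `window_seconds` (default 5 s, so a 60-s trial yields 12 windows); a
#' trailing remainder shorter than one window is dropped.
#'
#' @param rec An [eeg_recording()].
#' @param window_seconds Window length in seconds.
#' @return List of `eeg_segment` objects, each holding a channels x
#'   `window_seconds * fs` matrix and its window index.
#' @export
segment_eeg <- function(rec, window_seconds = 5) {
  assert_that(inherits(rec, "eeg_recording"), "rec must be an eeg_recording")
  win <- round(window_seconds * rec$fs)
  n <- ncol(rec$data)
  assert_that(win <= n, "window longer than the recording", "emofuse_range")
  n_win <- n %/% win
  lapply(seq_len(n_win), function(w) {
    structure(list(window = w,
                   fs = rec$fs,
                   channel_names = rec$channel_names,
                   data = rec$data[, ((w - 1) * win + 1):(w * win),
                                   drop = FALSE]),
              class = "eeg_segment")
  })
}

# Flatten segments to the model input layout: array (len, B, 1), channel-major
# (channel 1's samples, then channel 2's, ...).
segments_to_input <- function(segments) {
  mats <- lapply(segments, function(s) as.vector(t(s$data)))
  len <- length(mats[[1]])
  array(unlist(mats), dim = c(len, length(mats), 1L))
}
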