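# Redundant-frame elimination by frame differencing, and frame conditioning
# (centered square crop, brightness rescale, square resize).

#' Frame sequence container
#'
#' @param frames List of numeric frame arrays, all of identical dimensions:
#'   `M x N` grayscale or `M x N x 3` colour, values on any common scale.
#' @param fps Frames per second.
#' @param trial_ref Optional identifier carried through processing.
#' @return A `frame_sequence` object.
#' @export
frame_sequence <- function(frames, fps, trial_ref = NULL) {
  assert_that(length(frames) >= 1, "frame list is empty")
  assert_that(fps > 0, "fps must be positive")
  d1 <- dim(frames[[1]]) %||% length(frames[[1]])
  ok <- vapply(frames, function(f) identical(dim(f) %||% length(f), d1),
               logical(1))
  if (!all(ok)) {
    stop_emofuse(paste("frames differ in shape at positions:",
                       paste(utils::head(which(!ok), 5), collapse = ", ")),
                 "emofuse_shape")
  }
  structure(list(frames = frames, fps = fps, trial_ref = trial_ref,
                 source_index = seq_along(frames)),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_sequence> %d frames of %s @ %g fps (%.1f s)\n",
              length(x$frames), paste(d, collapse = "x"), x$fps,
              length(x$frames) / x$fps))
  invisible(x)
}

# Collapse a colour frame to grayscale by averaging channels.
to_gray <- function(f) {
  if (length(dim(f)) == 3L) (f[, , 1] + f[, , 2] + f[, , 3]) / 3 else f
}

#' Mean absolute difference between consecutive frames
#'
#' For `T` frames, computes the `T - 1` difference frames (element-wise
#' absolute difference of consecutive frames, averaged over colour channels)
#' and the mean pixel value `m_t` of each: the difference frame is zero
#' wherever the two frames match, so `m_t = 0` exactly when frame `t + 1`
#' duplicates frame `t`, and large `m_t` marks frames that introduce new
#' appearance information.
#'
#' @param seq A [frame_sequence()] with at least 2 frames.
#' @return A tibble with columns `index` (the difference frame `t`, scored
#'   between source frames `t` and `t + 1`) and `m` (its mean).
#' @export
difference_scores <- function(seq) {
  assert_that(inherits(seq, "frame_sequence"), "seq must be a frame_sequence")
  n <- length(seq$frames)
  assert_that(n >= 2, "need at least 2 frames for differencing",
              "emofuse_range")
  m <- numeric(n - 1)
  prev <- to_gray(seq$frames[[1]])
  for (t in seq_len(n - 1)) {
    cur <- to_gray(seq$frames[[t + 1]])
    m[t] <- mean(abs(cur - prev))
    prev <- cur
  }
  tibble::tibble(index = seq_len(n - 1), m = m)
}

#' Keep the most informative frames in each second
#'
#' Frames are grouped into consecutive non-overlapping 1-second blocks
#' anchored at the first frame.  Within each block the difference scores
#' `m_t` are ranked in descending order (ties broken by earlier index) and
#' the frames adjacent to the top `ceiling(keep_fraction * fps)` scores are
#' retained in temporal order; a trailing partial block keeps
#' `ceiling(keep_fraction * length)` frames.  At the default 40% retention a
#' 60-fps second keeps 24 frames.
#'
#' @param seq A [frame_sequence()] spanning at least one block.
#' @param keep_fraction Fraction of frames retained per second, in `(0, 1]`.
#' @param retain Which neighbour of a selected difference frame to keep:
#'   `"later"` (default; the frame that introduced the change) or
#'   `"earlier"`.
#' @return A [frame_sequence()] of the retained frames, with
#'   `$source_index` mapping back to positions in the input and a
#'   `$selection_log` tibble (block, score, kept flag).
#' @export
select_frames <- function(seq, keep_fraction = 0.40,
                          retain = c("later", "earlier")) {
  retain <- match.arg(retain)
  assert_that(inherits(seq, "frame_sequence"), "seq must be a frame_sequence")
  assert_that(keep_fraction > 0 && keep_fraction <= 1,
              "keep_fraction must lie in (0, 1]", "emofuse_range")
  n <- length(seq$frames)
  fps <- seq$fps
  scores <- difference_scores(seq)
  block_of <- ceiling(seq_len(n) / fps)           # per-frame block id
  keep_idx <- integer(0)
  log_rows <- list()
  for (b in unique(block_of)) {
    frames_b <- which(block_of == b)
    k <- ceiling(keep_fraction * length(frames_b))
    # scores whose retained neighbour falls inside this block
    cand_t <- if (retain == "later") frames_b[frames_b >= 2] - 1L
              else frames_b[frames_b <= n - 1L]
    cand_t <- cand_t[cand_t >= 1L & cand_t <= n - 1L]
    if (length(cand_t) == 0L) {
      # degenerate first block of a 1-frame sequence slice: keep as-is
      keep_idx <- c(keep_idx, frames_b[seq_len(min(k, length(frames_b)))])
      next
    }
    ord <- cand_t[order(-scores$m[cand_t], cand_t)]  # desc m, ties earlier t
    top_t <- utils::head(ord, k)
    kept_frames <- sort(top_t + as.integer(retain == "later"))
    # first frame of the first block has no preceding difference frame when
    # retain = "later"; if the block came up short, backfill from the start
    if (length(kept_frames) < k) {
      extra <- setdiff(frames_b, kept_frames)
      kept_frames <- sort(c(kept_frames,
                            utils::head(extra, k - length(kept_frames))))
    }
    keep_idx <- c(keep_idx, kept_frames)
    log_rows[[b]] <- tibble::tibble(block = b, index = cand_t,
                                    m = scores$m[cand_t],
                                    kept = cand_t %in% top_t)
  }
  keep_idx <- sort(unique(keep_idx))
  out <- frame_sequence(seq$frames[keep_idx], fps, seq$trial_ref)
  out$source_index <- keep_idx
  out$selection_log <- dplyr::bind_rows(log_rows)
  out
}

# Bilinear resize of a grayscale matrix to size x size.
resize_bilinear <- function(img, size) {
  h <- nrow(img); w <- ncol(img)
  if (h == size && w == size) return(img)
  ys <- (seq_len(size) - 0.5) * h / size + 0.5
  xs <- (seq_len(size) - 0.5) * w / size + 0.5
  y0 <- pmin(pmax(floor(ys), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(xs), 1), w); x1 <- pmin(x0 + 1, w)
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  A <- img[y0, x0, drop = FALSE]; B <- img[y0, x1, drop = FALSE]
  C <- img[y1, x0, drop = FALSE]; D <- img[y1, x1, drop = FALSE]
  top <- A * outer(rep(1, size), 1 - wx) + B * outer(rep(1, size), wx)
  bot <- C * outer(rep(1, size), 1 - wx) + D * outer(rep(1, size), wx)
  top * outer(1 - wy, rep(1, size)) + bot * outer(wy, rep(1, size))
}

#' Condition a frame for the video backbone
#'
#' Crops (default: the centered largest square), optionally rescales the
#' mean intensity to `brightness_target`, and resizes to
#' `out_size x out_size` with bilinear interpolation.  Colour frames are
#' processed per channel.
#'
#' @param frame `M x N` or `M x N x 3` numeric array.
#' @param out_size Output side length in pixels (default 224).
#' @param crop_box Optional `c(row0, row1, col0, col1)` crop (inclusive).
#' @param brightness_target Optional target mean intensity.
#' @return Conditioned frame of shape `out_size x out_size` (x 3).
#' @export
condition_frame <- function(frame, out_size = 224, crop_box = NULL,
                            brightness_target = NULL) {
  d <- dim(frame)
  assert_that(!is.null(d) && all(d > 0), "frame must be a non-empty array")
  channels <- if (length(d) == 3L) d[3] else 1L
  one <- function(img) {
    if (!is.null(crop_box)) {
      assert_that(length(crop_box) == 4 &&
                    crop_box[1] >= 1 && crop_box[2] <= nrow(img) &&
                    crop_box[3] >= 1 && crop_box[4] <= ncol(img) &&
                    crop_box[1] < crop_box[2] && crop_box[3] < crop_box[4],
                  "degenerate crop_box", "emofuse_range")
      img <- img[crop_box[1]:crop_box[2], crop_box[3]:crop_box[4],
                 drop = FALSE]
    } else {
      s <- min(nrow(img), ncol(img))
      r0 <- (nrow(img) - s) %/% 2 + 1L
      c0 <- (ncol(img) - s) %/% 2 + 1L
      img <- img[r0:(r0 + s - 1L), c0:(c0 + s - 1L), drop = FALSE]
    }
    if (!is.null(brightness_target)) {
      mu <- mean(img)
      img <- if (mu > 0) img * (brightness_target / mu)
             else img + brightness_target
    }
    resize_bilinear(img, out_size)
  }
  if (channels == 1L) one(frame)
  else {
    out <- array(0, c(out_size, out_size, channels))
    for (c in seq_len(channels)) out[, , c] <- one(frame[, , c])
    out
  }
}

#' Condition every frame of a sequence
#'
#' @inheritParams condition_frame
#' @param seq A [frame_sequence()].
#' @return A [frame_sequence()] of conditioned frames.
#' @export
condition_frames <- function(seq, out_size = 224, crop_box = NULL,
                             brightness_target = NULL) {
  out <- frame_sequence(lapply(seq$frames, condition_frame,
                               out_size = out_size, crop_box = crop_box,
                               brightness_target = brightness_target),
                        seq$fps, seq$trial_ref)
  out$source_index <- seq$source_index
  out
}
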