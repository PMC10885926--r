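#' RGB video clip
#'
#' The raw unit of input: a `T x H x W x 3` array of pixel intensities in
#' `[0, 1]` (channels ordered R, G, B) together with its frame rate.
#'
#' @param frames Numeric array of dim `(T, H, W, 3)` with values in `[0, 1]`.
#' @param rate Frame rate in frames per second.
#' @return An object of class `video_clip`.
#' @export
video_clip <- function(frames, rate) {
  d <- dim(frames)
  if (length(d) != 4 || d[4] != 3) {
    stop_shape("`frames` must be a T x H x W x 3 array.")
  }
  if (d[1] < 2) {
    stop_insufficient_length("a clip needs at least 2 frames.")
  }
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop_invalid_parameter("`rate` must be a single positive number (fps).")
  }
  rng <- range(frames)
  if (!all(is.finite(rng)) || rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    stop_invalid_parameter("pixel intensities must be finite and in [0, 1].")
  }
  structure(list(frames = frames, rate = as.numeric(rate)), class = "video_clip")
}

#' @export
print.video_clip <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<video_clip> %d frames, %dx%d px, %g fps (%.2f s)\n",
    d[1], d[2], d[3], x$rate, d[1] / x$rate
  ))
  invisible(x)
}

n_frames <- function(clip) dim(clip$frames)[1]

#' Convert a clip to channel-first tensor layout
#'
#' Returns the `(3, T, H, W)` array layout the estimator operates on.
#' @param clip A [video_clip()].
#' @return Numeric array of dim `(3, T, H, W)`.
#' @export
clip_tensor <- function(clip) {
  aperm(clip$frames, c(4, 1, 2, 3))
}

#' Extract a sub-clip of consecutive frames
#' @param clip A [video_clip()].
#' @param start First frame (1-based).
#' @param len Number of frames.
#' @return A [video_clip()].
#' @export
clip_window <- function(clip, start, len) {
  tt <- n_frames(clip)
  if (start < 1 || start + len - 1 > tt) {
    stop_invalid_parameter(sprintf(
      "window [%d, %d] outside clip of %d frames.", start, start + len - 1, tt
    ))
  }
  video_clip(clip$frames[start:(start + len - 1), , , , drop = FALSE], clip$rate)
}

#' Spatial-mean intensity traces per color channel
#'
#' Averages each frame over pixels (optionally restricted to a logical mask),
#' giving one intensity trace per color channel — the classic starting point
#' of ratio-of-ratios pulse oximetry.
#'
#' @param clip A [video_clip()].
#' @param mask Optional `H x W` logical matrix selecting pixels.
#' @return A `T x 3` matrix with columns R, G, B.
#' @export
channel_means <- function(clip, mask = NULL) {
  d <- dim(clip$frames)
  out <- matrix(0, d[1], 3)
  for (c in 1:3) {
    ch <- clip$frames[, , , c, drop = FALSE]
    dim(ch) <- d[1:3]
    if (is.null(mask)) {
      dim(ch) <- c(d[1], d[2] * d[3])
      out[, c] <- rowMeans(ch)
    } else {
      dim(ch) <- c(d[1], d[2] * d[3])
      out[, c] <- rowMeans(ch[, as.vector(mask), drop = FALSE])
    }
  }
  colnames(out) <- c("R", "G", "B")
  out
}
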