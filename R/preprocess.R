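#' Detect the skin region of interest in each frame
#'
#' The detector is pluggable: `"skin"` thresholds skin-colored pixels
#' (red dominant over blue and green, the usual camera signature of bare
#' skin) and takes the largest connected component per frame; `"fixed"`
#' returns a user-supplied box verbatim for every frame, which is the
#' appropriate detector for synthetic scenes with known geometry. Heavier
#' learned detectors can be slotted in by passing a function that maps a
#' frame to a box.
#'
#' Boxes are 0-based, half-open `[x0, x1) x [y0, y1)` with `x` along frame
#' width and `y` along height.
#'
#' @param clip A [video_clip()].
#' @param region `"face"` or `"hand"`; informational (both use the same
#'   color heuristic).
#' @param detector `"skin"`, `"fixed"`, or a function `frame_array -> c(x0,
#'   y0, x1, y1)`.
#' @param box For the fixed detector: numeric of length 4 `(x0, y0, x1, y1)`.
#' @param per_frame If `FALSE`, detect once on the time-averaged frame and
#'   reuse the box (steadier but ignores motion); default `TRUE` as detection
#'   is per frame.
#' @return Integer matrix `T x 4` with columns `x0, y0, x1, y1`.
#' @export
detect_roi <- function(clip, region = c("face", "hand"),
                       detector = c("skin", "fixed"), box = NULL,
                       per_frame = TRUE) {
  region <- match.arg(region)
  tt <- n_frames(clip)
  if (is.function(detector)) {
    boxes <- t(vapply(seq_len(tt), function(t) {
      as.numeric(detector(clip$frames[t, , , ]))
    }, numeric(4)))
    colnames(boxes) <- c("x0", "y0", "x1", "y1")
    return(boxes)
  }
  detector <- match.arg(detector)
  if (detector == "fixed") {
    if (is.null(box) || length(box) != 4) {
      stop_invalid_parameter("the fixed detector needs `box = c(x0, y0, x1, y1)`.")
    }
    boxes <- matrix(as.integer(box), tt, 4, byrow = TRUE)
    colnames(boxes) <- c("x0", "y0", "x1", "y1")
    return(boxes)
  }
  d <- dim(clip$frames)
  one <- function(r, g, b, t_label) {
    mask <- (r - b > 0.1) & (r > g)
    if (!any(mask)) {
      stop_detection_failure(sprintf("no skin-colored region found (frame %s).", t_label))
    }
    lab <- label_components(mask)
    best <- which.max(tabulate(lab[lab > 0]))
    mask_bbox(lab == best)
  }
  if (!per_frame) {
    mr <- apply(clip$frames[, , , 1, drop = FALSE], c(2, 3), mean)
    mg <- apply(clip$frames[, , , 2, drop = FALSE], c(2, 3), mean)
    mb <- apply(clip$frames[, , , 3, drop = FALSE], c(2, 3), mean)
    bx <- one(mr, mg, mb, "mean")
    boxes <- matrix(as.integer(bx), tt, 4, byrow = TRUE)
  } else {
    boxes <- t(vapply(seq_len(tt), function(t) {
      as.integer(one(
        clip$frames[t, , , 1], clip$frames[t, , , 2], clip$frames[t, , , 3], t
      ))
    }, integer(4)))
  }
  colnames(boxes) <- c("x0", "y0", "x1", "y1")
  boxes
}

# 4-connected component labeling via two-pass union-find on a logical matrix.
label_components <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  lab <- matrix(0L, h, w)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  nxt <- 0L
  for (x in seq_len(w)) {
    for (y in seq_len(h)) {
      if (!mask[y, x]) next
      up <- if (y > 1) lab[y - 1, x] else 0L
      lf <- if (x > 1) lab[y, x - 1] else 0L
      if (up == 0L && lf == 0L) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[y, x] <- nxt
      } else if (up != 0L && lf != 0L) {
        ru <- find(up)
        rl <- find(lf)
        if (ru != rl) parent[max(ru, rl)] <- min(ru, rl)
        lab[y, x] <- min(ru, rl)
      } else {
        lab[y, x] <- max(up, lf)
      }
    }
  }
  if (nxt > 0L) {
    roots <- vapply(seq_len(nxt), find, integer(1))
    remap <- match(roots, sort(unique(roots)))
    pos <- lab > 0L
    lab[pos] <- remap[lab[pos]]
  }
  lab
}

bilinear_matrix <- function(n_in, n_out) {
  # half-pixel-centered sampling; exactly the identity when n_in == n_out
  src <- pmin(pmax(((seq_len(n_out) - 0.5) * n_in / n_out) - 0.5, 0), n_in - 1)
  i0 <- pmin(floor(src), n_in - 1)
  wt <- src - i0
  i1 <- pmin(i0 + 1, n_in - 1)
  m <- matrix(0, n_out, n_in)
  m[cbind(seq_len(n_out), i0 + 1)] <- 1 - wt
  m[cbind(seq_len(n_out), i1 + 1)] <- m[cbind(seq_len(n_out), i1 + 1)] + wt
  m
}

#' Crop per-frame boxes and rescale to the working resolution
#'
#' Crops every frame to its bounding box and bilinearly resamples the crop to
#' `out_size x out_size` (128 by default, the estimator's full-scale input),
#' so downstream stages always see a fixed spatial shape regardless of how
#' the detected region moved or changed size.
#'
#' @param clip A [video_clip()].
#' @param boxes `T x 4` matrix from [detect_roi()] (or a single length-4 box
#'   recycled over frames).
#' @param out_size Output height/width in pixels.
#' @return A [video_clip()] of dim `T x out_size x out_size x 3`.
#' @export
crop_resize <- function(clip, boxes, out_size = 128) {
  tt <- n_frames(clip)
  d <- dim(clip$frames)
  if (is.null(dim(boxes))) boxes <- matrix(boxes, tt, 4, byrow = TRUE)
  if (nrow(boxes) != tt) {
    stop_shape(sprintf("need one box per frame (%d boxes for %d frames).", nrow(boxes), tt))
  }
  if (out_size < 2) stop_invalid_parameter("`out_size` must be at least 2.")
  clipped <- FALSE
  out <- array(0, c(tt, out_size, out_size, 3))
  cache <- new.env(parent = emptyenv())
  for (t in seq_len(tt)) {
    b <- boxes[t, ]
    x0 <- max(0, b[1]); y0 <- max(0, b[2])
    x1 <- min(d[3], b[3]); y1 <- min(d[2], b[4])
    if (x0 != b[1] || y0 != b[2] || x1 != b[3] || y1 != b[4]) clipped <- TRUE
    if (x1 <= x0 || y1 <= y0) {
      stop_invalid_parameter(sprintf("box at frame %d has zero area.", t))
    }
    ch <- y1 - y0
    cw <- x1 - x0
    key <- paste0(ch, "x", cw)
    if (is.null(cache[[key]])) {
      cache[[key]] <- list(
        wy = bilinear_matrix(ch, out_size),
        wx = t(bilinear_matrix(cw, out_size))
      )
    }
    m <- cache[[key]]
    for (c in 1:3) {
      crop <- clip$frames[t, (y0 + 1):y1, (x0 + 1):x1, c]
      dim(crop) <- c(ch, cw)
      out[t, , , c] <- m$wy %*% crop %*% m$wx
    }
  }
  if (clipped) {
    rlang::warn("some boxes extended beyond the frame and were clipped.")
  }
  video_clip(out, clip$rate)
}

#' Split a clip into its four spatial quadrants
#'
#' Divides each frame along the horizontal and vertical center lines,
#' yielding the four sub-ROIs whose rPPG spectra the contrastive losses
#' compare (regions A--D for the hand, E--H for the face).
#'
#' @param clip A [video_clip()] with even height and width.
#' @return A named list of four [video_clip()]s in fixed order `tl`, `tr`,
#'   `bl`, `br` (top-left, top-right, bottom-left, bottom-right).
#' @export
split_quadrants <- function(clip) {
  d <- dim(clip$frames)
  if (d[2] %% 2 != 0 || d[3] %% 2 != 0) {
    stop_invalid_parameter("frame height and width must be even to split quadrants.")
  }
  h2 <- d[2] / 2
  w2 <- d[3] / 2
  sub <- function(ys, xs) video_clip(clip$frames[, ys, xs, , drop = FALSE], clip$rate)
  list(
    tl = sub(1:h2, 1:w2),
    tr = sub(1:h2, (w2 + 1):d[3]),
    bl = sub((h2 + 1):d[2], 1:w2),
    br = sub((h2 + 1):d[2], (w2 + 1):d[3])
  )
}

#' Align reference PPG and SpO2 labels to a clip
#'
#' Band-passes the reference PPG to the cardiac band, standardizes it,
#' resamples it to the clip's frame rate and truncates it to the clip length;
#' SpO2 labels are aggregated per analysis window as the mean of the
#' per-second readings the window spans.
#'
#' @param ppg Reference PPG [waveform()] covering the clip duration.
#' @param spo2 Per-second SpO2 values covering the clip duration.
#' @param clip The [video_clip()] the labels belong to.
#' @param band Cardiac band in Hz for the PPG filter.
#' @param window_frames Analysis window length in frames; defaults to the
#'   whole clip (one window).
#' @return A list with `ppg` (aligned [waveform()], length `T`, rate = fps)
#'   and `windows` (a [tibble::tibble()] with `window`, `start_frame`,
#'   `end_frame`, `spo2`).
#' @export
prepare_labels <- function(ppg, spo2, clip, band = c(0.5, 4),
                           window_frames = NULL) {
  tt <- n_frames(clip)
  rate <- clip$rate
  clip_dur <- tt / rate
  if (duration(ppg) < clip_dur - 1 / rate) {
    stop_alignment(sprintf(
      "reference PPG (%.2f s) does not cover the clip (%.2f s).",
      duration(ppg), clip_dur
    ))
  }
  if (length(spo2) < floor(clip_dur)) {
    stop_alignment("per-second SpO2 trace does not cover the clip duration.")
  }
  n <- length(ppg$samples)
  ord <- round(4 * ppg$rate / band[1])
  if (ord %% 2 == 0) ord <- ord + 1
  if (ord >= n) {
    ord <- n - 2 - (n %% 2)  # largest odd order below n
    if (ord < 15) stop_insufficient_length("reference PPG too short to filter.")
  }
  w <- bandpass_fir(ppg, band[1], band[2], order = ord)
  w <- normalize(w)
  w <- resample(w, rate)
  if (length(w$samples) < tt) {
    if (tt - length(w$samples) > 1) {
      stop_alignment("resampled PPG falls short of the clip length.")
    }
    w$samples <- c(w$samples, w$samples[length(w$samples)])
  }
  w <- waveform(w$samples[seq_len(tt)], rate)
  if (is.null(window_frames)) window_frames <- tt
  starts <- seq(1, tt - window_frames + 1, by = window_frames)
  lab <- vapply(starts, function(s) {
    s0 <- floor((s - 1) / rate) + 1
    s1 <- min(length(spo2), ceiling((s - 1 + window_frames) / rate))
    mean(spo2[s0:s1])
  }, numeric(1))
  list(
    ppg = w,
    windows = tibble::tibble(
      window = seq_along(starts),
      start_frame = as.integer(starts),
      end_frame = as.integer(starts + window_frames - 1),
      spo2 = lab
    )
  )
}

#' Write / read per-frame boxes as CSV (`frame, x0, y0, x1, y1`)
#' @param boxes `T x 4` box matrix.
#' @param path File path.
#' @return `write_boxes_csv()` returns `path` invisibly; `read_boxes_csv()`
#'   the box matrix.
#' @export
write_boxes_csv <- function(boxes, path) {
  df <- data.frame(frame = seq_len(nrow(boxes)) - 1L, boxes)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_boxes_csv
#' @export
read_boxes_csv <- function(path) {
  df <- utils::read.csv(path)
  as.matrix(df[, c("x0", "y0", "x1", "y1")])
}
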