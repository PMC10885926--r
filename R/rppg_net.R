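#' Configuration of the 3D-CNN rPPG estimator
#'
#' Describes the spatiotemporal convolutional backbone that maps a
#' `(3, T, S, S)` video block to a `6 x T` multi-channel pulse time series.
#' The layer sequence is fixed: per-clip standardization; a `1x5x5`
#' convolution; spatial average pooling; three stacks of two `3x3x3`
#' convolutions with temporal dilation 2 separated by average poolings (the
#' second of which halves the temporal axis); temporal linear interpolation
#' back to `T`; a `3x3x3` convolution; global spatial average pooling; and a
#' final `3x3x3` convolution producing 6 output channels. Every convolution
#' except the output one is followed by per-clip channel normalization and a
#' ReLU. Because all pooling after the first stage adapts to the input
#' extent, one set of weights serves full-resolution clips and the
#' smaller quadrant sub-ROIs alike.
#'
#' @param input_size Nominal square input resolution in pixels (a multiple
#'   of 8); at run time any even square input of at least 8 px is accepted,
#'   since the pooling chain adapts to the input extent.
#' @param width Channel width multiplier applied to the reference widths
#'   (32 after the first convolution, 64 thereafter). `width = 1` is the
#'   full-scale network; smaller values give CPU-friendly variants.
#' @param out_channels Number of output signal channels (6).
#' @return An object of class `rppg_config`.
#' @export
rppg_config <- function(input_size = 128, width = 1, out_channels = 6) {
  if (input_size %% 8 != 0 || input_size < 8) {
    stop_invalid_parameter("`input_size` must be a positive multiple of 8.")
  }
  if (width <= 0) stop_invalid_parameter("`width` must be positive.")
  structure(
    list(
      input_size = as.integer(input_size),
      width = width,
      out_channels = as.integer(out_channels),
      c1 = max(4L, as.integer(round(32 * width))),
      c2 = max(4L, as.integer(round(64 * width)))
    ),
    class = "rppg_config"
  )
}

rppg_layers <- function(cfg) {
  c1 <- cfg$c1
  c2 <- cfg$c2
  conv_block <- function(name, cin, cout, dil) {
    list(
      new_layer("conv", name = name, cin = cin, cout = cout, kt = 3L, kh = 3L,
                kw = 3L, dil = dil),
      new_layer("cnorm", name = paste0(name, "_n"), ch = cout),
      new_layer("relu")
    )
  }
  c(
    list(new_layer("standardize")),
    list(
      new_layer("conv", name = "conv1", cin = 3L, cout = c1, kt = 1L, kh = 5L,
                kw = 5L, dil = 1L),
      new_layer("cnorm", name = "conv1_n", ch = c1),
      new_layer("relu"),
      new_layer("pool", kernel = c(1L, 2L, 2L), stride = c(1L, 2L, 2L))
    ),
    conv_block("conv2a", c1, c2, 2L),
    conv_block("conv2b", c2, c2, 2L),
    list(new_layer("pool", kernel = c(2L, 2L, 2L), stride = c(2L, 2L, 2L))),
    conv_block("conv3a", c2, c2, 2L),
    conv_block("conv3b", c2, c2, 2L),
    list(new_layer("pool", kernel = c(2L, 2L, 2L), stride = c(1L, 2L, 2L))),
    conv_block("conv4a", c2, c2, 2L),
    conv_block("conv4b", c2, c2, 2L),
    list(new_layer("interp2")),
    conv_block("conv5", c2, c2, 1L),
    # global spatial average pooling (sentinel -1 = full extent)
    list(new_layer("pool", kernel = c(1L, -1L, -1L), stride = c(1L, 1L, 1L))),
    list(new_layer("conv", name = "conv6", cin = c2, cout = cfg$out_channels,
                   kt = 3L, kh = 3L, kw = 3L, dil = 1L))
  )
}

#' Build the rPPG estimator
#'
#' Instantiates the backbone described by [rppg_config()] with seeded He
#' initialization.
#'
#' @param cfg An [rppg_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `rppg_estimator` with elements `cfg`, `layers`,
#'   `params` and `n_params`.
#' @examples
#' est <- build_estimator(rppg_config(input_size = 32, width = 0.125), seed = 1)
#' est$n_params
#' @export
build_estimator <- function(cfg = rppg_config(), seed = 1) {
  if (!inherits(cfg, "rppg_config")) {
    stop_config("`cfg` must be an rppg_config object.")
  }
  layers <- rppg_layers(cfg)
  params <- with_seed(seed, {
    p <- list()
    for (ly in layers) {
      if (ly$type == "conv") {
        p <- c(p, init_conv_params(ly$name, ly$cin, ly$cout, ly$kt, ly$kh, ly$kw))
      } else if (ly$type == "cnorm") {
        p <- c(p, init_cnorm_params(ly$name, ly$ch))
      }
    }
    p
  })
  structure(
    list(cfg = cfg, layers = layers, params = params,
         n_params = sum(vapply(params, length, 1L))),
    class = "rppg_estimator"
  )
}

#' @export
print.rppg_estimator <- function(x, ...) {
  cat(sprintf(
    "<rppg_estimator> input %dx%d, width %g, %d output channels, %d parameters\n",
    x$cfg$input_size, x$cfg$input_size, x$cfg$width, x$cfg$out_channels,
    x$n_params
  ))
  invisible(x)
}

check_clip_tensor <- function(x) {
  d <- dim(x)
  if (length(d) != 4 || d[1] != 3) {
    stop_shape("input must have dim (3, T, H, W).")
  }
  if (d[3] != d[4] || d[3] %% 2 != 0 || d[3] < 8) {
    stop_shape(paste0(
      "spatial dims must be square, even and at least 8 px (got ", d[3], "x",
      d[4], "); use crop_resize() to bring the ROI to the working resolution."
    ))
  }
  if (d[2] %% 2 != 0 || d[2] < 4) {
    stop_shape("temporal length T must be even and at least 4.")
  }
  invisible(d)
}

#' Run the rPPG estimator on a clip
#'
#' @param est An estimator from [build_estimator()].
#' @param clip A [video_clip()] or a `(3, T, H, W)` array; `H == W`, even,
#'   at least 8 px, `T` even.
#' @return An object of class `rppg_signals`: a list with `signals`
#'   (`6 x T` matrix) and `rate` (fps; `NA` for bare arrays).
#' @export
rppg_forward <- function(est, clip) {
  rate <- NA_real_
  if (inherits(clip, "video_clip")) {
    rate <- clip$rate
    clip <- clip_tensor(clip)
  }
  check_clip_tensor(clip)
  out <- net_forward(est$layers, est$params, clip, keep = FALSE)$out
  sig <- out
  dim(sig) <- dim(out)[1:2]
  if (!all(is.finite(sig))) stop_degenerate_signal("non-finite estimator output.")
  structure(list(signals = sig, rate = rate), class = "rppg_signals")
}

#' @export
print.rppg_signals <- function(x, ...) {
  cat(sprintf(
    "<rppg_signals> %d channels x %d samples @ %s fps\n",
    nrow(x$signals), ncol(x$signals),
    if (is.na(x$rate)) "?" else format(x$rate)
  ))
  invisible(x)
}

#' Save / load model checkpoints
#'
#' Checkpoints embed the configuration alongside all parameter arrays so a
#' saved model can be rebuilt without the code that created it.
#'
#' @param model An `rppg_estimator` or `spo2cam_model`.
#' @param path File path (`.rds`).
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   the restored object.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_state(sprintf("checkpoint '%s' not found.", path))
  readRDS(path)
}
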