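# SpO2 estimation head: a CNN-BiLSTM over the 6-channel rPPG time series
# (deep feature M1), a manual-feature attention module over per-channel
# mean/variance statistics of the raw ROI clip (M2), and a structurally
# constrained fusion SpO2 = k1*M1 + k2*M2 with k1 + k2 = 100.

#' Per-channel manual features of an ROI clip
#'
#' The six handcrafted statistics feeding the manual-feature attention
#' module: the mean and the variance of each color channel over all pixels
#' and frames of the ROI clip. Pixel means track the DC component of the
#' skin reflection; variances track pulsatile (AC) energy plus noise.
#'
#' @param clip A [video_clip()].
#' @return Named numeric vector
#'   `(mean_red, mean_green, mean_blue, var_red, var_green, var_blue)`.
#' @export
manual_features <- function(clip) {
  d <- dim(clip$frames)
  out <- numeric(6)
  for (c in 1:3) {
    ch <- clip$frames[, , , c]
    m <- mean(ch)
    out[c] <- m
    out[3 + c] <- mean((ch - m)^2)
  }
  names(out) <- c(
    "mean_red", "mean_green", "mean_blue", "var_red", "var_green", "var_blue"
  )
  out
}

#' Per-channel AC/DC modulation traces of an ROI clip
#'
#' The classical pulse-oximetry observable, prepared as a time series for
#' the deep head: each frame's spatial-mean intensity per color channel,
#' expressed as percent modulation around its clip mean
#' (`100 * (x_c(t) / mean_c - 1)`). The relative amplitude of the red and
#' blue traces carries the ratio-of-ratios SpO2 information that per-channel
#' normalization inside the backbone deliberately discards.
#'
#' @param clip A [video_clip()].
#' @return A `3 x T` matrix (rows R, G, B) in percent-modulation units.
#' @export
clip_acdc_features <- function(clip) {
  tr <- channel_means(clip)
  t(100 * sweep(tr, 2, colMeans(tr), "/") - 100)
}

mfam_init <- function(seed = 1) {
  with_seed(seed, list(
    mfam.W = matrix(stats::rnorm(36, sd = sqrt(2 / 6)), 6, 6),
    mfam.b = numeric(6),
    # scalar affine calibration of the attention-weighted feature sum onto
    # the fractional SpO2 scale (raw pixel statistics live well below it);
    # initialized at the physiological midpoint with zero slope so the
    # branch starts on-scale and learns its feature dependence from there
    mfam.ws = 0,
    mfam.bs = 0.96
  ))
}

#' Manual-feature attention module
#'
#' Computes attention weights `a = softmax(relu(W %*% c + b))` over the six
#' manual features and returns the attention-weighted feature sum
#' `M2 = sum_i a_i * c_i`. The weights always sum to one, so `M2` is a
#' convex combination of the input features.
#'
#' @param c_w Numeric vector of 6 manual features (see [manual_features()]).
#' @param W A `6 x 6` weight matrix.
#' @param b Length-6 bias.
#' @return A list with `m2` (scalar) and `weights` (the 6 attention
#'   weights, summing to 1).
#' @export
mfam_forward <- function(c_w, W, b) {
  if (length(c_w) != 6) stop_shape("`c_w` must have 6 elements.")
  if (!all(is.finite(W)) || !all(is.finite(b))) {
    stop_invalid_parameter("MFAM parameters must be finite.")
  }
  z <- as.numeric(W %*% c_w + b)
  r <- pmax(z, 0)
  e <- exp(r - max(r))
  a <- e / sum(e)
  list(m2 = sum(a * c_w), weights = a)
}

# batched MFAM with output calibration: C is B x 6
mfam_forward_batch <- function(params, C, keep = FALSE) {
  Z <- C %*% t(params$mfam.W) + rep(params$mfam.b, each = nrow(C))
  R <- pmax(Z, 0)
  E <- exp(R - apply(R, 1, max))
  A <- E / rowSums(E)
  s <- rowSums(A * C)
  m2 <- params$mfam.ws * s + params$mfam.bs
  list(m2 = m2, cache = if (keep) list(Z = Z, A = A, C = C, s = s))
}

mfam_backward_batch <- function(params, cache, dm2) {
  ds <- dm2 * params$mfam.ws
  dA <- ds * cache$C
  dR <- cache$A * (dA - rowSums(dA * cache$A))
  dZ <- dR * (cache$Z > 0)
  list(
    mfam.W = t(dZ) %*% cache$C,
    mfam.b = colSums(dZ),
    mfam.ws = sum(dm2 * cache$s),
    mfam.bs = sum(dm2)
  )
}

#' Configuration of the CNN-BiLSTM deep head
#'
#' @param in_ch Input channels (6 rPPG channels plus 3 AC/DC modulation
#'   traces, see [clip_acdc_features()]).
#' @param conv_channels Channel widths of the 1-D convolution stack
#'   (kernel 5, ReLU); use `integer(0)` for no convolutions (the plain LSTM
#'   baseline head).
#' @param kernel Convolution kernel length.
#' @param hidden LSTM hidden size per direction.
#' @param bidirectional If `FALSE`, a unidirectional LSTM (baseline).
#' @return An object of class `head_config`.
#' @export
head_config <- function(in_ch = 9, conv_channels = c(32, 64), kernel = 5L,
                        hidden = 64, bidirectional = TRUE) {
  structure(
    list(in_ch = as.integer(in_ch), conv_channels = as.integer(conv_channels),
         kernel = as.integer(kernel), hidden = as.integer(hidden),
         bidirectional = isTRUE(bidirectional)),
    class = "head_config"
  )
}

head_init <- function(cfg, seed = 1) {
  with_seed(seed, {
    p <- list()
    cin <- cfg$in_ch
    for (j in seq_along(cfg$conv_channels)) {
      cout <- cfg$conv_channels[j]
      k <- cin * cfg$kernel
      p[[paste0("conv", j, ".W")]] <-
        matrix(stats::rnorm(cout * k, sd = sqrt(2 / k)), cout, k)
      p[[paste0("conv", j, ".b")]] <- numeric(cout)
      cin <- cout
    }
    h <- cfg$hidden
    r <- 1 / sqrt(h)
    dirs <- if (cfg$bidirectional) c("f", "b") else "f"
    for (d in dirs) {
      p[[paste0("lstm_", d, ".Wx")]] <- matrix(stats::runif(cin * 4 * h, -r, r), cin, 4 * h)
      p[[paste0("lstm_", d, ".Wh")]] <- matrix(stats::runif(h * 4 * h, -r, r), h, 4 * h)
      bb <- numeric(4 * h)
      bb[(h + 1):(2 * h)] <- 1  # forget-gate bias
      p[[paste0("lstm_", d, ".b")]] <- bb
    }
    p[["out.W"]] <- stats::rnorm(h * length(dirs), sd = r)
    # start the sigmoid readout at the physiological midpoint (~96% SpO2 on
    # the fractional scale) so early training never drives it into terminal
    # saturation chasing an out-of-range mean
    p[["out.b"]] <- stats::qlogis(0.96)
    p
  })
}

im2col1d <- function(X, k) {
  # X: cin x T -> (cin*k) x T, zero "same" padding; row order (dk outer)
  cin <- nrow(X)
  tt <- ncol(X)
  p <- (k - 1) %/% 2
  col <- matrix(0, cin * k, tt)
  for (j in seq_len(k)) {
    off <- j - 1 - p
    src <- intersect(seq_len(tt), seq_len(tt) + off)
    dst <- src - off
    col[((j - 1) * cin + 1):(j * cin), dst] <- X[, src]
  }
  col
}

col2im1d <- function(dcol, cin, k, tt) {
  p <- (k - 1) %/% 2
  dX <- matrix(0, cin, tt)
  for (j in seq_len(k)) {
    off <- j - 1 - p
    src <- intersect(seq_len(tt), seq_len(tt) + off)
    dst <- src - off
    dX[, src] <- dX[, src] + dcol[((j - 1) * cin + 1):(j * cin), dst]
  }
  dX
}

# forward the deep head over a list of (in_ch x T) matrices -> m1 in [0,1]
head_forward <- function(params, cfg, zlist, keep = FALSE) {
  B <- length(zlist)
  tt <- ncol(zlist[[1]])
  conv_caches <- if (keep) vector("list", B)
  d <- if (length(cfg$conv_channels)) {
    cfg$conv_channels[length(cfg$conv_channels)]
  } else {
    cfg$in_ch
  }
  X <- array(0, c(B, tt, d))
  for (w in seq_len(B)) {
    A <- zlist[[w]]
    cc <- list()
    for (j in seq_along(cfg$conv_channels)) {
      col <- im2col1d(A, cfg$kernel)
      Z <- params[[paste0("conv", j, ".W")]] %*% col + params[[paste0("conv", j, ".b")]]
      A <- Z * (Z > 0)
      if (keep) cc[[j]] <- list(col = col, mask = Z > 0)
    }
    if (keep) conv_caches[[w]] <- cc
    X[w, , ] <- t(A)
  }
  h <- cfg$hidden
  dirs <- if (cfg$bidirectional) c("f", "b") else "f"
  lstm_caches <- list()
  finals <- list()
  for (dname in dirs) {
    Wx <- params[[paste0("lstm_", dname, ".Wx")]]
    Wh <- params[[paste0("lstm_", dname, ".Wh")]]
    b <- params[[paste0("lstm_", dname, ".b")]]
    steps <- if (dname == "f") seq_len(tt) else rev(seq_len(tt))
    H <- matrix(0, B, h)
    Cc <- matrix(0, B, h)
    cache <- if (keep) vector("list", tt)
    for (s in seq_along(steps)) {
      t <- steps[s]
      Xt <- matrix(X[, t, ], B, d)
      G <- Xt %*% Wx + H %*% Wh + rep(b, each = B)
      ig <- stats::plogis(G[, 1:h, drop = FALSE])
      fg <- stats::plogis(G[, (h + 1):(2 * h), drop = FALSE])
      og <- stats::plogis(G[, (2 * h + 1):(3 * h), drop = FALSE])
      gg <- tanh(G[, (3 * h + 1):(4 * h), drop = FALSE])
      Cn <- fg * Cc + ig * gg
      tc <- tanh(Cn)
      Hn <- og * tc
      if (keep) {
        cache[[s]] <- list(Xt = Xt, Hp = H, Cp = Cc, i = ig, f = fg, o = og,
                           g = gg, C = Cn, tc = tc)
      }
      H <- Hn
      Cc <- Cn
    }
    lstm_caches[[dname]] <- cache
    finals[[dname]] <- H
  }
  U <- do.call(cbind, finals)
  s <- as.numeric(U %*% params$out.W) + params$out.b
  m1 <- stats::plogis(s)
  list(
    m1 = m1,
    cache = if (keep) {
      list(conv = conv_caches, lstm = lstm_caches, U = U, m1 = m1, X_dim = dim(X),
           d = d, tt = tt, dirs = dirs)
    }
  )
}

head_backward <- function(params, cfg, cache, dm1) {
  B <- length(dm1)
  h <- cfg$hidden
  d <- cache$d
  tt <- cache$tt
  ds <- dm1 * cache$m1 * (1 - cache$m1)
  grads <- list(
    out.W = as.numeric(t(cache$U) %*% ds),
    out.b = sum(ds)
  )
  dU <- outer(ds, params$out.W)
  dX <- array(0, cache$X_dim)
  for (di in seq_along(cache$dirs)) {
    dname <- cache$dirs[di]
    Wx <- params[[paste0("lstm_", dname, ".Wx")]]
    Wh <- params[[paste0("lstm_", dname, ".Wh")]]
    steps <- if (dname == "f") seq_len(tt) else rev(seq_len(tt))
    dWx <- Wx * 0
    dWh <- Wh * 0
    db <- numeric(4 * h)
    dH <- dU[, ((di - 1) * h + 1):(di * h), drop = FALSE]
    dC <- matrix(0, B, h)
    for (s in rev(seq_along(steps))) {
      cc <- cache$lstm[[dname]][[s]]
      do_ <- dH * cc$tc
      dC <- dC + dH * cc$o * (1 - cc$tc^2)
      di_ <- dC * cc$g
      dg_ <- dC * cc$i
      df_ <- dC * cc$Cp
      dCp <- dC * cc$f
      dA <- cbind(
        di_ * cc$i * (1 - cc$i),
        df_ * cc$f * (1 - cc$f),
        do_ * cc$o * (1 - cc$o),
        dg_ * (1 - cc$g^2)
      )
      t <- steps[s]
      dX[, t, ] <- dX[, t, ] + dA %*% t(Wx)
      dWx <- dWx + t(cc$Xt) %*% dA
      dWh <- dWh + t(cc$Hp) %*% dA
      db <- db + colSums(dA)
      dH <- dA %*% t(Wh)
      dC <- dCp
    }
    grads[[paste0("lstm_", dname, ".Wx")]] <- dWx
    grads[[paste0("lstm_", dname, ".Wh")]] <- dWh
    grads[[paste0("lstm_", dname, ".b")]] <- db
  }
  nc <- length(cfg$conv_channels)
  if (nc > 0) {
    for (j in seq_len(nc)) {
      grads[[paste0("conv", j, ".W")]] <- params[[paste0("conv", j, ".W")]] * 0
      grads[[paste0("conv", j, ".b")]] <- numeric(length(params[[paste0("conv", j, ".b")]]))
    }
    for (w in seq_len(B)) {
      dA <- t(matrix(dX[w, , ], tt, d))
      for (j in rev(seq_len(nc))) {
        cc <- cache$conv[[w]][[j]]
        dZ <- dA * cc$mask
        grads[[paste0("conv", j, ".W")]] <-
          grads[[paste0("conv", j, ".W")]] + dZ %*% t(cc$col)
        grads[[paste0("conv", j, ".b")]] <-
          grads[[paste0("conv", j, ".b")]] + rowSums(dZ)
        if (j > 1) {
          cin <- cfg$conv_channels[j - 1]
          dcol <- t(params[[paste0("conv", j, ".W")]]) %*% dZ
          dA <- col2im1d(dcol, cin, cfg$kernel, tt)
        }
      }
    }
  }
  grads
}

#' Deep-feature head forward pass
#'
#' Runs the CNN-BiLSTM head on one window: the 6-channel rPPG signals
#' (globally standardized so relative channel amplitudes survive) stacked
#' with the clip's AC/DC modulation traces, through the 1-D convolution
#' stack and the bidirectional LSTM, whose concatenated final hidden states
#' feed a sigmoid-squashed linear readout.
#'
#' @param signals An `rppg_signals` object or `6 x T` matrix.
#' @param clip_features Optional `3 x T` matrix from [clip_acdc_features()]
#'   (omitted for a signals-only head).
#' @param params Head parameters (from a trained `spo2cam_model`'s `head`,
#'   or [head_init()] internals).
#' @param cfg The matching [head_config()].
#' @return Scalar deep feature `m1` in `[0, 1]`.
#' @export
cnn_bilstm_forward <- function(signals, clip_features = NULL, params, cfg) {
  if (inherits(signals, "rppg_signals")) signals <- signals$signals
  if (ncol(signals) < cfg$kernel) {
    stop_insufficient_length("window shorter than the convolution kernel.")
  }
  z <- standardize_head_input(signals)
  if (!is.null(clip_features)) z <- rbind(z, clip_features)
  if (nrow(z) != cfg$in_ch) {
    stop_shape(sprintf("head expects %d input channels, got %d.", cfg$in_ch, nrow(z)))
  }
  head_forward(params, cfg, list(z))$m1
}

#' Constrained fusion weights
#'
#' The fusion attention weights are parametrized by a single free scalar
#' `theta` through `k1 = 100 * sigmoid(theta)`, `k2 = 100 - k1`, so the
#' constraint `k1 + k2 = 100` holds exactly at every optimization step by
#' construction. `theta = 0` gives the 50/50 initialization.
#'
#' @param theta Free parameter (real scalar).
#' @return An object of class `fusion_weights` with `k1`, `k2`, `theta`.
#' @export
fusion_weights <- function(theta = 0) {
  k1 <- 100 * stats::plogis(theta)
  structure(list(k1 = k1, k2 = 100 - k1, theta = theta), class = "fusion_weights")
}

#' @export
print.fusion_weights <- function(x, ...) {
  cat(sprintf("<fusion_weights> k1 = %.2f, k2 = %.2f (k1 + k2 = %g)\n",
              x$k1, x$k2, x$k1 + x$k2))
  invisible(x)
}

#' Fuse deep and manual feature outputs into an SpO2 value
#'
#' `SpO2 = k1 * m1 + k2 * m2`, clipped to `[0, 100]`. Both `m1` and `m2`
#' live on a `[0, 1]` scale so the 100-scale weights produce percent output.
#'
#' @param m1 Deep-head output scalar (or vector) in `[0, 1]`.
#' @param m2 Manual-feature attention output on the same scale.
#' @param w A [fusion_weights()].
#' @return SpO2 value(s) in percent, clipped to `[0, 100]`.
#' @export
fuse <- function(m1, m2, w) {
  if (!inherits(w, "fusion_weights")) stop_config("`w` must be fusion_weights.")
  pmin(pmax(w$k1 * m1 + w$k2 * m2, 0), 100)
}

#' End-to-end SpO2 training loss
#'
#' Mean squared error between predicted and reference SpO2 on the percent
#' scale.
#'
#' @param pred,ref Equal-length numeric vectors (percent).
#' @return Non-negative scalar.
#' @export
end_to_end_loss <- function(pred, ref) {
  pred <- as.numeric(pred)
  ref <- as.numeric(ref)
  if (length(pred) != length(ref)) {
    stop_shape(sprintf("lengths differ (%d vs %d).", length(pred), length(ref)))
  }
  mean((pred - ref)^2)
}

#' Assemble the full video-to-SpO2 model
#'
#' Couples a (frozen or trainable) rPPG backbone with the deep CNN-BiLSTM
#' head and, optionally, the manual-feature attention module under the
#' constrained fusion. Without MFAM the deep output is used alone
#' (`SpO2 = 100 * m1`).
#'
#' @param backbone An [build_estimator()] estimator.
#' @param head_cfg A [head_config()].
#' @param use_mfam Include the manual-feature attention branch and fusion?
#' @param seed Seed for head/MFAM initialization.
#' @return An object of class `spo2cam_model`.
#' @export
build_spo2_model <- function(backbone, head_cfg = head_config(),
                             use_mfam = TRUE, seed = 1) {
  structure(
    list(
      backbone = backbone,
      head_cfg = head_cfg,
      head = head_init(head_cfg, seed),
      mfam = if (use_mfam) mfam_init(seed + 1),
      theta = 0,
      use_mfam = isTRUE(use_mfam)
    ),
    class = "spo2cam_model"
  )
}

#' @export
print.spo2cam_model <- function(x, ...) {
  w <- fusion_weights(x$theta)
  cat(sprintf(
    "<spo2cam_model> backbone %d params; %s head; %s\n",
    x$backbone$n_params,
    if (x$head_cfg$bidirectional) "CNN-BiLSTM" else "LSTM",
    if (x$use_mfam) sprintf("MFAM fusion (k1 = %.1f, k2 = %.1f)", w$k1, w$k2)
    else "no MFAM (deep output only)"
  ))
  invisible(x)
}

# standardize a backbone output window globally (preserving relative channel
# amplitudes, which carry the red/blue pulsatility ratio)
standardize_head_input <- function(z) {
  (z - mean(z)) / (stats::sd(z) + 1e-6)
}

model_window_features <- function(model, clips) {
  zlist <- lapply(clips, function(cl) {
    sig <- rppg_forward(model$backbone, cl)$signals
    z <- standardize_head_input(sig)
    # the proposed head consumes the AC/DC modulation traces alongside the
    # rPPG channels; the generic LSTM baseline head sees the signals only
    if (model$head_cfg$in_ch > nrow(z)) z <- rbind(z, clip_acdc_features(cl))
    z
  })
  Cw <- do.call(rbind, lapply(clips, manual_features))
  list(zlist = zlist, Cw = Cw)
}

model_predict_features <- function(model, zlist, Cw, keep = FALSE) {
  hf <- head_forward(model$head, model$head_cfg, zlist, keep = keep)
  if (model$use_mfam) {
    mf <- mfam_forward_batch(model$mfam, Cw, keep = keep)
    w <- fusion_weights(model$theta)
    y <- w$k1 * hf$m1 + w$k2 * mf$m2
  } else {
    mf <- NULL
    y <- 100 * hf$m1
  }
  list(y = y, hf = hf, mf = mf)
}

#' End-to-end SpO2 training with a frozen backbone (stage 3)
#'
#' Trains the deep head, the manual-feature attention module and the fusion
#' parameter against per-window SpO2 labels with Adam on the MSE loss. The
#' rPPG backbone is frozen: its parameters are not part of the optimization
#' and are returned bit-identical. The fusion constraint `k1 + k2 = 100`
#' holds exactly after every step by construction.
#'
#' @param model A [build_spo2_model()] (typically with a stage-2 backbone).
#' @param windows List of labeled windows, each a list with `clip` (ROI
#'   [video_clip()], `T` frames) and `spo2` (label, percent).
#' @param cfg A [stage_config()] (reference learning rate 0.005).
#' @return A list with the trained `model` and `history` (per-epoch MSE).
#' @export
train_stage3 <- function(model, windows, cfg) {
  if (!inherits(model, "spo2cam_model")) {
    stop_state("`model` must be a spo2cam_model (load or build one first).")
  }
  if (length(windows) == 0) stop_data("no labeled windows provided.")
  feats <- model_window_features(model, lapply(windows, `[[`, "clip"))
  ref <- vapply(windows, `[[`, numeric(1), "spo2")
  params <- c(model$head, model$mfam, list(theta = model$theta))
  state <- adam_init(params)
  hist <- numeric(cfg$epochs)
  n_head <- length(model$head)
  with_seed(cfg$seed + 2, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(length(windows))
      ep_mse <- 0
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
        model$head <- params[seq_len(n_head)]
        if (model$use_mfam) model$mfam <- params[grep("^mfam\\.", names(params))]
        model$theta <- params$theta
        pred <- model_predict_features(
          model, feats$zlist[idx], feats$Cw[idx, , drop = FALSE], keep = TRUE
        )
        err <- pred$y - ref[idx]
        ep_mse <- ep_mse + sum(err^2)
        dy <- 2 * err / length(err)
        if (model$use_mfam) {
          w <- fusion_weights(model$theta)
          dm1 <- dy * w$k1
          dm2 <- dy * w$k2
          sg <- stats::plogis(model$theta)
          dtheta <- sum(dy * (pred$hf$m1 - pred$mf$m2)) * 100 * sg * (1 - sg)
          grads <- c(
            head_backward(model$head, model$head_cfg, pred$hf$cache, dm1),
            mfam_backward_batch(model$mfam, pred$mf$cache, dm2),
            list(theta = dtheta)
          )
        } else {
          grads <- c(
            head_backward(model$head, model$head_cfg, pred$hf$cache, dy * 100),
            list(theta = 0)
          )
        }
        upd <- adam_step(params, grads, state, cfg$lr)
        params <- upd$params
        state <- upd$state
      }
      hist[ep] <- ep_mse / length(windows)
    }
  })
  model$head <- params[seq_len(n_head)]
  if (model$use_mfam) model$mfam <- params[grep("^mfam\\.", names(params))]
  model$theta <- params$theta
  list(model = model, history = tibble::tibble(epoch = seq_len(cfg$epochs), mse = hist))
}

#' Predict per-window SpO2 from an ROI clip
#'
#' Splits the clip into consecutive analysis windows, runs the backbone,
#' head and (if present) the manual-feature attention fusion, and returns
#' one SpO2 estimate per window, clipped to `[0, 100]`.
#'
#' @param model A trained [build_spo2_model()].
#' @param clip ROI [video_clip()] at the model's working resolution.
#' @param window_frames Window length in frames (even, default 60).
#' @return A [tibble::tibble()] with `window`, `start_s`, `end_s`, `spo2`.
#' @export
predict_spo2 <- function(model, clip, window_frames = 60) {
  tt <- n_frames(clip)
  if (tt < window_frames) {
    stop_insufficient_length("clip shorter than one analysis window.")
  }
  starts <- seq(1, tt - window_frames + 1, by = window_frames)
  clips <- lapply(starts, function(s) clip_window(clip, s, window_frames))
  feats <- model_window_features(model, clips)
  pred <- model_predict_features(model, feats$zlist, feats$Cw)
  tibble::tibble(
    window = seq_along(starts),
    start_s = (starts - 1) / clip$rate,
    end_s = (starts - 1 + window_frames) / clip$rate,
    spo2 = pmin(pmax(pred$y, 0), 100)
  )
}
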