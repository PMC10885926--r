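# Contrastive pre-training of the rPPG estimator.
#
# The learning signal is built entirely from band-limited, L1-normalized
# power spectra of the estimator's 6-channel outputs: spectra of face and
# hand quadrant sub-ROIs are pulled together (spatial similarity), the
# whole-clip spectra of the stationary face, the hand, and the rotated face
# segment are pulled together (spatio-temporal invariance), and the spectrum
# of a static "pseudo" clip regenerated from a single augmented frame is
# pushed away (it carries lighting/sensor structure but no pulse).

PSD_EPS <- 1e-12

# cos/sin DFT bases for the analysis band, cached per (T, rate, band, nfft)
psd_basis_cache <- new.env(parent = emptyenv())

psd_basis <- function(t_len, rate, band = c(0.5, 4), nfft = 128) {
  nfft <- max(nfft, t_len)
  key <- paste(t_len, rate, band[1], band[2], nfft, sep = "_")
  if (!is.null(psd_basis_cache[[key]])) {
    return(psd_basis_cache[[key]])
  }
  freqs <- (seq_len(nfft) - 1) * rate / nfft
  keep <- which(freqs >= band[1] & freqs <= band[2] & freqs <= rate / 2)
  n <- seq_len(t_len) - 1
  ang <- 2 * pi * outer(keep - 1, n) / nfft
  basis <- list(
    C = cos(ang), S = sin(ang), freqs = freqs[keep],
    win = hann_window(t_len), nb = length(keep)
  )
  psd_basis_cache[[key]] <- basis
  basis
}

# Channel-averaged normalized band PSD of a (6 x T) signal matrix.
# Returns the feature vector plus a cache for the backward pass.
psd_feature_forward <- function(y, basis) {
  ch <- nrow(y)
  z <- y - rowMeans(y)
  v <- z * rep(basis$win, each = ch)
  a <- basis$C %*% t(v)     # nb x ch
  b <- basis$S %*% t(v)
  p <- a^2 + b^2
  s <- colSums(p)
  q <- (p + PSD_EPS) / rep(s + basis$nb * PSD_EPS, each = basis$nb)
  f <- rowMeans(q)
  list(f = f, cache = list(a = a, b = b, q = q, s = s, ch = ch))
}

psd_feature_backward <- function(df, cache, basis) {
  ch <- cache$ch
  dq <- matrix(df / ch, basis$nb, ch)
  denom <- rep(cache$s + basis$nb * PSD_EPS, each = basis$nb)
  dp <- (dq - rep(colSums(dq * cache$q), each = basis$nb)) / denom
  dv <- t(basis$C) %*% (2 * cache$a * dp) + t(basis$S) %*% (2 * cache$b * dp)
  dz <- t(dv) * rep(basis$win, each = ch)   # ch x T
  dz - rowMeans(dz)
}

#' Regenerate a static pseudo clip from one augmented frame
#'
#' Picks one frame of the input uniformly at random, applies chromatic
#' augmentation (per-channel gain and offset) plus additive pixel noise, and
#' replicates the augmented frame across all time steps. The result carries
#' the scene's spatial and chromatic structure but no pulsatile content,
#' making it the negative sample for the contrastive losses.
#'
#' @param x_a A [video_clip()].
#' @param seed Integer seed (frame choice and augmentation are deterministic
#'   given the seed).
#' @param strength Augmentation strength in `[0, 1]`; `0` yields exact
#'   copies of the chosen frame.
#' @return A [video_clip()] with the same dimensions as `x_a`.
#' @export
build_pseudo_sample <- function(x_a, seed = 1, strength = 1) {
  tt <- n_frames(x_a)
  with_seed(seed, {
    pick <- sample.int(tt, 1)
    fr <- x_a$frames[pick, , , ]
    if (strength > 0) {
      gain <- 1 + strength * stats::runif(3, -0.2, 0.2)
      offs <- strength * stats::runif(3, -0.05, 0.05)
      for (c in 1:3) fr[, , c] <- fr[, , c] * gain[c] + offs[c]
      fr <- fr + strength * stats::rnorm(length(fr), sd = 0.01)
      fr <- pmin(pmax(fr, 0), 1)
    }
    frames <- array(0, dim(x_a$frames))
    for (t in seq_len(tt)) frames[t, , , ] <- fr
    video_clip(frames, x_a$rate)
  })
}

#' Assemble one contrastive training tuple from a face/hand window
#'
#' From a `T`-frame window of concurrently recorded face and hand clips,
#' builds the four half-window clips the contrastive stage trains on:
#' `x_a` (face, first half, stationary), `x_b` (hand, first half), `x_c`
#' (static pseudo clip regenerated from one augmented frame of `x_a`), and
#' `x_d` (face, second half, where any rotation perturbation lives), plus
#' the four spatial quadrants of `x_a` and of `x_b`.
#'
#' @param face_clip,hand_clip [video_clip()]s sharing `T` frames (`T`
#'   divisible by 4).
#' @param seed Seed for the pseudo-sample augmentation.
#' @param aug_strength Augmentation strength for [build_pseudo_sample()].
#' @return A list with clips `x_a`, `x_b`, `x_c`, `x_d`, and lists
#'   `face_regions`, `hand_regions` of four quadrant clips each.
#' @export
make_contrastive_tuple <- function(face_clip, hand_clip, seed = 1,
                                   aug_strength = 1) {
  tt <- n_frames(face_clip)
  if (n_frames(hand_clip) != tt) {
    stop_shape("face and hand clips must share the frame count.")
  }
  if (tt %% 4 != 0) {
    stop_invalid_parameter("window length must be divisible by 4.")
  }
  half <- tt / 2
  x_a <- clip_window(face_clip, 1, half)
  x_b <- clip_window(hand_clip, 1, half)
  x_d <- clip_window(face_clip, half + 1, half)
  x_c <- build_pseudo_sample(x_a, seed = seed, strength = aug_strength)
  list(
    x_a = x_a, x_b = x_b, x_c = x_c, x_d = x_d,
    face_regions = split_quadrants(x_a),
    hand_regions = split_quadrants(x_b)
  )
}

as_psd_vec <- function(p) {
  if (inherits(p, "psd")) p$power else as.numeric(p)
}

check_psd_grid <- function(lst) {
  n <- unique(vapply(lst, length, 1L))
  if (length(n) != 1) stop_shape("all PSDs must share one frequency grid.")
  n
}

#' Positive contrastive loss over a batch of PSD tuples
#'
#' Sums squared distances between all ordered pairs of hand-region PSDs and
#' all ordered pairs of face-region PSDs across the batch (divided by
#' `16 N^2`), plus the spatio-temporal term: the batch mean of
#' `||f_a - f_b||^2 + ||f_a - f_d||^2`.
#'
#' @param batch A list of per-sample lists, each with elements `f_a`, `f_b`,
#'   `f_d` (whole-clip PSD vectors) and `face_regions`, `hand_regions`
#'   (lists of four region PSD vectors). PSDs may be plain numeric vectors
#'   or `psd` objects; all must share one frequency grid.
#' @return A single non-negative number.
#' @export
positive_loss <- function(batch) {
  positive_loss_grad(batch, want_grad = FALSE)$value
}

positive_loss_grad <- function(batch, want_grad = TRUE) {
  n <- length(batch)
  if (n == 0) stop_data("empty batch.")
  hand <- lapply(batch, function(s) lapply(s$hand_regions, as_psd_vec))
  face <- lapply(batch, function(s) lapply(s$face_regions, as_psd_vec))
  fa <- lapply(batch, function(s) as_psd_vec(s$f_a))
  fb <- lapply(batch, function(s) as_psd_vec(s$f_b))
  fd <- lapply(batch, function(s) as_psd_vec(s$f_d))
  check_psd_grid(c(unlist(hand, recursive = FALSE),
                   unlist(face, recursive = FALSE), fa, fb, fd))

  # all-ordered-pairs sum of squared distances of a set of m vectors:
  # sum_{p,q} ||v_p - v_q||^2 = 2m * sum_p ||v_p||^2 - 2 ||sum_p v_p||^2
  pair_term <- function(vecs) {
    m <- length(vecs)
    vm <- do.call(cbind, vecs)
    tot <- rowSums(vm)
    val <- 2 * m * sum(vm^2) - 2 * sum(tot^2)
    grad <- if (want_grad) 4 * (m * vm - tot) else NULL
    list(value = val, grad = grad)
  }
  h <- pair_term(unlist(hand, recursive = FALSE))
  f <- pair_term(unlist(face, recursive = FALSE))
  scale <- 1 / (16 * n^2)
  st_val <- 0
  g <- if (want_grad) {
    list(
      hand = lapply(seq_len(4 * n), function(i) h$grad[, i] * scale),
      face = lapply(seq_len(4 * n), function(i) f$grad[, i] * scale),
      f_a = vector("list", n), f_b = vector("list", n), f_d = vector("list", n)
    )
  }
  for (i in seq_len(n)) {
    dab <- fa[[i]] - fb[[i]]
    dad <- fa[[i]] - fd[[i]]
    st_val <- st_val + sum(dab^2) + sum(dad^2)
    if (want_grad) {
      g$f_a[[i]] <- (2 * dab + 2 * dad) / n
      g$f_b[[i]] <- -2 * dab / n
      g$f_d[[i]] <- -2 * dad / n
    }
  }
  list(value = (h$value + f$value) * scale + st_val / n, grad = g)
}

#' Negative contrastive loss over a batch of PSD tuples
#'
#' `-(1/N^2) * sum_{n1, n2} ||f_a^{(n1)} - f_c^{(n2)}||^2`: the whole-clip
#' PSD of each real face segment is pushed away from the PSD of every static
#' pseudo clip in the batch. With L1-normalized PSDs the loss is bounded
#' below by -4.
#'
#' @param batch As in [positive_loss()], with elements `f_a` and `f_c`.
#' @return A single non-positive number.
#' @export
negative_loss <- function(batch) {
  negative_loss_grad(batch, want_grad = FALSE)$value
}

negative_loss_grad <- function(batch, want_grad = TRUE) {
  n <- length(batch)
  if (n == 0) stop_data("empty batch.")
  fa <- lapply(batch, function(s) as_psd_vec(s$f_a))
  fc <- lapply(batch, function(s) as_psd_vec(s$f_c))
  check_psd_grid(c(fa, fc))
  am <- do.call(cbind, fa)
  cm <- do.call(cbind, fc)
  ca <- rowSums(am)
  cc <- rowSums(cm)
  val <- -(n * (sum(am^2) + sum(cm^2)) - 2 * sum(ca * cc)) / n^2
  g <- NULL
  if (want_grad) {
    ga <- -(2 * n * am - 2 * cc) / n^2
    gc <- -(2 * n * cm - 2 * ca) / n^2
    g <- list(
      f_a = lapply(seq_len(n), function(i) ga[, i]),
      f_c = lapply(seq_len(n), function(i) gc[, i])
    )
  }
  list(value = val, grad = g)
}

#' Supervised cosine-similarity loss for rPPG fine-tuning
#'
#' `L_s = 2 - sim(y_a, ref1) - sim(y_d, ref2)` where each prediction is the
#' mean of the six estimator channels and `sim` is [cosine_similarity()].
#' Zero when both predictions match their references up to positive scaling;
#' 4 when both are negated.
#'
#' @param y_a,y_d `rppg_signals` objects (or `6 x T` matrices): predictions
#'   for the stationary and the rotated half-window.
#' @param ref1,ref2 Reference PPG [waveform()]s (or numeric vectors) of
#'   matching length.
#' @return A number in `[0, 4]`.
#' @export
supervised_loss <- function(y_a, y_d, ref1, ref2) {
  red <- function(y) {
    if (inherits(y, "rppg_signals")) y <- y$signals
    colMeans(y)
  }
  r1 <- if (inherits(ref1, "waveform")) ref1$samples else as.numeric(ref1)
  r2 <- if (inherits(ref2, "waveform")) ref2$samples else as.numeric(ref2)
  2 - cosine_similarity(red(y_a), r1) - cosine_similarity(red(y_d), r2)
}

# gradient of -cos(mean_channels(y), ref) w.r.t. y (ch x T)
neg_cos_grad <- function(y, ref) {
  u <- colMeans(y)
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(ref^2))
  if (nu == 0 || nv == 0) stop_degenerate_signal("zero-norm signal in loss.")
  cs <- sum(u * ref) / (nu * nv)
  du <- -(ref / (nu * nv) - cs * u / nu^2)
  matrix(rep(du / nrow(y), each = nrow(y)), nrow(y))
}

#' Stage configuration for the training schedules
#'
#' @param lr Learning rate (> 0). Full-scale reference values: 0.001 for the
#'   contrastive stage, 0.0001 for supervised rPPG fine-tuning, 0.005 for
#'   end-to-end SpO2 training.
#' @param epochs Number of epochs (>= 1).
#' @param batch_size Samples per optimizer step (contrastive stage).
#' @param seed Integer seed controlling shuffling and augmentation.
#' @return An object of class `stage_config`.
#' @export
stage_config <- function(lr, epochs, batch_size = 4, seed = 1) {
  if (lr <= 0) stop_invalid_parameter("`lr` must be positive.")
  if (epochs < 1) stop_invalid_parameter("`epochs` must be at least 1.")
  structure(
    list(lr = lr, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), seed = as.integer(seed)),
    class = "stage_config"
  )
}

# forward a clip through the estimator keeping caches, then its PSD feature
clip_psd_forward <- function(est, clip, basis) {
  x <- clip_tensor(clip)
  fw <- net_forward(est$layers, est$params, x, keep = TRUE)
  sig <- fw$out
  dim(sig) <- dim(fw$out)[1:2]
  pf <- psd_feature_forward(sig, basis)
  list(f = pf$f, net_cache = fw$caches, psd_cache = pf$cache,
       out_dim = dim(fw$out))
}

clip_psd_backward <- function(est, cp, df, basis) {
  dy <- psd_feature_backward(df, cp$psd_cache, basis)
  dy4 <- array(dy, cp$out_dim)
  net_backward(est$layers, est$params, cp$net_cache, dy4)
}

#' Contrastive pre-training of the estimator (stage 1)
#'
#' Minimizes `positive_loss + negative_loss` with Adam over tuples built by
#' [make_contrastive_tuple()]. Labels are not used. Deterministic for a
#' fixed seed.
#'
#' @param est An [build_estimator()] estimator.
#' @param tuples List of contrastive tuples (see
#'   [make_contrastive_tuple()]).
#' @param cfg A [stage_config()] (reference learning rate 0.001).
#' @param band,nfft PSD analysis band (Hz) and FFT length for the loss
#'   spectra.
#' @return A list with the updated `est` and `history` (tibble with
#'   per-epoch `loss_p`, `loss_n`, `loss`).
#' @export
train_stage1 <- function(est, tuples, cfg, band = c(0.5, 4), nfft = 128) {
  if (length(tuples) == 0) stop_data("no training tuples provided.")
  rate <- tuples[[1]]$x_a$rate
  t_half <- n_frames(tuples[[1]]$x_a)
  basis <- psd_basis(t_half, rate, band, nfft)
  state <- adam_init(est$params)
  hist <- vector("list", cfg$epochs)
  clip_names <- c("x_a", "x_b", "x_c", "x_d")
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(length(tuples))
      ep_p <- ep_n <- 0
      n_b <- 0
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
        fwd <- lapply(tuples[idx], function(tp) {
          cl <- c(
            stats::setNames(lapply(clip_names, function(nm) {
              clip_psd_forward(est, tp[[nm]], basis)
            }), clip_names),
            list(
              face_regions = lapply(tp$face_regions, clip_psd_forward,
                                    est = est, basis = basis),
              hand_regions = lapply(tp$hand_regions, clip_psd_forward,
                                    est = est, basis = basis)
            )
          )
          cl
        })
        psd_batch <- lapply(fwd, function(s) {
          list(
            f_a = s$x_a$f, f_b = s$x_b$f, f_c = s$x_c$f, f_d = s$x_d$f,
            face_regions = lapply(s$face_regions, `[[`, "f"),
            hand_regions = lapply(s$hand_regions, `[[`, "f")
          )
        })
        lp <- positive_loss_grad(psd_batch)
        ln <- negative_loss_grad(psd_batch)
        grads <- list()
        for (i in seq_along(fwd)) {
          s <- fwd[[i]]
          dfa <- lp$grad$f_a[[i]] + ln$grad$f_a[[i]]
          grads <- accumulate_grads(grads, clip_psd_backward(est, s$x_a, dfa, basis))
          grads <- accumulate_grads(grads, clip_psd_backward(est, s$x_b, lp$grad$f_b[[i]], basis))
          grads <- accumulate_grads(grads, clip_psd_backward(est, s$x_c, ln$grad$f_c[[i]], basis))
          grads <- accumulate_grads(grads, clip_psd_backward(est, s$x_d, lp$grad$f_d[[i]], basis))
          for (r in 1:4) {
            grads <- accumulate_grads(grads, clip_psd_backward(
              est, s$face_regions[[r]], lp$grad$face[[(i - 1) * 4 + r]], basis
            ))
            grads <- accumulate_grads(grads, clip_psd_backward(
              est, s$hand_regions[[r]], lp$grad$hand[[(i - 1) * 4 + r]], basis
            ))
          }
        }
        upd <- adam_step(est$params, grads, state, cfg$lr)
        est$params <- upd$params
        state <- upd$state
        ep_p <- ep_p + lp$value
        ep_n <- ep_n + ln$value
        n_b <- n_b + 1
      }
      hist[[ep]] <- tibble::tibble(
        epoch = ep, loss_p = ep_p / n_b, loss_n = ep_n / n_b,
        loss = (ep_p + ep_n) / n_b
      )
    }
  })
  list(est = est, history = do.call(rbind, hist))
}

#' Supervised rPPG fine-tuning (stage 2)
#'
#' Minimizes the cosine-similarity loss [supervised_loss()] against aligned
#' reference PPG half-windows with Adam.
#'
#' @param est The estimator (typically after [train_stage1()]).
#' @param labeled List of samples, each a list with `face` (a
#'   [video_clip()] of `T` frames, `T` divisible by 4) and `ppg` (aligned
#'   reference [waveform()] of length `T`, e.g. from [prepare_labels()]).
#' @param cfg A [stage_config()] (reference learning rate 0.0001).
#' @return A list with the updated `est` and `history` (per-epoch mean
#'   `loss_s`).
#' @export
train_stage2 <- function(est, labeled, cfg) {
  if (length(labeled) == 0) stop_data("no labeled samples provided.")
  for (s in labeled) {
    if (is.null(s$face) || is.null(s$ppg)) {
      stop_data("each labeled sample needs `face` and `ppg`.")
    }
  }
  state <- adam_init(est$params)
  hist <- numeric(cfg$epochs)
  with_seed(cfg$seed + 1, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(length(labeled))
      ep_loss <- 0
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
        grads <- list()
        for (i in idx) {
          s <- labeled[[i]]
          tt <- n_frames(s$face)
          half <- tt / 2
          halves <- list(
            list(clip = clip_window(s$face, 1, half), ref = s$ppg$samples[1:half]),
            list(clip = clip_window(s$face, half + 1, half),
                 ref = s$ppg$samples[(half + 1):tt])
          )
          loss_i <- 2
          for (hv in halves) {
            x <- clip_tensor(hv$clip)
            fw <- net_forward(est$layers, est$params, x, keep = TRUE)
            sig <- fw$out
            dim(sig) <- dim(fw$out)[1:2]
            loss_i <- loss_i - cosine_similarity(colMeans(sig), hv$ref)
            dy <- neg_cos_grad(sig, hv$ref) / length(idx)
            dy4 <- array(dy, dim(fw$out))
            grads <- accumulate_grads(
              grads, net_backward(est$layers, est$params, fw$caches, dy4)
            )
          }
          ep_loss <- ep_loss + loss_i
        }
        upd <- adam_step(est$params, grads, state, cfg$lr)
        est$params <- upd$params
        state <- upd$state
      }
      hist[ep] <- ep_loss / length(labeled)
    }
  })
  list(est = est, history = tibble::tibble(epoch = seq_len(cfg$epochs), loss_s = hist))
}
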