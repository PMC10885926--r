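#' Scene configuration for the synthetic pulsatile-video generator
#'
#' Describes one synthetic recording: a textured background with a skin
#' region (an ellipse for the face scene, a rounded rectangle for the hand)
#' whose pixels carry a cardiac-synchronous color oscillation. Each color
#' channel c follows `DC_c * (1 + r_c(t) * p(t)) * L(t)` where `p` is the
#' pulse waveform (fundamental at the configured heart rate plus a second
#' harmonic at 30% amplitude), `L` is a slow multiplicative lighting drift,
#' and the AC-to-DC ratios `r_c` encode the ground-truth SpO2 through the
#' classical linear ratio-of-ratios calibration
#' `SpO2 = A - B * (r_R / r_B)` with documented constants `A = 110`,
#' `B = 13` chosen so the physiological range 93--100% maps to plausible
#' red/blue ratio values.
#'
#' @param duration_s Scene length in seconds (>= 2).
#' @param rate Frame rate in fps (default 30).
#' @param size Square frame size in pixels (default 64).
#' @param hr_bpm Heart rate in beats/min; `hr_bpm/60` must lie in the
#'   0.5--4 Hz cardiac analysis band and below `rate/2`.
#' @param spo2_trace Per-second SpO2 values in percent, all in `[93, 100]`;
#'   default a constant 97.
#' @param lighting_amp Relative amplitude of a 0.1 Hz global illumination
#'   drift (0 disables it).
#' @param rotation_deg Maximum in-plane rotation of the face skin patch in
#'   degrees (0.2 Hz oscillation; 0 disables it).
#' @param noise_sd Per-pixel Gaussian sensor noise standard deviation.
#' @param seed Integer seed; generation is reproducible bit-for-bit.
#' @param cal_a,cal_b Ratio-of-ratios calibration constants.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(duration_s = 10, rate = 30, size = 64, hr_bpm = 72,
                         spo2_trace = NULL, lighting_amp = 0, rotation_deg = 0,
                         noise_sd = 0.003, seed = 1, cal_a = 110, cal_b = 13) {
  f <- hr_bpm / 60
  if (f < 0.5 || f > 4) {
    stop_invalid_parameter(sprintf(
      "hr_bpm = %g lies outside the 0.5-4 Hz cardiac band (30-240 bpm).", hr_bpm
    ))
  }
  if (rate <= 2 * f) {
    stop_invalid_parameter("frame rate must exceed twice the cardiac frequency.")
  }
  if (duration_s < 2) stop_invalid_parameter("`duration_s` must be at least 2 s.")
  if (size < 16 || size %% 2 != 0) {
    stop_invalid_parameter("`size` must be an even number of pixels >= 16.")
  }
  if (is.null(spo2_trace)) spo2_trace <- rep(97, duration_s)
  if (length(spo2_trace) != duration_s) {
    stop_invalid_parameter("`spo2_trace` must hold one value per second.")
  }
  if (any(spo2_trace < 93 | spo2_trace > 100)) {
    stop_invalid_parameter("all `spo2_trace` values must lie in [93, 100]%.")
  }
  structure(
    list(
      duration_s = as.integer(duration_s), rate = rate, size = as.integer(size),
      hr_bpm = hr_bpm, spo2_trace = as.numeric(spo2_trace),
      lighting_amp = lighting_amp, rotation_deg = rotation_deg,
      noise_sd = noise_sd, seed = as.integer(seed),
      cal_a = cal_a, cal_b = cal_b
    ),
    class = "scene_config"
  )
}

# per-channel optical parameters of the synthetic skin model
SYN_DC_FACE <- c(R = 0.62, G = 0.44, B = 0.34)
SYN_DC_HAND <- c(R = 0.66, G = 0.48, B = 0.38)
SYN_AC_DC_BLUE <- 0.010   # r_B, fixed
SYN_AC_DC_GREEN <- 0.020  # r_G, fixed (green carries the strongest pulse)
SYN_HAND_AC_SCALE <- 0.8  # hand pulsatility relative to the face
SYN_HARMONIC <- 0.3       # second-harmonic amplitude relative to fundamental

skin_mask <- function(size, region = c("face", "hand"), angle_rad = 0) {
  region <- match.arg(region)
  cx <- (size + 1) / 2
  yy <- matrix(seq_len(size), size, size) - cx          # row = y
  xx <- matrix(seq_len(size), size, size, byrow = TRUE) - cx
  u <- cos(angle_rad) * xx + sin(angle_rad) * yy
  v <- -sin(angle_rad) * xx + cos(angle_rad) * yy
  if (region == "face") {
    (u / (0.28 * size))^2 + (v / (0.38 * size))^2 <= 1
  } else {
    abs(u / (0.30 * size))^4 + abs(v / (0.36 * size))^4 <= 1
  }
}

mask_bbox <- function(mask) {
  ys <- which(rowSums(mask) > 0)
  xs <- which(colSums(mask) > 0)
  # 0-based, half-open [x0, x1) x [y0, y1)
  c(x0 = xs[1] - 1L, y0 = ys[1] - 1L, x1 = xs[length(xs)], y1 = ys[length(ys)])
}

#' Generate a synthetic face/hand recording with known ground truth
#'
#' Renders the scene described by a [scene_config()]: concurrently recorded
#' face and hand clips sharing one pulse waveform and SpO2 trace. The
#' per-channel AC/DC amplitude ratios obey the generator's ratio-of-ratios
#' law, so [invert_ratio_of_ratios()] can recover the configured SpO2 from
#' clean scenes. Rotation perturbs the face patch only; lighting drift and
#' sensor noise affect every pixel.
#'
#' @param cfg A [scene_config()].
#' @return An object of class `synth_sample`: `face_clip`, `hand_clip`
#'   ([video_clip()]s), `ppg` (ground-truth pulse [waveform()] at the frame
#'   rate), `spo2_trace`, `meta` (the config), and the generator-true skin
#'   masks / bounding boxes for oracle use in tests.
#' @examples
#' s <- generate_sample(scene_config(duration_s = 4, size = 32, seed = 7))
#' s$face_clip
#' @export
generate_sample <- function(cfg) {
  if (!inherits(cfg, "scene_config")) stop_config("`cfg` must be a scene_config.")
  tt <- cfg$duration_s * round(cfg$rate)
  tsec <- (seq_len(tt) - 1) / cfg$rate
  f <- cfg$hr_bpm / 60
  pulse <- sin(2 * pi * f * tsec) + SYN_HARMONIC * sin(4 * pi * f * tsec)
  spo2_f <- stats::approx(
    x = seq_along(cfg$spo2_trace) - 0.5, y = cfg$spo2_trace,
    xout = tsec, rule = 2
  )$y
  r_ratio <- (cfg$cal_a - spo2_f) / cfg$cal_b
  r <- list(
    R = r_ratio * SYN_AC_DC_BLUE,
    G = rep(SYN_AC_DC_GREEN, tt),
    B = rep(SYN_AC_DC_BLUE, tt)
  )
  light <- 1 + cfg$lighting_amp * sin(2 * pi * 0.1 * tsec)
  angle <- if (cfg$rotation_deg > 0) {
    cfg$rotation_deg * pi / 180 * sin(2 * pi * 0.2 * tsec)
  } else {
    numeric(tt)
  }

  # the background texture is scene structure, not noise: it is drawn from a
  # fixed internal seed so that disjoint scene seeds change only the noise
  # realization, never the deterministic content
  texture <- with_seed(424242L,
    matrix(stats::runif(cfg$size^2, -1, 1), cfg$size, cfg$size)
  )
  with_seed(cfg$seed, {
    bg <- 0.28 + 0.08 * texture
    render <- function(region, dc, ac_scale, rotating) {
      frames <- array(0, c(tt, cfg$size, cfg$size, 3))
      mask0 <- skin_mask(cfg$size, region, 0)
      idx0 <- which(mask0)
      for (t in seq_len(tt)) {
        m_idx <- if (rotating && angle[t] != 0) {
          which(skin_mask(cfg$size, region, angle[t]))
        } else {
          idx0
        }
        for (c in 1:3) {
          fr <- bg * light[t]
          fr[m_idx] <- dc[c] * (1 + ac_scale * r[[c]][t] * pulse[t]) * light[t]
          frames[t, , , c] <- fr
        }
      }
      if (cfg$noise_sd > 0) {
        frames <- frames + array(
          stats::rnorm(length(frames), sd = cfg$noise_sd), dim(frames)
        )
        frames <- pmin(pmax(frames, 0), 1)
      }
      list(clip = video_clip(frames, cfg$rate), mask = mask0, box = mask_bbox(mask0))
    }
    face <- render("face", SYN_DC_FACE, 1, rotating = TRUE)
    hand <- render("hand", SYN_DC_HAND, SYN_HAND_AC_SCALE, rotating = FALSE)
    structure(
      list(
        face_clip = face$clip, hand_clip = hand$clip,
        ppg = waveform(pulse, cfg$rate),
        spo2_trace = cfg$spo2_trace, meta = cfg,
        face_mask = face$mask, hand_mask = hand$mask,
        face_box = face$box, hand_box = hand$box
      ),
      class = "synth_sample"
    )
  })
}

#' @export
print.synth_sample <- function(x, ...) {
  cat(sprintf(
    "<synth_sample> %d s @ %g fps, %dx%d px, HR %g bpm, SpO2 [%g, %g]%%\n",
    x$meta$duration_s, x$meta$rate, x$meta$size, x$meta$size, x$meta$hr_bpm,
    min(x$spo2_trace), max(x$spo2_trace)
  ))
  invisible(x)
}

#' Recover SpO2 from a synthetic clip via ratio-of-ratios
#'
#' The classical two-wavelength pulse-oximetry computation, used here as the
#' generator's consistency oracle: per second, the AC (root-mean-square of
#' the mean-removed skin trace) and DC (mean) components of the red and blue
#' channels give `R_ratio = (AC_R/DC_R) / (AC_B/DC_B)` and
#' `SpO2 = A - B * R_ratio`. Valid for scenes rendered without rotation or
#' lighting drift.
#'
#' @param clip A [video_clip()] produced by [generate_sample()].
#' @param cal_a,cal_b Calibration constants (must match the generator's).
#' @param mask Optional `H x W` logical skin mask; by default skin pixels are
#'   detected as `R - B > 0.1` on the time-mean frame.
#' @return Numeric vector of per-second SpO2 estimates (percent).
#' @export
invert_ratio_of_ratios <- function(clip, cal_a = 110, cal_b = 13, mask = NULL) {
  tt <- n_frames(clip)
  rate <- clip$rate
  if (tt < 2 * rate) {
    stop_insufficient_length(
      "clip must span at least 2 s (one cardiac cycle at the 0.5 Hz band floor)."
    )
  }
  if (is.null(mask)) {
    mr <- apply(clip$frames[, , , 1, drop = FALSE], c(2, 3), mean)
    mb <- apply(clip$frames[, , , 3, drop = FALSE], c(2, 3), mean)
    mask <- (mr - mb) > 0.1
    if (!any(mask)) stop_detection_failure("no skin-like pixels found in clip.")
  }
  tr <- channel_means(clip, mask)
  n_sec <- floor(tt / rate)
  half <- round(rate)  # 2-second centered analysis windows
  out <- numeric(n_sec)
  for (s in seq_len(n_sec)) {
    ctr <- round((s - 0.5) * rate)
    i0 <- max(1, ctr - half)
    i1 <- min(tt, ctr + half)
    comp <- function(ch) {
      w <- tr[i0:i1, ch]
      dc <- mean(w)
      list(ac = sqrt(mean((w - dc)^2)), dc = dc)
    }
    r <- comp(1)
    b <- comp(3)
    rr <- (r$ac / r$dc) / (b$ac / b$dc)
    out[s] <- cal_a - cal_b * rr
  }
  out
}

#' Build a per-second SpO2 trace with a breath-hold style desaturation
#'
#' Convenience trace generator: a baseline saturation with an optional
#' Gaussian-shaped dip (emulating a breath-hold) or a linear ramp, clamped to
#' the generator's physiological range 93--100%.
#'
#' @param duration_s Trace length in seconds.
#' @param kind `"constant"`, `"dip"` or `"ramp"`.
#' @param base Baseline SpO2 (percent).
#' @param depth Dip depth (percent) or ramp total change.
#' @param t0 Dip center time (s); defaults to mid-trace.
#' @param width Dip standard deviation (s).
#' @return Numeric vector of length `duration_s` in `[93, 100]`.
#' @export
make_spo2_trace <- function(duration_s, kind = c("dip", "constant", "ramp"),
                            base = 98, depth = 4, t0 = NULL, width = NULL) {
  kind <- match.arg(kind)
  s <- seq_len(duration_s) - 0.5
  y <- switch(kind,
    constant = rep(base, duration_s),
    ramp = base - depth + depth * (s - s[1]) / (s[length(s)] - s[1]),
    dip = {
      if (is.null(t0)) t0 <- duration_s / 2
      if (is.null(width)) width <- duration_s / 8
      base - depth * exp(-0.5 * ((s - t0) / width)^2)
    }
  )
  pmin(pmax(y, 93), 100)
}
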