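test_that("manual features match a brute-force mean/variance oracle", {
  const <- video_clip(array(0.5, c(4, 8, 8, 3)), 30)
  f <- manual_features(const)
  expect_equal(unname(f[1:3]), rep(0.5, 3))
  expect_equal(unname(f[4:6]), rep(0, 3))

  set.seed(8)
  clip <- video_clip(array(stats::runif(5 * 6 * 6 * 3), c(5, 6, 6, 3)), 30)
  f2 <- manual_features(clip)
  for (c in 1:3) {
    vals <- c()
    for (t in 1:5) for (y in 1:6) for (x in 1:6) {
      vals <- c(vals, clip$frames[t, y, x, c])
    }
    expect_equal(unname(f2[c]), mean(vals), tolerance = 1e-9)
    expect_equal(unname(f2[3 + c]), mean((vals - mean(vals))^2), tolerance = 1e-9)
  }

  half <- video_clip(clip$frames / 2, 30)
  fh <- manual_features(half)
  expect_equal(unname(fh[1:3]), unname(f2[1:3]) / 2, tolerance = 1e-12)
  expect_equal(unname(fh[4:6]), unname(f2[4:6]) / 4, tolerance = 1e-12)
})

test_that("MFAM attention weights form a convex combination", {
  set.seed(2)
  W <- matrix(rnorm(36), 6, 6)
  b <- rnorm(6)
  c_w <- c(0.5, 0.4, 0.3, 0.01, 0.02, 0.03)
  out <- mfam_forward(c_w, W, b)
  expect_equal(sum(out$weights), 1, tolerance = 1e-9)
  expect_true(all(out$weights >= 0))

  equal_feats <- rep(0.37, 6)
  expect_equal(mfam_forward(equal_feats, W, b)$m2, 0.37, tolerance = 1e-12)

  unif <- mfam_forward(c_w, matrix(0, 6, 6), rep(0, 6))
  expect_equal(unif$weights, rep(1 / 6, 6), tolerance = 1e-12)
  expect_equal(unif$m2, mean(c_w), tolerance = 1e-12)

  expect_error(mfam_forward(c_w, matrix(NA, 6, 6), b),
               class = "spo2cam_error_invalid_parameter")
  expect_error(mfam_forward(c(1, 2), W, b), class = "spo2cam_error_shape")
})

test_that("the CNN-BiLSTM head is deterministic, bounded, and length-guarded", {
  cfg <- head_config(in_ch = 9, conv_channels = c(4, 8), hidden = 8)
  params <- spo2cam:::head_init(cfg, seed = 3)
  set.seed(4)
  sig <- matrix(rnorm(6 * 40), 6)
  feats <- matrix(rnorm(3 * 40), 3)
  m1 <- cnn_bilstm_forward(sig, feats, params, cfg)
  expect_identical(cnn_bilstm_forward(sig, feats, params, cfg), m1)
  for (i in 1:5) {
    mm <- cnn_bilstm_forward(matrix(rnorm(6 * 40), 6), matrix(rnorm(3 * 40), 3),
                             params, cfg)
    expect_gte(mm, 0)
    expect_lte(mm, 1)
  }
  batch <- spo2cam:::head_forward(
    params, cfg, replicate(3, matrix(rnorm(9 * 40), 9), simplify = FALSE)
  )
  expect_length(batch$m1, 3)
  expect_error(cnn_bilstm_forward(matrix(rnorm(6 * 3), 6), NULL, params,
                                  head_config(in_ch = 6, hidden = 8)),
               class = "spo2cam_error_insufficient_length")
})

test_that("fusion respects the structural constraint and its anchors", {
  w0 <- fusion_weights(0)
  expect_identical(w0$k1, 50)
  expect_identical(w0$k2, 50)
  for (theta in c(-3, -0.7, 0, 1.2, 5)) {
    w <- fusion_weights(theta)
    expect_identical(w$k1 + w$k2, 100)
    expect_gte(w$k1, 0)
    expect_gte(w$k2, 0)
  }
  # the trained split reported at the end of the schedule: k1 = 87, k2 = 13
  w87 <- fusion_weights(stats::qlogis(0.87))
  expect_equal(fuse(0.97, 0.97, w87), 97, tolerance = 1e-9)
  expect_equal(fuse(0.5, 0.5, fusion_weights(2)), 50, tolerance = 1e-9)
  big <- fusion_weights(30)  # k1 numerically 100
  expect_equal(fuse(0.8, 0.1, big), 80, tolerance = 1e-6)
  expect_equal(fuse(1.5, 1.2, w87), 100)  # clipped
  expect_error(fuse(0.5, 0.5, list(k1 = 50, k2 = 50)),
               class = "spo2cam_error_config")
})

test_that("end-to-end loss is mean squared error on the percent scale", {
  r <- c(96, 95, 98)
  expect_equal(end_to_end_loss(r, r), 0)
  expect_equal(end_to_end_loss(r + 2, r), 4)
  expect_equal(end_to_end_loss(c(95, 99), c(96, 96)), 5)
  expect_error(end_to_end_loss(1:3, 1:2), class = "spo2cam_error_shape")
})

test_that("stage-3 training freezes the backbone and keeps k1 + k2 = 100 exactly", {
  s <- tiny_scene_noisy()
  roi <- crop_resize(s$face_clip, s$face_box, out_size = 16)
  spread <- c(95, 97.5, 99, 96)  # varied labels so the loss has structure
  windows <- lapply(seq_len(4), function(k) {
    list(clip = clip_window(roi, 1 + (k - 1) * 30, 30), spo2 = spread[k])
  })
  est <- build_estimator(rppg_config(input_size = 16, width = 0.125), seed = 9)
  model <- build_spo2_model(
    est, head_config(in_ch = 9, conv_channels = c(4, 8), hidden = 8),
    use_mfam = TRUE, seed = 1
  )
  before <- model$backbone$params
  res <- train_stage3(model, windows, stage_config(0.02, 20, 4, seed = 3))
  expect_identical(res$model$backbone$params, before)
  w <- fusion_weights(res$model$theta)
  expect_identical(w$k1 + w$k2, 100)
  expect_false(identical(res$model$head, model$head))
  expect_lt(res$history$mse[20], res$history$mse[1])
  expect_error(train_stage3(model, list(), stage_config(0.02, 2, 4, 1)),
               class = "spo2cam_error_data")
  expect_error(train_stage3(est, windows, stage_config(0.02, 2, 4, 1)),
               class = "spo2cam_error_state")
})

test_that("prediction emits one clipped estimate per analysis window", {
  s <- tiny_scene_noisy()
  roi <- crop_resize(s$face_clip, s$face_box, out_size = 16)
  est <- build_estimator(rppg_config(input_size = 16, width = 0.125), seed = 9)
  model <- build_spo2_model(est, head_config(in_ch = 9, conv_channels = c(4, 8),
                                             hidden = 8), seed = 2)
  pred <- predict_spo2(model, roi, window_frames = 60)
  expect_equal(nrow(pred), 2)
  expect_true(all(pred$spo2 >= 0 & pred$spo2 <= 100))
  expect_equal(pred$start_s, c(0, 2))
  expect_error(predict_spo2(model, clip_window(roi, 1, 30), 60),
               class = "spo2cam_error_insufficient_length")
})

test_that("fused model gradients match finite differences", {
  set.seed(3)
  hcfg <- head_config(in_ch = 9, conv_channels = c(4, 6), kernel = 3, hidden = 5)
  head <- spo2cam:::head_init(hcfg, 1)
  mfam <- spo2cam:::mfam_init(2)
  theta <- 0.3
  zlist <- replicate(4, matrix(rnorm(9 * 16), 9, 16), simplify = FALSE)
  Cw <- cbind(matrix(runif(12, 0.3, 0.6), 4, 3), matrix(runif(12, 0, 0.01), 4, 3))
  ref <- c(97, 95, 99, 94)
  obj <- function(head, mfam, theta) {
    hf <- spo2cam:::head_forward(head, hcfg, zlist)
    mf <- spo2cam:::mfam_forward_batch(mfam, Cw)
    k1 <- 100 * stats::plogis(theta)
    mean((k1 * hf$m1 + (100 - k1) * mf$m2 - ref)^2)
  }
  hf <- spo2cam:::head_forward(head, hcfg, zlist, keep = TRUE)
  mf <- spo2cam:::mfam_forward_batch(mfam, Cw, keep = TRUE)
  k1 <- 100 * stats::plogis(theta)
  dy <- 2 * (k1 * hf$m1 + (100 - k1) * mf$m2 - ref) / 4
  gh <- spo2cam:::head_backward(head, hcfg, hf$cache, dy * k1)
  gm <- spo2cam:::mfam_backward_batch(mfam, mf$cache, dy * (100 - k1))
  sg <- stats::plogis(theta)
  gt <- sum(dy * (hf$m1 - mf$m2)) * 100 * sg * (1 - sg)
  eps <- 1e-6
  for (nm in c("conv1.W", "lstm_f.Wx", "lstm_b.Wh", "out.W", "out.b")) {
    for (i in sample(length(head[[nm]]), min(2, length(head[[nm]])))) {
      h2 <- head
      h2[[nm]][i] <- h2[[nm]][i] + eps
      h3 <- head
      h3[[nm]][i] <- h3[[nm]][i] - eps
      expect_equal(gh[[nm]][i], (obj(h2, mfam, theta) - obj(h3, mfam, theta)) / (2 * eps),
                   tolerance = 1e-3)
    }
  }
  for (nm in names(mfam)) {
    i <- sample.int(length(mfam[[nm]]), 1)
    m2p <- mfam
    m2p[[nm]][i] <- m2p[[nm]][i] + eps
    m3 <- mfam
    m3[[nm]][i] <- m3[[nm]][i] - eps
    expect_equal(gm[[nm]][i], (obj(head, m2p, theta) - obj(head, m3, theta)) / (2 * eps),
                 tolerance = 1e-3)
  }
  expect_equal(gt, (obj(head, mfam, theta + eps) - obj(head, mfam, theta - eps)) / (2 * eps),
               tolerance = 1e-3)
})
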