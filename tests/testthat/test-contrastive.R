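test_that("pseudo samples are static, deterministic, and honor zero strength", {
  s <- tiny_scene()
  x_a <- clip_window(s$face_clip, 1, 30)
  p1 <- build_pseudo_sample(x_a, seed = 4)
  p2 <- build_pseudo_sample(x_a, seed = 4)
  expect_identical(p1$frames, p2$frames)
  # every frame equals the first: no temporal (pulsatile) content at all
  for (t in 2:n_frames(p1)) {
    expect_identical(p1$frames[t, , , ], p1$frames[1, , , ])
  }
  p0 <- build_pseudo_sample(x_a, seed = 4, strength = 0)
  matched <- vapply(seq_len(n_frames(x_a)), function(t) {
    identical(p0$frames[1, , , ], x_a$frames[t, , , ])
  }, logical(1))
  expect_true(any(matched))
})

test_that("the static pseudo clip has a flat band spectrum", {
  s <- tiny_scene()
  x_a <- clip_window(s$face_clip, 1, 30)
  pseudo <- build_pseudo_sample(x_a, seed = 4)
  tr <- channel_means(pseudo)[, "G"]
  basis <- spo2cam:::psd_basis(30, 30)
  f <- spo2cam:::psd_feature_forward(matrix(tr, 1), basis)$f
  expect_lte(max(f), 2 * stats::median(f))
})

test_that("positive and negative losses match literal brute-force evaluation", {
  set.seed(9)
  for (n in 1:2) {
    batch <- replicate(n, list(
      f_a = random_psd(), f_b = random_psd(), f_c = random_psd(),
      f_d = random_psd(),
      face_regions = replicate(4, random_psd(), simplify = FALSE),
      hand_regions = replicate(4, random_psd(), simplify = FALSE)
    ), simplify = FALSE)
    bf_regions <- 0
    for (n1 in seq_len(n)) for (n2 in seq_len(n)) for (i in 1:4) for (j in 1:4) {
      bf_regions <- bf_regions +
        sum((batch[[n1]]$hand_regions[[i]] - batch[[n2]]$hand_regions[[j]])^2) +
        sum((batch[[n1]]$face_regions[[i]] - batch[[n2]]$face_regions[[j]])^2)
    }
    bf_st <- mean(vapply(batch, function(s) {
      sum((s$f_a - s$f_b)^2) + sum((s$f_a - s$f_d)^2)
    }, numeric(1)))
    expect_equal(positive_loss(batch), bf_regions / (16 * n^2) + bf_st,
                 tolerance = 1e-9)

    bf_n <- 0
    for (n1 in seq_len(n)) for (n2 in seq_len(n)) {
      bf_n <- bf_n - sum((batch[[n1]]$f_a - batch[[n2]]$f_c)^2)
    }
    expect_equal(negative_loss(batch), bf_n / n^2, tolerance = 1e-9)
  }
})

test_that("loss values honor their analytic anchors and bounds", {
  p <- random_psd()
  same <- list(list(
    f_a = p, f_b = p, f_c = p, f_d = p,
    face_regions = list(p, p, p, p), hand_regions = list(p, p, p, p)
  ))
  expect_equal(positive_loss(same), 0)
  expect_equal(negative_loss(same), 0)

  expect_equal(
    negative_loss(list(list(f_a = c(1, 0), f_c = c(0, 1)))), -2
  )

  set.seed(11)
  for (i in 1:10) {
    batch <- replicate(2, list(
      f_a = random_psd(), f_b = random_psd(), f_c = random_psd(),
      f_d = random_psd(),
      face_regions = replicate(4, random_psd(), simplify = FALSE),
      hand_regions = replicate(4, random_psd(), simplify = FALSE)
    ), simplify = FALSE)
    expect_gte(positive_loss(batch), 0)
    ln <- negative_loss(batch)
    expect_lte(ln, 0)
    expect_gte(ln, -4)
  }
})

test_that("positive loss is invariant to batch and region permutations", {
  set.seed(13)
  batch <- replicate(3, list(
    f_a = random_psd(), f_b = random_psd(), f_c = random_psd(),
    f_d = random_psd(),
    face_regions = replicate(4, random_psd(), simplify = FALSE),
    hand_regions = replicate(4, random_psd(), simplify = FALSE)
  ), simplify = FALSE)
  v0 <- positive_loss(batch)
  expect_equal(positive_loss(batch[c(3, 1, 2)]), v0, tolerance = 1e-12)
  permuted <- lapply(batch, function(s) {
    s$hand_regions <- s$hand_regions[c(2, 4, 1, 3)]
    s$face_regions <- s$face_regions[c(4, 3, 2, 1)]
    s
  })
  expect_equal(positive_loss(permuted), v0, tolerance = 1e-12)
})

test_that("PSD grid mismatches raise shape errors", {
  bad <- list(list(
    f_a = random_psd(12), f_b = random_psd(10), f_c = random_psd(12),
    f_d = random_psd(12),
    face_regions = replicate(4, random_psd(12), simplify = FALSE),
    hand_regions = replicate(4, random_psd(12), simplify = FALSE)
  ))
  expect_error(positive_loss(bad), class = "spo2cam_error_shape")
})

test_that("supervised loss hits 0 / 2 / 4 at its analytic anchors", {
  t <- seq(0, 2 - 1 / 30, by = 1 / 30)
  ref <- sin(2 * pi * t)
  orth <- cos(2 * pi * t)
  y_ref <- matrix(rep(ref, each = 6), 6)
  y_orth <- matrix(rep(orth, each = 6), 6)
  expect_equal(supervised_loss(y_ref, y_ref, ref, ref), 0, tolerance = 1e-9)
  expect_equal(supervised_loss(y_orth, y_orth, ref, ref), 2, tolerance = 1e-9)
  expect_equal(supervised_loss(-y_ref, -y_ref, ref, ref), 4, tolerance = 1e-9)
  set.seed(3)
  for (i in 1:10) {
    a <- matrix(rnorm(6 * 20), 6)
    b <- matrix(rnorm(6 * 20), 6)
    l <- supervised_loss(a, b, rnorm(20), rnorm(20))
    expect_gte(l, 0)
    expect_lte(l, 4)
  }
  expect_error(supervised_loss(y_ref * 0, y_ref, ref, ref),
               class = "spo2cam_error_degenerate_signal")
})

test_that("contrastive tuples carry four half-windows and eight quadrants", {
  s <- tiny_scene()
  face <- clip_window(s$face_clip, 1, 60)
  hand <- clip_window(s$hand_clip, 1, 60)
  tp <- make_contrastive_tuple(face, hand, seed = 2)
  for (nm in c("x_a", "x_b", "x_c", "x_d")) {
    expect_equal(n_frames(tp[[nm]]), 30)
  }
  expect_length(tp$face_regions, 4)
  expect_length(tp$hand_regions, 4)
  expect_identical(tp$x_a$frames, face$frames[1:30, , , , drop = FALSE])
  expect_identical(tp$x_d$frames, face$frames[31:60, , , , drop = FALSE])
  expect_error(make_contrastive_tuple(clip_window(face, 1, 30), hand),
               class = "spo2cam_error_shape")
})

test_that("stage-1 training reduces the contrastive loss deterministically", {
  s <- tiny_scene_noisy()
  roi_face <- crop_resize(s$face_clip, s$face_box, out_size = 16)
  roi_hand <- crop_resize(s$hand_clip, s$hand_box, out_size = 16)
  tuples <- lapply(c(1, 61), function(st) {
    make_contrastive_tuple(clip_window(roi_face, st, 60),
                           clip_window(roi_hand, st, 60), seed = st)
  })
  est <- build_estimator(rppg_config(input_size = 16, width = 0.125), seed = 1)
  cfg <- stage_config(lr = 0.001, epochs = 4, batch_size = 2, seed = 5)
  r1 <- train_stage1(est, tuples, cfg)
  expect_lt(r1$history$loss[4], r1$history$loss[1])
  r2 <- train_stage1(est, tuples, cfg)
  expect_identical(r1$history, r2$history)
  expect_error(train_stage1(est, list(), cfg), class = "spo2cam_error_data")
})

test_that("supervised fine-tuning improves channel-mean similarity", {
  s <- tiny_scene_noisy()
  roi <- crop_resize(s$face_clip, s$face_box, out_size = 16)
  lab <- prepare_labels(s$ppg, s$spo2_trace, roi)
  win <- clip_window(roi, 1, 120)
  ppg <- waveform(lab$ppg$samples[1:120], 30)
  est <- build_estimator(rppg_config(input_size = 16, width = 0.125), seed = 4)
  sim_before <- cosine_similarity(colMeans(rppg_forward(est, win)$signals),
                                  ppg$samples)
  res <- train_stage2(est, list(list(face = win, ppg = ppg)),
                      stage_config(lr = 1e-3, epochs = 15, batch_size = 1, seed = 2))
  sim_after <- cosine_similarity(colMeans(rppg_forward(res$est, win)$signals),
                                 ppg$samples)
  expect_gt(sim_after, sim_before)
  expect_true(all(is.finite(res$history$loss_s)))
})

test_that("sustained fine-tuning on one clip overfits it (similarity > 0.9)", {
  s <- tiny_scene_noisy()
  roi <- crop_resize(s$face_clip, s$face_box, out_size = 16)
  lab <- prepare_labels(s$ppg, s$spo2_trace, roi)
  win <- clip_window(roi, 1, 120)
  ppg <- waveform(lab$ppg$samples[1:120], 30)
  est <- build_estimator(rppg_config(input_size = 16, width = 0.25), seed = 2)
  res <- train_stage2(est, list(list(face = win, ppg = ppg)),
                      stage_config(lr = 1e-3, epochs = 100, batch_size = 1, seed = 1))
  sim <- cosine_similarity(colMeans(rppg_forward(res$est, win)$signals),
                           ppg$samples)
  expect_gt(sim, 0.9)
})
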