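test_that("skin-color detection recovers the generator's region", {
  s <- tiny_scene()
  short <- clip_window(s$face_clip, 1, 30)
  boxes <- detect_roi(short, "face", "skin")
  expect_equal(nrow(boxes), 30)
  for (t in seq_len(nrow(boxes))) {
    expect_gt(box_iou(boxes[t, ], s$face_box), 0.7)
  }
})

test_that("fixed and functional detectors pass boxes through", {
  s <- tiny_scene()
  short <- clip_window(s$hand_clip, 1, 10)
  bx <- c(4, 6, 40, 44)
  boxes <- detect_roi(short, "hand", "fixed", box = bx)
  expect_true(all(boxes == matrix(bx, 10, 4, byrow = TRUE)))
  fn <- function(frame) c(0, 0, dim(frame)[2], dim(frame)[1])
  boxes2 <- detect_roi(short, "hand", fn)
  expect_equal(boxes2[1, ], c(x0 = 0, y0 = 0, x1 = 48, y1 = 48))
  expect_error(detect_roi(short, "hand", "fixed"),
               class = "spo2cam_error_invalid_parameter")
})

test_that("an all-background clip raises a detection failure naming the frame", {
  bg <- video_clip(array(0.3, c(5, 16, 16, 3)), 30)
  err <- expect_error(detect_roi(bg, "face", "skin"),
                      class = "spo2cam_error_detection_failure")
  expect_match(conditionMessage(err), "frame 1")
})

test_that("crop_resize always yields the requested square resolution", {
  s <- tiny_scene()
  short <- clip_window(s$face_clip, 1, 10)
  for (out in c(128, 32)) {
    cr <- crop_resize(short, s$face_box, out_size = out)
    expect_equal(dim(cr$frames), c(10, out, out, 3))
  }
  skew <- crop_resize(short, c(3, 10, 20, 45), out_size = 24)
  expect_equal(dim(skew$frames), c(10, 24, 24, 3))
  expect_true(all(skew$frames >= 0 & skew$frames <= 1))
})

test_that("full-frame crop at native size is the identity and constants stay constant", {
  s <- tiny_scene()
  short <- clip_window(s$face_clip, 1, 5)
  d <- dim(short$frames)
  same <- crop_resize(short, c(0, 0, d[3], d[2]), out_size = d[2])
  expect_lt(max(abs(same$frames - short$frames)), 1e-6)

  const <- video_clip(array(0.4, c(3, 20, 20, 3)), 30)
  cr <- crop_resize(const, c(2, 3, 15, 17), out_size = 8)
  expect_lt(max(abs(cr$frames - 0.4)), 1e-9)
})

test_that("crop_resize validates boxes", {
  s <- tiny_scene()
  short <- clip_window(s$face_clip, 1, 5)
  expect_error(crop_resize(short, c(5, 5, 5, 20), out_size = 16),
               class = "spo2cam_error_invalid_parameter")
  expect_warning(crop_resize(short, c(-4, 0, 40, 40), out_size = 16),
                 "clipped")
  expect_error(crop_resize(short, matrix(1, 3, 4), out_size = 16),
               class = "spo2cam_error_shape")
})

test_that("quadrant split partitions the frame and reassembles exactly", {
  s <- tiny_scene()
  short <- clip_window(s$face_clip, 1, 20)
  q <- split_quadrants(short)
  expect_named(q, c("tl", "tr", "bl", "br"))
  expect_equal(dim(q$tl$frames), c(20, 24, 24, 3))
  top <- abind_frames(q$tl$frames, q$tr$frames, along = 3)
  bottom <- abind_frames(q$bl$frames, q$br$frames, along = 3)
  whole <- abind_frames(top, bottom, along = 2)
  expect_identical(whole, short$frames)

  odd <- video_clip(array(0.5, c(3, 15, 16, 3)), 30)
  expect_error(split_quadrants(odd), class = "spo2cam_error_invalid_parameter")
})

test_that("quadrant traces of a synthetic face share the cardiac PSD peak", {
  s <- tiny_scene()
  q <- split_quadrants(s$face_clip)
  peaks <- vapply(q, function(cl) {
    tr <- channel_means(cl)[, "G"]
    psd_peak(compute_psd(waveform(tr, cl$rate)))
  }, numeric(1))
  expect_true(all(peaks == peaks[1]))
  expect_equal(unname(peaks[1]), s$meta$hr_bpm / 60, tolerance = 1 / 4 + 1e-9)
})

test_that("label preparation aligns PPG and aggregates SpO2 per window", {
  s <- tiny_scene()
  roi <- crop_resize(s$face_clip, s$face_box, out_size = 16)
  # a 60 Hz reference PPG covering the clip
  t60 <- seq(0, duration(s$ppg), by = 1 / 60)
  f <- s$meta$hr_bpm / 60
  ppg60 <- waveform(sin(2 * pi * f * t60) + 0.3 * sin(4 * pi * f * t60), 60)
  lab <- prepare_labels(ppg60, s$spo2_trace, roi, window_frames = 60)
  expect_equal(lab$ppg$rate, 30)
  expect_equal(length(lab$ppg$samples), n_frames(roi))
  expect_lt(abs(mean(lab$ppg$samples)), 0.05)
  expect_equal(nrow(lab$windows), 2)
  expect_true(all(lab$windows$spo2 == 97))

  pk_before <- psd_peak(compute_psd(waveform(ppg60$samples, 60)))
  pk_after <- psd_peak(compute_psd(lab$ppg))
  expect_equal(pk_after, pk_before, tolerance = 1 / 4 + 1e-9)

  short_ppg <- waveform(sin(2 * pi * 1.2 * seq(0, 1, by = 1 / 30)), 30)
  expect_error(prepare_labels(short_ppg, s$spo2_trace, roi),
               class = "spo2cam_error_alignment")
})

test_that("box CSV round-trip is exact", {
  s <- tiny_scene()
  boxes <- detect_roi(clip_window(s$face_clip, 1, 5), detector = "fixed",
                      box = s$face_box)
  path <- withr::local_tempfile(fileext = ".csv")
  write_boxes_csv(boxes, path)
  expect_equal(unname(read_boxes_csv(path)), unname(boxes))
})
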