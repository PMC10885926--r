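# Shared fixtures, all generated in code. Heavier objects are built lazily
# and cached for the session so several test files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# a small clean scene used across preprocess / synthetic tests
tiny_scene <- function() {
  fixture("tiny_scene", function() {
    generate_sample(scene_config(
      duration_s = 4, size = 48, hr_bpm = 72, noise_sd = 0, seed = 101
    ))
  })
}

# the same scene with sensor noise
tiny_scene_noisy <- function() {
  fixture("tiny_scene_noisy", function() {
    generate_sample(scene_config(
      duration_s = 4, size = 48, hr_bpm = 72, noise_sd = 0.003, seed = 102
    ))
  })
}

# a small random-weights estimator for structural tests
tiny_estimator <- function() {
  fixture("tiny_estimator", function() {
    build_estimator(rppg_config(input_size = 16, width = 0.125), seed = 7)
  })
}

# ultra-small experiment profile for plumbing tests (not a learning test)
tiny_experiment_cfg <- function(...) {
  experiment_config(
    n_subjects = 3, duration_s = 8, frame_size = 48, roi_size = 16,
    width = 0.125, epochs = c(1, 1, 4), tuples_per_subject = 1,
    supervised_per_subject = 1, hidden = 8, conv_channels = c(4, 8),
    seed = 11, ...
  )
}

random_psd <- function(n = 12) {
  p <- stats::runif(n)
  p / sum(p)
}

box_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

# bind two T x H x W x 3 arrays along a spatial dimension
abind_frames <- function(a, b, along) {
  da <- dim(a)
  db <- dim(b)
  dn <- da
  dn[along] <- da[along] + db[along]
  out <- array(0, dn)
  idx_a <- lapply(seq_along(dn), function(i) seq_len(da[i]))
  idx_b <- lapply(seq_along(dn), function(i) seq_len(db[i]))
  idx_b[[along]] <- da[along] + seq_len(db[along])
  out[idx_a[[1]], idx_a[[2]], idx_a[[3]], idx_a[[4]]] <- a
  out[idx_b[[1]], idx_b[[2]], idx_b[[3]], idx_b[[4]]] <- b
  out
}
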