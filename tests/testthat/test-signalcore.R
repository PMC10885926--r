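make_sine <- function(freq, dur = 20, rate = 30, phase = 0) {
  waveform(sin(2 * pi * freq * seq(0, dur, by = 1 / rate) + phase), rate)
}

central <- function(w, edge_s = 1) {
  n <- length(w$samples)
  k <- round(edge_s * w$rate)
  w$samples[(k + 1):(n - k)]
}

test_that("band-pass FIR preserves in-band sinusoids and rejects DC / out-of-band", {
  for (f in c(0.5, 1.5, 3, 4)) {
    y <- bandpass_fir(make_sine(f), 0.5, 4)
    amp <- max(abs(central(y)))
    expect_gte(amp, 0.9)
    expect_lte(amp, 1.1)
  }
  dc <- bandpass_fir(waveform(rep(1, 601), 30), 0.5, 4)
  expect_lt(max(abs(central(dc))), 0.05)
  hi <- bandpass_fir(make_sine(8), 0.5, 4)
  expect_lte(max(abs(central(hi))), 0.1)
})

test_that("band-pass FIR validates band and length", {
  w <- make_sine(1.5)
  expect_error(bandpass_fir(w, 0.5, 20), class = "spo2cam_error_invalid_parameter")
  expect_error(bandpass_fir(w, -1, 4), class = "spo2cam_error_invalid_parameter")
  short <- waveform(rnorm(100), 30)
  expect_error(bandpass_fir(short, 0.5, 4), class = "spo2cam_error_insufficient_length")
})

test_that("resampling preserves duration, identity, and spectral content", {
  w <- waveform(rnorm(600), 60)
  r <- resample(w, 30)
  expect_equal(r$rate, 30)
  expect_equal(length(r$samples), 300)

  same <- resample(w, 60)
  expect_identical(same$samples, w$samples)

  s <- waveform(sin(2 * pi * 1 * seq(0, 10, by = 0.01)), 100)
  r2 <- resample(s, 30)
  expect_equal(psd_peak(compute_psd(r2)), 1, tolerance = 1 / duration(r2))

  expect_error(resample(w, -5), class = "spo2cam_error_invalid_parameter")
})

test_that("normalize standardizes and is idempotent", {
  w <- normalize(waveform(c(1, 2, 3), 10))
  expect_equal(mean(w$samples), 0, tolerance = 1e-9)
  expect_equal(stats::sd(w$samples), 1, tolerance = 1e-9)
  w2 <- normalize(w)
  expect_equal(w2$samples, w$samples, tolerance = 1e-9)
  expect_error(normalize(waveform(rep(2, 10), 10)),
               class = "spo2cam_error_degenerate_signal")
})

test_that("PSD is band-limited, normalized, phase- and amplitude-invariant", {
  w <- make_sine(1.2, dur = 10)
  p <- compute_psd(w)
  expect_equal(psd_peak(p), 1.2, tolerance = 1 / duration(w))
  expect_equal(sum(p$power), 1, tolerance = 1e-9)
  expect_true(all(p$freqs >= 0.5 & p$freqs <= 4))
  expect_true(all(diff(p$freqs) > 0))

  shifted <- compute_psd(make_sine(1.2, dur = 10, phase = pi / 2))
  expect_lt(sum(abs(p$power - shifted$power)), 0.05)

  scaled <- compute_psd(waveform(5 * w$samples, w$rate))
  expect_equal(scaled$power, p$power, tolerance = 1e-12)

  expect_error(compute_psd(waveform(rep(0, 300), 30)),
               class = "spo2cam_error_degenerate_signal")
  expect_error(compute_psd(make_sine(1.2, dur = 2)),
               class = "spo2cam_error_insufficient_length")
})

test_that("cosine similarity matches its definition and guards its domain", {
  x <- c(0.3, -1, 2, 4)
  expect_equal(cosine_similarity(x, x), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2, 3), c(4, 5, 6)), 0.9746, tolerance = 1e-4)
  expect_equal(cosine_similarity(x, 3 * x), 1)
  expect_equal(cosine_similarity(x, -2 * x), -1)
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), class = "spo2cam_error_shape")
  expect_error(cosine_similarity(c(0, 0), c(1, 2)),
               class = "spo2cam_error_degenerate_signal")
})

test_that("agreement metrics match hand-computed values and RMSE >= MAE always", {
  m <- spo2_metrics(c(95, 97), c(96, 96))
  expect_equal(m$mae, 1)
  expect_equal(m$rmse, 1)
  expect_true(is.na(m$pearson))  # constant reference: correlation undefined

  r <- c(94, 96, 98, 97)
  m2 <- spo2_metrics(r, r)
  expect_equal(m2$mae, 0)
  expect_equal(m2$rmse, 0)
  expect_equal(m2$pearson, 1)

  m3 <- spo2_metrics(r + 1, r)
  expect_equal(m3$mae, 1)
  expect_equal(m3$rmse, 1)
  expect_equal(m3$pearson, 1)

  set.seed(42)
  for (i in 1:25) {
    a <- rnorm(10, 96, 2)
    b <- rnorm(10, 96, 2)
    mm <- spo2_metrics(a, b)
    expect_gte(mm$rmse, mm$mae)
    expect_gte(mm$pearson, -1)
    expect_lte(mm$pearson, 1)
  }

  expect_error(spo2_metrics(1:3, 1:4), class = "spo2cam_error_shape")
  expect_true(is.na(spo2_metrics(c(96, 96), c(95, 97))$pearson))
})

test_that("band-passed broadband noise concentrates PSD power inside the band", {
  set.seed(7)
  w <- waveform(rnorm(900), 30)
  f <- bandpass_fir(w, 0.5, 4)
  p <- compute_psd(f, band = c(0.25, 14.9))
  in_band <- p$freqs >= 0.5 & p$freqs <= 4
  expect_gte(sum(p$power[in_band]), 0.95)
})

test_that("waveform and PSD CSV round-trips preserve data", {
  w <- make_sine(1.1, dur = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(w, path)
  r <- read_waveform_csv(path)
  expect_equal(r$rate, w$rate, tolerance = 1e-6)
  expect_equal(r$samples, w$samples, tolerance = 1e-6)

  p <- compute_psd(w)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_psd_csv(p, path2)
  back <- utils::read.csv(path2)
  expect_equal(back$power, p$power, tolerance = 1e-6)
})
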