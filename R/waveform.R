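#' Sampled waveform
#'
#' A `waveform` is the package's unit of 1-D signal: a finite numeric sample
#' vector together with its sampling rate in Hz. It carries reference
#' photoplethysmograms (PPG), per-channel intensity traces extracted from
#' video, and the multi-channel rPPG signals produced by the estimator.
#'
#' @param samples Numeric vector of at least two finite samples.
#' @param rate Sampling frequency in Hz (> 0).
#' @return An object of class `waveform` with fields `samples` and `rate`.
#' @examples
#' w <- waveform(sin(2 * pi * 1.2 * seq(0, 10, by = 1 / 30)), rate = 30)
#' duration(w)
#' @export
waveform <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate <= 0) {
    stop_invalid_parameter("`rate` must be a single positive number (Hz).")
  }
  if (length(samples) < 2) {
    stop_insufficient_length("a waveform needs at least 2 samples.")
  }
  if (!all(is.finite(samples))) {
    stop_degenerate_signal("waveform samples must all be finite.")
  }
  structure(list(samples = samples, rate = as.numeric(rate)), class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf(
    "<waveform> %d samples @ %g Hz (%.2f s)\n",
    length(x$samples), x$rate, duration(x)
  ))
  invisible(x)
}

#' @export
length.waveform <- function(x) length(x$samples)

#' Duration of a waveform in seconds
#' @param w A [waveform()].
#' @return Length in seconds (`n / rate`).
#' @export
duration <- function(w) length(w$samples) / w$rate

as_waveform <- function(x, rate) {
  if (inherits(x, "waveform")) x else waveform(x, rate)
}

#' Zero-phase FIR band-pass filter
#'
#' Filters a waveform with a linear-phase windowed-sinc band-pass filter
#' applied forward and backward (zero phase, same length output). The default
#' band of 0.5--4 Hz covers the human cardiac fundamental (0.5--2.5 Hz
#' heart-rate range) and its second harmonic. The design cut-offs are widened
#' slightly beyond `low_hz`/`high_hz` so that, after the double pass,
#' sinusoids anywhere inside the nominal band keep at least 90% of their
#' amplitude while DC and out-of-band components are attenuated below 10%.
#' The first and last second of the output contain edge transients and should
#' be discarded in amplitude-sensitive use.
#'
#' @param w A [waveform()].
#' @param low_hz,high_hz Pass-band edges in Hz; `0 < low_hz < high_hz < rate/2`.
#' @param order Filter order; default `4 * rate / low_hz` rounded to the
#'   nearest odd integer.
#' @return A filtered [waveform()] of the same length and rate.
#' @export
bandpass_fir <- function(w, low_hz = 0.5, high_hz = 4, order = NULL) {
  w <- as_waveform(w, NULL)
  nyq <- w$rate / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop_invalid_parameter(sprintf(
      "band [%g, %g] Hz must satisfy 0 < low < high < Nyquist (%g Hz).",
      low_hz, high_hz, nyq
    ))
  }
  if (is.null(order)) {
    order <- round(4 * w$rate / low_hz)
    if (order %% 2 == 0) order <- order + 1
  }
  n <- length(w$samples)
  if (n <= order) {
    stop_insufficient_length(sprintf(
      "waveform (%d samples) must be longer than the filter order (%d).", n, order
    ))
  }
  # Widened design cut-offs: the windowed-sinc transition band (about
  # 3.3 * rate / order Hz for a Hamming window) is placed outside the nominal
  # pass band so the band edges themselves sit in the flat region.
  tw <- 3.3 * w$rate / order
  lo_d <- max(low_hz - tw / 2, low_hz / 4)
  hi_d <- min(high_hz + tw / 2, nyq * 0.98)
  b <- signal::fir1(order, c(lo_d, hi_d) / nyq, type = "pass")
  x <- w$samples
  # forward-backward with reflection padding to tame edge transients
  pad <- min(n - 1, order)
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x, 2 * x[n] - rev(x[(n - pad):(n - 1)]))
  y <- signal::filtfilt(as.numeric(b), 1, xp)
  waveform(y[(pad + 1):(pad + n)], w$rate)
}

#' Resample a waveform to a new rate
#'
#' Linear-interpolation resampling onto a uniform grid at `target_rate`.
#' The duration is preserved to within one sample period; when
#' `target_rate == rate` the samples are returned unchanged.
#'
#' @param w A [waveform()].
#' @param target_rate New sampling rate in Hz (> 0).
#' @return A [waveform()] at `target_rate`.
#' @export
resample <- function(w, target_rate) {
  w <- as_waveform(w, NULL)
  if (!is.numeric(target_rate) || length(target_rate) != 1 ||
      !is.finite(target_rate) || target_rate <= 0) {
    stop_invalid_parameter("`target_rate` must be a single positive number (Hz).")
  }
  if (target_rate == w$rate) {
    return(w)
  }
  n_in <- length(w$samples)
  n_out <- max(2L, round(n_in * target_rate / w$rate))
  t_in <- (seq_len(n_in) - 1) / w$rate
  t_out <- (seq_len(n_out) - 1) / target_rate
  y <- stats::approx(t_in, w$samples, xout = t_out, rule = 2)$y
  waveform(y, target_rate)
}

#' Standardize a waveform to zero mean, unit standard deviation
#'
#' @param w A [waveform()].
#' @return A [waveform()] with mean 0 and standard deviation 1.
#' @export
normalize <- function(w) {
  w <- as_waveform(w, NULL)
  s <- stats::sd(w$samples)
  if (!is.finite(s) || s == 0) {
    stop_degenerate_signal("cannot normalize a constant waveform.")
  }
  waveform((w$samples - mean(w$samples)) / s, w$rate)
}

#' Band-limited normalized power spectral density
#'
#' Computes a Hann-windowed periodogram of the (mean-removed) waveform,
#' restricts it to the analysis band, and L1-normalizes it so the retained
#' power sums to one. The PSD is phase-invariant and, because of the
#' normalization, amplitude-invariant; it is the feature the contrastive
#' losses operate on.
#'
#' @param w A [waveform()].
#' @param band Two-element numeric, band edges in Hz (default cardiac band
#'   0.5--4 Hz).
#' @param nfft FFT length; defaults to the signal length. Larger values
#'   zero-pad for a finer frequency grid.
#' @return An object of class `psd` with fields `power` (sums to 1) and
#'   `freqs` (strictly increasing, inside `band`).
#' @export
compute_psd <- function(w, band = c(0.5, 4), nfft = NULL) {
  w <- as_waveform(w, NULL)
  nyq <- w$rate / 2
  if (length(band) != 2 || !(band[1] > 0 && band[1] < band[2] && band[2] <= nyq)) {
    stop_invalid_parameter("`band` must satisfy 0 < low < high <= Nyquist.")
  }
  if (all(w$samples == 0)) {
    stop_degenerate_signal("cannot compute the PSD of an all-zero waveform.")
  }
  if (duration(w) < 2 / band[1]) {
    stop_insufficient_length(sprintf(
      "waveform must span at least 2 cycles of the band floor (%.1f s).", 2 / band[1]
    ))
  }
  n <- length(w$samples)
  if (is.null(nfft)) nfft <- n
  nfft <- max(nfft, n)
  x <- w$samples - mean(w$samples)
  win <- hann_window(n)
  xf <- c(x * win, numeric(nfft - n))
  p <- Mod(stats::fft(xf))^2
  freqs <- (seq_len(nfft) - 1) * w$rate / nfft
  keep <- freqs >= band[1] & freqs <= band[2]
  if (!any(keep)) {
    stop_invalid_parameter("no frequency bins fall inside `band`; use a larger nfft.")
  }
  power <- p[keep]
  tot <- sum(power)
  if (tot == 0) {
    stop_degenerate_signal("waveform has no power inside the analysis band.")
  }
  structure(list(power = power / tot, freqs = freqs[keep]), class = "psd")
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

#' @export
print.psd <- function(x, ...) {
  cat(sprintf(
    "<psd> %d bins over [%.3g, %.3g] Hz, peak at %.3g Hz\n",
    length(x$power), min(x$freqs), max(x$freqs), psd_peak(x)
  ))
  invisible(x)
}

#' Frequency of the PSD maximum
#' @param p A `psd` object from [compute_psd()].
#' @return The frequency (Hz) of the largest power bin.
#' @export
psd_peak <- function(p) p$freqs[which.max(p$power)]

#' Cosine similarity between two signals
#'
#' `sim(A, B) = (A . B) / (||A|| ||B||)`, the similarity measure used by the
#' supervised rPPG fine-tuning loss.
#'
#' @param a,b Numeric vectors or [waveform()]s of equal length, neither of
#'   zero norm.
#' @return A number in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  if (inherits(a, "waveform")) a <- a$samples
  if (inherits(b, "waveform")) b <- b$samples
  if (length(a) != length(b)) {
    stop_shape(sprintf("lengths differ (%d vs %d).", length(a), length(b)))
  }
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop_degenerate_signal("cosine similarity is undefined for a zero-norm signal.")
  }
  s <- sum(a * b) / (na * nb)
  max(-1, min(1, s))
}

#' Agreement metrics between predicted and reference SpO2 series
#'
#' Mean absolute error, root-mean-square error, and the Pearson correlation
#' coefficient, the three metrics used throughout the evaluation protocol.
#'
#' @param pred,ref Equal-length numeric vectors (length >= 2) on the percent
#'   scale.
#' @return A one-row [tibble::tibble()] with columns `mae`, `rmse`, `pearson`
#'   (`NA` when either series is constant, where correlation is undefined).
#' @export
spo2_metrics <- function(pred, ref) {
  pred <- as.numeric(pred)
  ref <- as.numeric(ref)
  if (length(pred) != length(ref)) {
    stop_shape(sprintf("lengths differ (%d vs %d).", length(pred), length(ref)))
  }
  if (length(pred) < 2) {
    stop_insufficient_length("need at least 2 paired values.")
  }
  err <- pred - ref
  mae <- mean(abs(err))
  rmse <- sqrt(mean(err^2))
  # MAE/RMSE are always defined; the correlation of a constant series is not
  pearson <- if (stats::sd(pred) > 0 && stats::sd(ref) > 0) {
    stats::cor(pred, ref)
  } else {
    NA_real_
  }
  tibble::tibble(mae = mae, rmse = rmse, pearson = pearson)
}

#' Read / write waveforms as two-column CSV
#'
#' The on-disk exchange format is a plain CSV with columns `time_s` and
#' `value`; the sampling rate is recovered from the time column.
#'
#' @param w A [waveform()].
#' @param path File path.
#' @return `write_waveform_csv()` returns `path` invisibly;
#'   `read_waveform_csv()` returns a [waveform()].
#' @export
write_waveform_csv <- function(w, path) {
  n <- length(w$samples)
  df <- data.frame(time_s = (seq_len(n) - 1) / w$rate, value = w$samples)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df)) || nrow(df) < 2) {
    stop_data(sprintf("'%s' is not a two-column (time_s, value) waveform CSV.", path))
  }
  dt <- diff(df$time_s)
  waveform(df$value, rate = 1 / stats::median(dt))
}

#' Write a PSD as two-column CSV (`freq_hz`, `power`)
#' @param p A `psd` object.
#' @param path File path.
#' @export
write_psd_csv <- function(p, path) {
  utils::write.csv(data.frame(freq_hz = p$freqs, power = p$power), path,
    row.names = FALSE
  )
  invisible(path)
}
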