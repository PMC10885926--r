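# Plotting conveniences (ggplot2 is a suggested dependency).

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_config("plotting requires the 'ggplot2' package.")
  }
}

#' Plot a waveform
#' @param object A [waveform()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.waveform <- function(object, ...) {
  need_ggplot()
  df <- data.frame(
    time_s = (seq_along(object$samples) - 1) / object$rate,
    value = object$samples
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "amplitude")
}

#' Plot a normalized band-limited PSD
#' @param object A `psd` from [compute_psd()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.psd <- function(object, ...) {
  need_ggplot()
  df <- data.frame(freq_hz = object$freqs, power = object$power)
  ggplot2::ggplot(df, ggplot2::aes(.data$freq_hz, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = psd_peak(object), linetype = 2) +
    ggplot2::labs(x = "frequency (Hz)", y = "normalized power")
}

#' Plot per-subject evaluation metrics
#' @param object A `spo2cam_eval` report from [leave_one_out()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.spo2cam_eval <- function(object, ...) {
  need_ggplot()
  df <- data.frame(
    subject = rep(object$subject, 2),
    metric = rep(c("MAE", "RMSE"), each = nrow(object)),
    value = c(object$mae, object$rmse)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$subject, .data$value, fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "error (% SpO2)")
}

#' Plot a training-loss history
#' @param history A tibble with an `epoch` column and one or more loss
#'   columns (as returned by the training stages).
#' @return A ggplot object.
#' @export
plot_loss_history <- function(history) {
  need_ggplot()
  cols <- setdiff(names(history), "epoch")
  df <- do.call(rbind, lapply(cols, function(cn) {
    data.frame(epoch = history$epoch, loss = history[[cn]], term = cn)
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss, colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss")
}
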