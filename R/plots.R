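#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the package's result
#' types: an event raster for streams, the training log for fits, the
#' accuracy-versus-window curve, and an output spike raster for readouts.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name fscoding-plots
NULL

#' @rdname fscoding-plots
#' @export
autoplot.event_stream <- function(object, ...) {
  modality <- attr(object, "modality")
  df <- as_tibble(object)
  if (modality == "audio") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$channel)) +
      ggplot2::geom_point(shape = "|", size = 2) +
      ggplot2::labs(x = "time [s]", y = "channel",
                    title = "Event raster")
  } else {
    df$polarity <- factor(ifelse(df$p > 0, "+1", "-1"), levels = c("+1", "-1"))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$y,
                                     colour = .data$polarity)) +
      ggplot2::geom_point(shape = "|", size = 2) +
      ggplot2::scale_colour_manual(values = c("+1" = "#1f77b4", "-1" = "#d62728")) +
      ggplot2::labs(x = "time [s]", y = "row", colour = "polarity",
                    title = "Event raster (rows over time)")
  }
}

#' @rdname fscoding-plots
#' @export
autoplot.fs_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, c("loss", "accuracy"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = sprintf("%s training", toupper(object$cfg$loss_mode)))
}

#' @rdname fscoding-plots
#' @param dt Step width in seconds, for the time axis.
#' @param p Peak fractions (percent) to mark as time delays.
#' @param curve A tibble from [accuracy_vs_window()].
#' @export
plot_accuracy_vs_window <- function(curve, dt = NULL, p = c(50, 90)) {
  if (is.null(dt)) dt <- curve$time[1] / curve$T_prime[1]
  g <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$time, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "observation window [s]", y = "accuracy",
                  title = "Accuracy vs. observation window")
  for (pp in p) {
    td <- time_delay(curve, pp, dt)
    g <- g + ggplot2::geom_vline(xintercept = td$time,
                                 linetype = if (pp == 50) "dashed" else "dotted")
  }
  g
}

#' @rdname fscoding-plots
#' @param trajectories An `"fs_trajectories"`.
#' @param trial Trial index.
#' @export
plot_output_raster <- function(trajectories, trial = 1L) {
  out <- trajectories[[length(trajectories)]]
  T <- attr(trajectories, "T")
  dt <- attr(trajectories, "dt")
  S <- matrix(out$S[, , trial], ncol = T)
  idx <- which(S == 1, arr.ind = TRUE)
  df <- tibble(neuron = idx[, 1], time = idx[, 2] * dt)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$neuron)) +
    ggplot2::geom_point(shape = "|", size = 3) +
    ggplot2::scale_y_continuous(breaks = seq_len(nrow(S)),
                                limits = c(0.5, nrow(S) + 0.5)) +
    ggplot2::labs(x = "time [s]", y = "output neuron",
                  title = "Output spike raster")
}
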