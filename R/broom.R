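#' Tidy a trained spiking network
#'
#' One row per layer with its kind, size, neuron parameters and weight-scale
#' summaries.
#'
#' @param x An `"fs_fit"`.
#' @param ... Unused.
#' @return A tibble with columns `layer, kind, neurons, tau, theta,
#'   w_rms, v_rms`.
#' @export
tidy.fs_fit <- function(x, ...) {
  rows <- lapply(seq_along(x$net$layers), function(i) {
    l <- x$net$layers[[i]]
    tibble(
      layer = i, kind = l$kind, neurons = l$Q,
      tau = if (is.null(l$params)) NA_real_ else l$params$tau,
      theta = if (is.null(l$params)) NA_real_ else l$params$theta,
      w_rms = if (is.null(l$W)) NA_real_ else sqrt(mean(l$W^2)),
      v_rms = if (is.null(l$V)) NA_real_ else sqrt(mean(l$V^2))
    )
  })
  dplyr::bind_rows(rows)
}

#' Glance at a trained spiking network
#'
#' @param x An `"fs_fit"`.
#' @param ... Unused.
#' @return A one-row tibble: loss mode, epochs, final training loss and
#'   accuracy, mean spike count, and the training window length.
#' @export
glance.fs_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  tibble(loss_mode = x$cfg$loss_mode, epochs = nrow(x$log),
         loss = last$loss, accuracy = last$accuracy, n_s = last$n_s,
         T_train = x$T_train, dt = x$dt)
}

#' Tidy an evaluation result
#' @param x An `"fs_eval"`.
#' @param ... Unused.
#' @return The per-trial predictions tibble.
#' @export
tidy.fs_eval <- function(x, ...) x$predictions

#' @rdname tidy.fs_eval
#' @export
glance.fs_eval <- function(x, ...) {
  tibble(mode = x$mode, accuracy = x$accuracy, n_s = x$n_s,
         n_trials = nrow(x$predictions))
}
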