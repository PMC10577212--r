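#' Evaluate a trained network
#'
#' Simulates every trial over the given window (no empty-sequence extension:
#' evaluation uses the configured test window as-is) and reports accuracy,
#' per-trial predictions and the mean spike count.
#'
#' @param fit An `"fs_fit"` from [train()], or a bare `"fs_network"`.
#' @param data List of [spike_tensor()]s or an `[n_in, T, N]` array.
#' @param labels Integer class labels in `1..C`.
#' @param mode Readout: `"fs"` (first spike) or `"fr"` (firing rate);
#'   defaults to the fit's training mode.
#' @return A list of class `"fs_eval"`: `accuracy`, `n_s`, `mode`, and a
#'   tibble `predictions` (`trial, label, predicted, correct`).
#' @export
evaluate <- function(fit, data, labels, mode = NULL) {
  net <- if (inherits(fit, "fs_fit")) fit$net else fit
  if (is.null(mode)) {
    mode <- if (inherits(fit, "fs_fit")) fit$cfg$loss_mode else "fs"
  }
  x <- as_input_array(data)
  N <- dim(x)[3]
  traj <- forward(net, x, n_trials = N)
  pred <- batch_predictions(traj, mode)
  structure(list(
    accuracy = mean(pred == labels),
    n_s = mean_spike_count(traj),
    mode = mode,
    predictions = tibble(trial = seq_len(N), label = as.integer(labels),
                         predicted = pred, correct = pred == labels)
  ), class = "fs_eval")
}

#' @export
print.fs_eval <- function(x, ...) {
  cat(sprintf("<fs_eval: %s readout, accuracy %.3f over %d trials, N_s %.2f>\n",
              toupper(x$mode), x$accuracy, nrow(x$predictions), x$n_s))
  invisible(x)
}

#' Accuracy as a function of the observation window
#'
#' Evaluates the network with the input truncated to `T' = 1..T` steps and
#' the readout applied to the truncated simulation. Because the simulation is
#' causal (the state at step `n` depends only on inputs up to `n`), a single
#' full-length forward pass per trial suffices: the truncated trajectory is
#' its prefix, and the readout is recomputed on each prefix.
#'
#' @inheritParams evaluate
#' @return A tibble (`T_prime, time, accuracy`) with `time = T' * dt`
#'   in seconds.
#' @export
accuracy_vs_window <- function(fit, data, labels, mode = NULL) {
  net <- if (inherits(fit, "fs_fit")) fit$net else fit
  if (is.null(mode)) {
    mode <- if (inherits(fit, "fs_fit")) fit$cfg$loss_mode else "fs"
  }
  x <- as_input_array(data)
  dt <- attr(x, "dt")
  if (is.null(dt)) dt <- net$layers[[1]]$params$dt
  N <- dim(x)[3]
  T <- dim(x)[2]
  traj <- forward(net, x, n_trials = N)
  out <- traj[[length(traj)]]
  C <- dim(out$S)[1]
  acc <- numeric(T)
  for (Tp in seq_len(T)) {
    correct <- 0
    for (b in seq_len(N)) {
      S <- matrix(out$S[, seq_len(Tp), b], C, Tp)
      U <- matrix(out$U[, seq_len(Tp), b], C, Tp)
      pred <- predict_prefix(S, U, mode)
      correct <- correct + (pred == labels[b])
    }
    acc[Tp] <- correct / N
  }
  tibble(T_prime = seq_len(T), time = seq_len(T) * dt, accuracy = acc)
}

# Readout on a trajectory prefix (S, U are C x T' matrices).
predict_prefix <- function(S, U, mode) {
  C <- nrow(S)
  first <- apply(S, 1, function(s) {
    w <- which(s == 1)
    if (length(w) == 0) NA_integer_ else w[1]
  })
  if (mode == "fr") {
    f <- rowSums(S)
    cand <- which(f == max(f))
    if (length(cand) > 1) {
      umax <- apply(matrix(U[cand, ], length(cand)), 1, max)
      cand <- cand[umax == max(umax)]
    }
    return(cand[1])
  }
  if (all(is.na(first))) return(which.max(apply(U, 1, max)))
  best <- min(first, na.rm = TRUE)
  cand <- which(first == best)
  if (length(cand) == 1) return(cand)
  cand[which.max(U[cbind(cand, first[cand])])]
}

#' Time delay to a fraction of peak accuracy
#'
#' The smallest evaluation window `T' * dt` at which the accuracy curve
#' reaches `p` percent of its peak value over the evaluated range. With an
#' all-zero curve the delay is reported at the full window `T * dt`.
#'
#' @param acc_curve Tibble from [accuracy_vs_window()] (columns `T_prime`,
#'   `accuracy`), or a bare accuracy vector.
#' @param p Percentage of the peak, usually 50 or 90.
#' @param dt Step width in seconds.
#' @return Named list: `steps` (T' in steps) and `time` (seconds).
#' @export
time_delay <- function(acc_curve, p, dt) {
  acc <- if (is.data.frame(acc_curve)) acc_curve$accuracy else acc_curve
  if (length(acc) == 0) abort("empty accuracy curve")
  peak <- max(acc)
  if (peak == 0) {
    return(list(steps = length(acc), time = length(acc) * dt))
  }
  Tp <- which(acc >= (p / 100) * peak)[1]
  list(steps = Tp, time = Tp * dt)
}

#' Mean spike count per neuron
#'
#' Total number of spikes emitted by all neurons of the network (every layer
#' after the input; the input tensor holds event counts, not spikes, and is
#' excluded) divided by the number of neurons, averaged over trials. Used as
#' a proxy for energy consumption on neuromorphic hardware.
#'
#' @param trajectories An `"fs_trajectories"` from [forward()].
#' @return Scalar `N_s`: mean spikes per neuron per trial.
#' @export
mean_spike_count <- function(trajectories) {
  B <- attr(trajectories, "B")
  total <- sum(vapply(trajectories, function(tr) sum(tr$S), numeric(1)))
  n_neurons <- sum(vapply(trajectories, function(tr) dim(tr$S)[1], numeric(1)))
  total / n_neurons / B
}

#' Total output-layer spikes split by target / non-target neurons
#'
#' Counts output spikes over a set of trials, separating the spikes of each
#' trial's target neuron from those of the remaining (non-target) neurons.
#' First-spike-trained networks are expected to concentrate output activity
#' on the target neuron.
#'
#' @param fit An `"fs_fit"` or `"fs_network"`.
#' @param data List of [spike_tensor()]s or an `[n_in, T, N]` array.
#' @param labels Integer class labels.
#' @return Named list `target` / `nontarget` with total spike counts.
#' @export
output_spike_split <- function(fit, data, labels) {
  net <- if (inherits(fit, "fs_fit")) fit$net else fit
  x <- as_input_array(data)
  N <- dim(x)[3]
  traj <- forward(net, x, n_trials = N)
  S <- traj[[length(traj)]]$S
  C <- dim(S)[1]
  tgt <- 0; non <- 0
  for (b in seq_len(N)) {
    per_neuron <- rowSums(matrix(S[, , b], C))
    tgt <- tgt + per_neuron[labels[b]]
    non <- non + sum(per_neuron[-labels[b]])
  }
  list(target = tgt, nontarget = non)
}
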