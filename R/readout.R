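#' Discrete temporal encoding of a spike train
#'
#' Maps a binary output spike train to discrete spike times: step `n`
#' (1-based) encodes to `n * dt` seconds if the neuron spiked at `n`, and to
#' the sentinel `t_inf = (T + 1) * dt` otherwise. The sentinel is a finite
#' stand-in for "never", deliberately larger than any observable time
#' `T * dt`, so that losses over spike times stay finite.
#'
#' @param spikes Binary vector of length `T`.
#' @param dt Step width in seconds.
#' @return Numeric vector of `T` times in seconds.
#' @examples
#' encode_times(c(0, 1, 0, 1), dt = 0.01)  # 0.05 0.02 0.05 0.04
#' @export
encode_times <- function(spikes, dt) {
  if (!all(spikes %in% c(0, 1))) abort("spike train must be binary")
  T <- length(spikes)
  t_inf <- (T + 1) * dt
  ifelse(spikes == 1, seq_len(T) * dt, t_inf)
}

#' First-spike time from temporal codes
#'
#' The first-spike time is the minimum of the temporal codes; it equals the
#' sentinel `t_inf` if and only if the neuron never fired.
#'
#' @param times Output of [encode_times()].
#' @return A single time in seconds.
#' @export
first_spike_time <- function(times) {
  if (length(times) == 0) abort("empty time sequence")
  min(times)
}

#' First-spike readout of the output layer
#'
#' Summarizes the output layer of a simulated trial for decision-making:
#' per-neuron first-spike time (`t_first`, seconds; the sentinel
#' `(T + 1) * dt` for silent neurons), the first-spike step (`first_step`,
#' `NA` if silent), the maximum membrane potential over time (`u_max`), the
#' membrane potential at the first-spike step (`u_at_first`, used for
#' tie-breaking), and the firing rate (`rate`, spikes per step).
#'
#' @param trajectories An `"fs_trajectories"` from [forward()].
#' @param trial Which trial (batch column) to read out.
#' @return A tibble of class `"fs_readout"` with one row per output neuron
#'   and attributes `T`, `dt`, `t_inf`.
#' @export
fs_readout <- function(trajectories, trial = 1L) {
  out <- trajectories[[length(trajectories)]]
  T <- attr(trajectories, "T")
  dt <- attr(trajectories, "dt")
  S <- matrix(out$S[, , trial], ncol = T)
  U <- matrix(out$U[, , trial], ncol = T)
  C <- nrow(S)
  first_step <- apply(S, 1, function(s) {
    w <- which(s == 1)
    if (length(w) == 0) NA_integer_ else w[1]
  })
  t_inf <- (T + 1) * dt
  res <- tibble(
    neuron = seq_len(C),
    first_step = as.integer(first_step),
    t_first = ifelse(is.na(first_step), t_inf, first_step * dt),
    u_max = apply(U, 1, max),
    u_at_first = ifelse(is.na(first_step), NA_real_,
                        U[cbind(seq_len(C), ifelse(is.na(first_step), 1L, first_step))]),
    rate = rowSums(S) / T
  )
  structure(res, T = T, dt = dt, t_inf = t_inf,
            class = c("fs_readout", class(res)))
}

#' Class prediction from the first spike
#'
#' The predicted class is the output neuron with the earliest first spike.
#' Ties (several neurons first firing at the same step) are broken by the
#' higher membrane potential at that step, then by the lower neuron index.
#' If every output neuron stays silent, the prediction falls back to the
#' neuron with the largest maximum membrane potential over time: the closer a
#' membrane came to threshold, the earlier that neuron would have fired.
#'
#' @param readout An [fs_readout()].
#' @return Predicted class as a neuron index in `1..C`.
#' @export
predict_fs <- function(readout) {
  if (nrow(readout) < 2) abort("need at least 2 output neurons")
  if (all(is.na(readout$first_step))) {
    return(which.max(readout$u_max))
  }
  best_t <- min(readout$t_first)
  cand <- which(readout$t_first == best_t)
  if (length(cand) == 1) return(cand)
  cand[which.max(readout$u_at_first[cand])]
}

#' Class prediction from firing rates
#'
#' The predicted class is the output neuron with the highest firing rate;
#' ties are broken by the larger maximum membrane potential, then by the
#' lower neuron index.
#'
#' @param readout An [fs_readout()].
#' @return Predicted class as a neuron index in `1..C`.
#' @export
predict_fr <- function(readout) {
  if (nrow(readout) < 2) abort("need at least 2 output neurons")
  best <- max(readout$rate)
  cand <- which(readout$rate == best)
  if (length(cand) > 1) {
    cand <- cand[readout$u_max[cand] == max(readout$u_max[cand])]
  }
  cand[1]
}

#' Export a trial raster and readout summary
#'
#' Writes the output-layer spike raster as a CSV (`neuron,step,spike`) and the
#' readout summary (first-spike times, maximum membrane potentials, rates and
#' both predictions) as a JSON-like key-value text file.
#'
#' @param trajectories An `"fs_trajectories"`.
#' @param path_raster,path_summary Output file paths (`NULL` to skip either).
#' @param trial Trial index.
#' @return The readout tibble, invisibly.
#' @export
export_raster <- function(trajectories, path_raster = NULL, path_summary = NULL,
                          trial = 1L) {
  ro <- fs_readout(trajectories, trial)
  out <- trajectories[[length(trajectories)]]
  T <- attr(trajectories, "T")
  S <- matrix(out$S[, , trial], ncol = T)
  if (!is.null(path_raster)) {
    df <- expand.grid(neuron = seq_len(nrow(S)), step = seq_len(T))
    df$spike <- as.integer(S[cbind(df$neuron, df$step)])
    utils::write.csv(df, path_raster, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(path_summary)) {
    lines <- c(
      "{",
      sprintf('  "t_first": [%s],', paste(sprintf("%.17g", ro$t_first), collapse = ", ")),
      sprintf('  "u_max": [%s],', paste(sprintf("%.17g", ro$u_max), collapse = ", ")),
      sprintf('  "rate": [%s],', paste(sprintf("%.17g", ro$rate), collapse = ", ")),
      sprintf('  "prediction_fs": %d,', predict_fs(ro)),
      sprintf('  "prediction_fr": %d', predict_fr(ro)),
      "}")
    writeLines(lines, path_summary)
  }
  invisible(ro)
}
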