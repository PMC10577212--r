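#' Loss configuration
#'
#' Hyperparameters of the first-spike (FS) and firing-rate (FR) losses and of
#' the optional spike-count constraint. Inside the loss exponentials,
#' first-spike times are expressed in *steps* (`t / dt`), not seconds: with
#' the typical scales `alpha0 ~ 0.1`, `beta0 = 0.02` and windows of up to a
#' few hundred steps, step units keep the exponents numerically sane, whereas
#' second units would flatten the softmax and make the inactivity penalty
#' either vanish or explode.
#'
#' @param alpha0 Softmax scale on negative first-spike times (FS loss); larger
#'   values sharpen the softmax and speed up training.
#' @param beta0 Exponent of the inactive-target penalty.
#' @param lambda_t Weight of the inactive-target penalty.
#' @param alpha1 Softmax scale on firing rates (FR loss).
#' @param lambda_s Weight of the spike-count constraint (0 disables it).
#' @param n_target Target mean spike count per neuron for the constraint.
#' @return A list of class `"loss_config"`.
#' @export
loss_config <- function(alpha0 = 0.2, beta0 = 0.02, lambda_t = 0.01,
                        alpha1 = 20, lambda_s = 0, n_target = 0) {
  stopifnot(alpha0 >= 0, beta0 >= 0, lambda_t >= 0, alpha1 >= 0,
            lambda_s >= 0, n_target >= 0)
  structure(list(alpha0 = alpha0, beta0 = beta0, lambda_t = lambda_t,
                 alpha1 = alpha1, lambda_s = lambda_s, n_target = n_target,
                 time_units = "steps"),
            class = "loss_config")
}

# log of the softmax of logits z, with max-subtraction for stability; the
# result is invariant to adding a constant to z.
log_softmax <- function(z) {
  z <- z - max(z)
  z - log(sum(exp(z)))
}

softmax <- function(z) {
  z <- exp(z - max(z))
  z / sum(z)
}

check_one_hot <- function(y, C) {
  if (length(y) != C || !all(y %in% c(0, 1)) || sum(y) != 1) {
    abort("y must be a one-hot vector with exactly one 1")
  }
}

#' First-spike cross-entropy loss
#'
#' Cross-entropy of the softmax over negative scaled first-spike times against
#' a one-hot target, plus a penalty on a target neuron that never fires inside
#' the window:
#' `L = -sum_i y_i log softmax(-alpha0 * t)_i
#'      + lambda_t * sum_{i : t_i > T} y_i * (exp(beta0 * t_i) - 1)`.
#' Minimizing it pulls the target neuron's first spike earlier and pushes
#' non-target first spikes later. Times are in steps; only the sentinel value
#' `T + 1` (a silent neuron) can exceed `T`, so the penalty fires exactly for
#' silent targets.
#'
#' @param t_f Per-neuron first-spike times in steps, each in `[1, T + 1]`.
#' @param y One-hot target vector.
#' @param cfg A [loss_config()].
#' @param T Number of observable steps.
#' @return Scalar loss.
#' @examples
#' cfg <- loss_config(alpha0 = 0.1)
#' fs_loss(c(3, 8), c(1, 0), cfg, T = 10)
#' @export
fs_loss <- function(t_f, y, cfg, T) {
  C <- length(t_f)
  check_one_hot(y, C)
  if (any(t_f < 1 | t_f > T + 1)) abort("t_f must lie in [1, T + 1] steps")
  ce <- -sum(y * log_softmax(-cfg$alpha0 * t_f))
  silent_target <- which(y == 1 & t_f > T)
  pen <- cfg$lambda_t * sum(exp(cfg$beta0 * t_f[silent_target]) - 1)
  ce + pen
}

#' Gradient of the first-spike loss
#'
#' Analytic derivative of [fs_loss()] with respect to each first-spike time
#' (in steps): `-alpha0 * (p_i - y_i)` from the cross-entropy term, where `p`
#' is the softmax over `-alpha0 * t_f`, plus
#' `lambda_t * beta0 * exp(beta0 * t_i)` for a silent target neuron.
#'
#' @inheritParams fs_loss
#' @return Numeric vector `dL/dt_f` (per neuron, step units).
#' @export
fs_loss_grad <- function(t_f, y, cfg, T) {
  C <- length(t_f)
  check_one_hot(y, C)
  if (any(t_f < 1 | t_f > T + 1)) abort("t_f must lie in [1, T + 1] steps")
  p <- softmax(-cfg$alpha0 * t_f)
  g <- -cfg$alpha0 * (p - y)
  silent_target <- y == 1 & t_f > T
  g[silent_target] <- g[silent_target] +
    cfg$lambda_t * cfg$beta0 * exp(cfg$beta0 * t_f[silent_target])
  g
}

#' Firing-rate cross-entropy loss
#'
#' Cross-entropy of the softmax over scaled firing rates against a one-hot
#' target: `L = -sum_i y_i log softmax(alpha1 * f)_i`. Maximizes the target
#' neuron's rate relative to the others; no inactivity penalty is needed since
#' rate training does not starve neurons of gradient.
#'
#' @param f Per-neuron firing rates in `[0, 1]`.
#' @param y One-hot target vector.
#' @param cfg A [loss_config()].
#' @return Scalar loss.
#' @export
fr_loss <- function(f, y, cfg) {
  check_one_hot(y, length(f))
  if (any(f < 0 | f > 1)) abort("rates must lie in [0, 1]")
  -sum(y * log_softmax(cfg$alpha1 * f))
}

#' Gradient of the firing-rate loss
#' @inheritParams fr_loss
#' @return Numeric vector `dL/df` per neuron.
#' @export
fr_loss_grad <- function(f, y, cfg) {
  check_one_hot(y, length(f))
  p <- softmax(cfg$alpha1 * f)
  cfg$alpha1 * (p - y)
}

#' Spike-count constraint
#'
#' Optional penalty constraining the mean number of spikes per neuron in the
#' system: `L_s = lambda_s * |N_s - n_target|`. Used to probe how many spikes
#' a network actually needs for correct classification.
#'
#' @param n_s Measured mean spike count per neuron (see
#'   [mean_spike_count()]).
#' @param cfg A [loss_config()].
#' @return Scalar penalty.
#' @export
spike_count_penalty <- function(n_s, cfg) {
  stopifnot(n_s >= 0)
  cfg$lambda_s * abs(n_s - cfg$n_target)
}
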