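#' Training configuration
#'
#' All knobs of a training run. `loss_mode = "fs"` trains on the first-spike
#' cross-entropy (with the empty-sequence extension `T_E` applied to every
#' training input before simulation); `"fr"` trains on the firing-rate
#' cross-entropy over the unextended window. Layer-specific neuron parameters
#' follow the feature-extraction/decision split: `tau1`/`theta1` for early
#' layers and `tau2 = mu * tau1`, `theta2` for decision layers (see
#' [parse_architecture()] / [build_network()]).
#'
#' @param eta Learning rate.
#' @param B Mini-batch size.
#' @param n_epochs Number of epochs.
#' @param weight_decay L2 weight decay added to the gradient (default 1e-4).
#' @param T_E Empty-sequence length in steps, appended during FS training.
#' @param tau1,theta1 Feature-extraction time constant (s) / threshold.
#' @param mu Decision-layer time-constant multiplier, `tau2 = mu * tau1`.
#' @param theta2 Decision-layer threshold.
#' @param rho Surrogate-gradient slope.
#' @param A,D Gaussian-window amplitude and factor; `A = NULL` means the
#'   default `2 * T` for the (extended) training window.
#' @param loss A [loss_config()].
#' @param loss_mode `"fs"` or `"fr"`.
#' @param seed RNG seed; fully determines weight initialization and batch
#'   order.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(eta = 1e-3, B = 16, n_epochs = 50,
                         weight_decay = 1e-4, T_E = 10,
                         tau1 = 0.05, theta1 = 0.3, mu = 4, theta2 = 1,
                         rho = 5, A = NULL, D = 24,
                         loss = loss_config(), loss_mode = c("fs", "fr"),
                         seed = 1) {
  loss_mode <- match.arg(loss_mode)
  stopifnot(eta >= 0, B >= 1, n_epochs >= 1, weight_decay >= 0, T_E >= 0,
            mu > 0, rho > 0, D >= 1)
  structure(list(eta = eta, B = as.integer(B), n_epochs = as.integer(n_epochs),
                 weight_decay = weight_decay, T_E = as.integer(T_E),
                 tau1 = tau1, theta1 = theta1, mu = mu, theta2 = theta2,
                 rho = rho, A = A, D = D, loss = loss, loss_mode = loss_mode,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build a network from an architecture string and a training configuration
#'
#' Convenience wrapper around [parse_architecture()] that applies the
#' configuration's layer-specific parameters (`tau1`, `theta1` for feature
#' extraction; `tau2 = mu * tau1`, `theta2` for decision layers).
#'
#' @param arch Architecture string (see [parse_architecture()]).
#' @param dt Simulation step in seconds.
#' @param cfg A [train_config()].
#' @return An uninitialized `"fs_network"`.
#' @export
build_network <- function(arch, dt, cfg) {
  parse_architecture(arch, dt, tau1 = cfg$tau1, theta1 = cfg$theta1,
                     tau2 = cfg$mu * cfg$tau1, theta2 = cfg$theta2)
}

#' Xavier-uniform weight initialization
#'
#' Draws every feed-forward, recurrent and convolutional weight from the
#' Xavier (Glorot) uniform distribution,
#' `U(-sqrt(6 / (fan_in + fan_out)), +sqrt(6 / (fan_in + fan_out)))`,
#' reproducibly for a given seed.
#'
#' @param net An `"fs_network"`.
#' @param seed Integer RNG seed.
#' @return The network with initialized weights.
#' @export
init_weights <- function(net, seed) {
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (i in seq_along(net$layers)) {
    lay <- net$layers[[i]]
    if (lay$kind == "maxpool") next
    if (lay$kind == "conv2d") {
      d <- dim(lay$W)  # filters, C, k, k
      fan_in <- d[2] * d[3] * d[4]
      fan_out <- d[1] * d[3] * d[4]
      bound <- sqrt(6 / (fan_in + fan_out))
      net$layers[[i]]$W <- array(runif(prod(d), -bound, bound), dim = d)
    } else {
      bound <- sqrt(6 / (lay$n_in + lay$Q))
      net$layers[[i]]$W <- matrix(runif(lay$Q * lay$n_in, -bound, bound),
                                  lay$Q, lay$n_in)
      if (!is.null(lay$V)) {
        bv <- sqrt(6 / (2 * lay$Q))
        net$layers[[i]]$V <- matrix(runif(lay$Q * lay$Q, -bv, bv),
                                    lay$Q, lay$Q)
      }
    }
  }
  net
}

# Adam with L2 weight decay folded into the gradient. beta1/beta2/eps are the
# conventional defaults; only the learning rate and decay are exposed.
adam_state <- function(net) {
  lapply(net$layers, function(l) {
    if (l$kind == "maxpool") return(NULL)
    s <- list(mW = array(0, dim = dim(l$W)), vW = array(0, dim = dim(l$W)))
    if (!is.null(l$V)) {
      s$mV <- array(0, dim = dim(l$V)); s$vV <- array(0, dim = dim(l$V))
    }
    s
  })
}

adam_step <- function(w, g, m, v, t, eta, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mh <- m / (1 - b1^t)
  vh <- v / (1 - b2^t)
  list(w = w - eta * mh / (sqrt(vh) + eps), m = m, v = v)
}

# Stack a list of spike tensors into an [n_in, T, N] array.
stack_tensors <- function(tensors) {
  T <- n_bins(tensors[[1]])
  n_in <- prod(dim(tensors[[1]])) / T
  x <- vapply(tensors, function(tn) {
    stopifnot(n_bins(tn) == T)
    array(as.numeric(tn), dim = c(n_in, T))
  }, matrix(0, n_in, T))
  structure(array(x, dim = c(n_in, T, length(tensors))),
            dt = attr(tensors[[1]], "dt"))
}

as_input_array <- function(data) {
  if (is.list(data) && !is.array(data)) return(stack_tensors(data))
  d <- dim(data)
  if (inherits(data, "spike_tensor")) {
    structure(array(as.numeric(data), dim = c(prod(d[-length(d)]), d[length(d)], 1)),
              dt = attr(data, "dt"))
  } else {
    data  # already [n_in, T, N]
  }
}

batch_predictions <- function(trajectories, mode) {
  B <- attr(trajectories, "B")
  vapply(seq_len(B), function(b) {
    ro <- fs_readout(trajectories, b)
    if (mode == "fs") predict_fs(ro) else predict_fr(ro)
  }, integer(1))
}

#' Train a spiking network
#'
#' Mini-batch Adam training of an `"fs_network"` on labeled spike tensors.
#' In `"fs"` mode each batch is simulated over the extended window
#' `T + T_E`, the first-spike loss gradient is assigned to output spikes
#' through the Gaussian window (rebuilt for the extended length), and the
#' custom [backward()] pass yields weight pseudo-gradients. In `"fr"` mode
#' the rate-loss error is spread uniformly over steps (`1/T` each) with no
#' window extension. When the loss configuration has `lambda_s > 0`, the
#' spike-count constraint adds `lambda_s * sign(N_s - n_target) /
#' n_neurons` to every spiking neuron's error at every step.
#'
#' Training aborts with a diagnostic if the loss becomes non-finite. A fixed
#' `cfg$seed` makes the whole run (initialization, batch order, log)
#' bit-reproducible.
#'
#' @param net An `"fs_network"`. Initialized with [init_weights()] and
#'   `cfg$seed` unless `init = FALSE`.
#' @param data List of [spike_tensor()]s, or an `[n_in, T, N]` array with
#'   attribute `dt`.
#' @param labels Integer class labels in `1..C`, one per trial.
#' @param cfg A [train_config()].
#' @param init Draw fresh Xavier weights from `cfg$seed` first?
#' @return An object of class `"fs_fit"`: the trained network, the
#'   configuration, and a per-epoch log tibble
#'   (`epoch, loss, penalty_s, accuracy, n_s`).
#' @export
train <- function(net, data, labels, cfg, init = TRUE) {
  x <- as_input_array(data)
  dt <- attr(x, "dt")
  if (is.null(dt)) dt <- net$layers[[1]]$params$dt
  N <- dim(x)[3]
  T0 <- dim(x)[2]
  stopifnot(length(labels) == N)
  mode <- cfg$loss_mode

  T_full <- if (mode == "fs") T0 + cfg$T_E else T0
  if (mode == "fs" && cfg$T_E > 0) {
    xe <- array(0, dim = c(dim(x)[1], T_full, N))
    xe[, seq_len(T0), ] <- x
    x <- xe
  }
  A <- if (is.null(cfg$A)) 2 * T_full else cfg$A
  gw <- gaussian_window_config(T_full, cfg$D, A)

  n_neurons <- sum(vapply(net$layers, function(l) l$Q, integer(1)))

  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  if (init) net <- init_weights(net, cfg$seed)
  set.seed(cfg$seed + 1L)

  opt <- adam_state(net)
  step_t <- 0
  log <- vector("list", cfg$n_epochs)
  for (ep in seq_len(cfg$n_epochs)) {
    perm <- sample.int(N)
    ep_loss <- 0; ep_pen <- 0; ep_correct <- 0; ep_spikes <- 0
    for (start in seq(1, N, by = cfg$B)) {
      idx <- perm[start:min(start + cfg$B - 1, N)]
      Bn <- length(idx)
      xb <- x[, , idx, drop = FALSE]
      traj <- forward(net, xb, n_trials = Bn)
      err <- if (mode == "fs") {
        fs_output_error(traj, labels[idx], cfg$loss, gw)
      } else {
        fr_output_error(traj, labels[idx], cfg$loss)
      }
      ds_bias <- 0
      pen <- 0
      if (cfg$loss$lambda_s > 0) {
        ns <- mean_spike_count(traj)
        pen <- spike_count_penalty(ns, cfg$loss)
        ds_bias <- cfg$loss$lambda_s * sign(ns - cfg$loss$n_target) / n_neurons
      }
      loss_b <- mean(err$losses) + pen
      if (!is.finite(loss_b)) {
        abort(sprintf("training diverged at epoch %d (non-finite loss)", ep))
      }
      tape <- backward(net, traj, xb, err$dl_ds, rho = cfg$rho,
                       ds_bias = ds_bias)
      step_t <- step_t + 1
      for (li in seq_along(net$layers)) {
        lay <- net$layers[[li]]
        if (lay$kind == "maxpool") next
        gW <- tape[[li]]$dW / Bn + cfg$weight_decay * lay$W
        up <- adam_step(lay$W, gW, opt[[li]]$mW, opt[[li]]$vW, step_t, cfg$eta)
        net$layers[[li]]$W <- up$w
        opt[[li]]$mW <- up$m; opt[[li]]$vW <- up$v
        if (!is.null(lay$V)) {
          gV <- tape[[li]]$dV / Bn + cfg$weight_decay * lay$V
          upv <- adam_step(lay$V, gV, opt[[li]]$mV, opt[[li]]$vV, step_t, cfg$eta)
          net$layers[[li]]$V <- upv$w
          opt[[li]]$mV <- upv$m; opt[[li]]$vV <- upv$v
        }
      }
      pred <- batch_predictions(traj, mode)
      ep_correct <- ep_correct + sum(pred == labels[idx])
      ep_loss <- ep_loss + loss_b * Bn
      ep_pen <- ep_pen + pen * Bn
      ep_spikes <- ep_spikes + mean_spike_count(traj) * Bn
    }
    log[[ep]] <- tibble(epoch = ep, loss = ep_loss / N, penalty_s = ep_pen / N,
                        accuracy = ep_correct / N, n_s = ep_spikes / N)
  }
  structure(list(net = net, cfg = cfg, dt = dt, T_train = T_full,
                 log = dplyr::bind_rows(log)),
            class = "fs_fit")
}

#' @export
print.fs_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  cat(sprintf("<fs_fit: %s-trained, %d epochs, final loss %.4f, train accuracy %.3f>\n",
              toupper(x$cfg$loss_mode), nrow(x$log), last$loss, last$accuracy))
  invisible(x)
}
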