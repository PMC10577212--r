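#' One simulation step of a spiking layer
#'
#' Advances a layer of discretized CUBA-LIF neurons from step `n` to `n + 1`.
#' The update order is normative and resolves the apparent same-step
#' dependence of the current on the layer's own spikes:
#'
#' 1. membrane: `U[n+1] = alpha * U[n] * (1 - S[n]) + (1 - alpha) * I[n]`
#'    (the `(1 - S)` factor implements the instant reset to the resting
#'    potential 0 after a spike);
#' 2. spikes:   `S[n+1] = 1(U[n+1] >= theta)`;
#' 3. current:  `I[n+1] = beta * I[n] + W s_in[n+1] + V S[n+1]`.
#'
#' A spike emitted through a recurrent connection at step `n + 1` therefore
#' first affects the membrane at step `n + 3`; there is no algebraic loop.
#' The state matrices carry one column per trial, so a whole mini-batch is
#' advanced at once.
#'
#' @param layer An `"fs_layer"` (not a pooling layer).
#' @param state List with matrices `I`, `U`, `S` (`Q x B`), the state at step
#'   `n`.
#' @param input Feed-forward drive at step `n + 1`: `n_in x B` matrix of
#'   presynaptic spikes (binary) or input counts (first layer).
#' @return The state list at step `n + 1`.
#' @export
layer_step <- function(layer, state, input) {
  if (layer$kind == "maxpool") abort("pooling layers are stateless; use pool_step()")
  input <- as.matrix(input)
  if (nrow(input) != layer$n_in || nrow(state$U) != layer$Q) {
    abort("state/input dimensions do not match layer")
  }
  p <- layer$params
  U1 <- p$alpha * state$U * (1 - state$S) + (1 - p$alpha) * state$I
  S1 <- (U1 >= p$theta) * 1
  Wm <- layer_weight_matrix(layer)
  I1 <- p$beta * state$I + as.matrix(Wm %*% input)
  if (!is.null(layer$V)) I1 <- I1 + layer$V %*% S1
  list(I = I1, U = U1, S = S1)
}

# Max pooling over binary spike maps: the max of a {0,1} block is a logical
# OR, evaluated independently at every step. No internal state.
pool_step <- function(layer, input) {
  out <- matrix(0, layer$Q, ncol(input))
  for (i in seq_along(layer$blocks)) {
    blk <- input[layer$blocks[[i]], , drop = FALSE]
    out[i, ] <- as.numeric(colSums(blk) > 0)
  }
  out
}

zero_state <- function(Q, B) {
  z <- matrix(0, Q, B)
  list(I = z, U = z, S = z)
}

#' Simulate a network over an input tensor
#'
#' Runs the full discrete-time forward pass for steps `n = 1..T`, starting
#' from `I = U = 0` in every layer, and records the complete state
#' trajectories needed by the backward pass. The first layer consumes the raw
#' (integer count) input tensor; all later layers consume binary spikes.
#' Pooling layers record spikes only.
#'
#' @param net An `"fs_network"`.
#' @param input A [spike_tensor()], or a plain array whose last axis is time.
#'   A trailing batch axis may be added: `[..., T, B]` with `n_trials = B`
#'   given.
#' @param n_trials Number of trials stacked along the final axis (default 1).
#' @return An object of class `"fs_trajectories"`: a list with one element per
#'   layer, each holding arrays `I`, `U`, `S` of dim `Q x T x B` (pooling
#'   layers: `S` only), plus attributes `T`, `B` and `dt`.
#' @examples
#' net <- parse_architecture("4-FC3(R)-2", dt = 0.01, tau1 = 0.05, theta1 = 0.5)
#' net <- init_weights(net, seed = 1)
#' x <- matrix(rpois(4 * 10, 0.5), 4, 10)
#' traj <- forward(net, spike_tensor(x, 0.01, "audio"))
#' dim(traj[[2]]$S)  # 2 x 10 x 1
#' @export
forward <- function(net, input, n_trials = 1L) {
  d <- dim(input)
  dt <- attr(input, "dt")
  if (is.null(dt)) dt <- net$layers[[1]]$params$dt
  B <- as.integer(n_trials)
  expected <- prod(net$input_shape)
  if (B > 1) {
    stopifnot(d[length(d)] == B)
    T <- d[length(d) - 1]
    n_in <- prod(d[-c(length(d) - 1, length(d))])
  } else if (length(d) >= 2 && d[length(d)] == 1 &&
             prod(d[-length(d)]) != expected) {
    # trailing singleton batch axis
    T <- d[length(d) - 1]
    n_in <- prod(d[-c(length(d) - 1, length(d))])
  } else {
    T <- d[length(d)]
    n_in <- prod(d[-length(d)])
  }
  if (n_in != prod(net$input_shape)) {
    abort(sprintf("input has %d units per step, network expects %d",
                  n_in, prod(net$input_shape)))
  }
  # flatten to n_in x T x B
  x <- array(as.numeric(input), dim = c(n_in, T, B))

  trajs <- vector("list", length(net$layers))
  prev <- x
  for (li in seq_along(net$layers)) {
    lay <- net$layers[[li]]
    if (lay$kind == "maxpool") {
      S <- array(0, dim = c(lay$Q, T, B))
      for (n in seq_len(T)) {
        S[, n, ] <- pool_step(lay, matrix(prev[, n, ], ncol = B))
      }
      trajs[[li]] <- list(S = S)
      prev <- S
      next
    }
    I <- array(0, dim = c(lay$Q, T, B))
    U <- array(0, dim = c(lay$Q, T, B))
    S <- array(0, dim = c(lay$Q, T, B))
    st <- zero_state(lay$Q, B)
    Wm <- layer_weight_matrix(lay)
    p <- lay$params
    for (n in seq_len(T)) {
      U1 <- p$alpha * st$U * (1 - st$S) + (1 - p$alpha) * st$I
      S1 <- (U1 >= p$theta) * 1
      I1 <- p$beta * st$I + as.matrix(Wm %*% matrix(prev[, n, ], ncol = B))
      if (!is.null(lay$V)) I1 <- I1 + lay$V %*% S1
      I[, n, ] <- I1; U[, n, ] <- U1; S[, n, ] <- S1
      st <- list(I = I1, U = U1, S = S1)
    }
    trajs[[li]] <- list(I = I, U = U, S = S)
    prev <- S
  }
  structure(trajs, T = T, B = B, dt = dt, class = "fs_trajectories")
}

#' @export
print.fs_trajectories <- function(x, ...) {
  cat(sprintf("<fs_trajectories: %d layers, T = %d, %d trial(s)>\n",
              length(x), attr(x, "T"), attr(x, "B")))
  invisible(x)
}
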