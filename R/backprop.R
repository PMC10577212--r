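#' Gaussian error-assignment window size
#'
#' The error of a first-spike time is distributed over neighbouring steps
#' through a negative Gaussian whose standard deviation is tied to the
#' sequence length: `sigma = floor(T / D)` for a window factor `D`, and the
#' window width follows the 3-sigma limit capped at the sequence length,
#' `W = min(6 * sigma + 1, T)`. Large `D` focuses the error on the steps
#' around the first spike (as `D -> Inf`, `sigma -> 0` and `W -> 1`, the
#' delta limit); small `D` spreads it over the whole sequence, approaching
#' rate-like error assignment.
#'
#' @param T Sequence length in steps (>= 1).
#' @param D Window factor (>= 1).
#' @return A list `(sigma, W)` in steps. `D > T` yields `sigma = 0, W = 1`.
#' @examples
#' window_size(100, 8)   # sigma 12, W 73
#' window_size(100, 16)  # sigma 6,  W 37
#' @export
window_size <- function(T, D) {
  stopifnot(T >= 1, D >= 1)
  sigma <- floor(T / D)
  list(sigma = sigma, W = min(6 * sigma + 1, T))
}

#' Gaussian window configuration
#'
#' Bundles the amplitude `A` and window factor `D` of the error-assignment
#' window, with `sigma` and `W` derived from the current sequence length via
#' [window_size()]. Because `sigma` depends on `T`, the configuration must be
#' rebuilt whenever the training window changes (in particular after
#' [extend_window()]); [train()] does this automatically. `A` defaults to
#' `2 * T`: much smaller amplitudes scale the whole pseudo-gradient down and
#' stall training.
#'
#' @param T Sequence length in steps.
#' @param D Window factor (>= 1).
#' @param A Amplitude (> 0), default `2 * T`.
#' @return A list of class `"gaussian_window"` with fields `A, D, sigma, W`.
#' @export
gaussian_window_config <- function(T, D, A = 2 * T) {
  stopifnot(A > 0, D >= 1, T >= 1)
  ws <- window_size(T, D)
  structure(list(A = A, D = D, sigma = ws$sigma, W = ws$W, T = T),
            class = "gaussian_window")
}

#' Negative Gaussian window weight
#'
#' `g(x) = -(A / (sqrt(2 * pi) * sigma)) * exp(-x^2 / (2 * sigma^2))`:
#' strictly negative, symmetric in the step offset `x`, with its largest
#' magnitude at `x = 0`. The negative sign encodes that the error of a spike
#' must oppose the error of its time: making a spike time earlier means
#' raising the spike variable from 0 toward 1 at earlier steps.
#'
#' @param x Integer step offset(s).
#' @param cfg A [gaussian_window_config()] with `sigma >= 1` (the `sigma = 0`
#'   delta limit is handled by [assign_time_error_to_spikes()], not here).
#' @return Numeric weight(s), all `< 0`.
#' @export
gaussian_weight <- function(x, cfg) {
  if (cfg$sigma < 1) abort("gaussian_weight requires sigma >= 1; sigma = 0 is the delta limit")
  -(cfg$A / (sqrt(2 * pi) * cfg$sigma)) * exp(-x^2 / (2 * cfg$sigma^2))
}

#' Assign a first-spike-time error to output spikes
#'
#' Implements the two error-assignment rules of the first-spike backward
#' pass for a single output neuron:
#'
#' * **active** neuron with first spike at step `m*`: the time error flows
#'   only through the first spike, so
#'   `dL/ds[n] = dL/dt_F * g(m* - n)` for `|n - m*| <= 3 * sigma`, 0
#'   elsewhere;
#' * **inactive** neuron (no spike in the window): the time error is assigned
#'   to every step, `dL/ds[n] = dL/dt_F * sum_m g(m - n)` over
#'   `m = 1..T` within the 3-sigma truncation, which nudges a silent target
#'   neuron toward firing anywhere and keeps a silent non-target silent.
#'
#' In the `sigma = 0` delta limit (`D > T`) the window degenerates to a
#' single step of weight `-A / sqrt(2 * pi)`.
#'
#' @param dl_dtf Scalar error of the neuron's first-spike time (step units).
#' @param first_step First-spike step in `1..T`, or `NA` for an inactive
#'   neuron.
#' @param T Sequence length in steps.
#' @param cfg A [gaussian_window_config()] built for this `T`.
#' @return Numeric vector of length `T`: `dL/ds` at each step.
#' @export
assign_time_error_to_spikes <- function(dl_dtf, first_step, T, cfg) {
  ds <- numeric(T)
  if (cfg$sigma < 1) {
    w0 <- -cfg$A / sqrt(2 * pi)
    if (is.na(first_step)) ds[] <- dl_dtf * w0 else ds[first_step] <- dl_dtf * w0
    return(ds)
  }
  r <- 3 * cfg$sigma
  if (!is.na(first_step)) {
    n <- max(1, first_step - r):min(T, first_step + r)
    ds[n] <- dl_dtf * gaussian_weight(first_step - n, cfg)
    return(ds)
  }
  for (o in -r:r) {
    # time step m = n + o contributes g(o) to step n, for m inside 1..T
    lo <- max(1, 1 - o); hi <- min(T, T - o)
    if (lo <= hi) ds[lo:hi] <- ds[lo:hi] + gaussian_weight(o, cfg)
  }
  ds * dl_dtf
}

#' Fast-sigmoid surrogate derivative of the spike function
#'
#' The hard threshold `s = 1(U >= theta)` has no useful derivative, so the
#' backward pass substitutes the fast-sigmoid pseudo-derivative
#' `f'(U) = 1 / (1 + rho * |U - theta|)^2`: equal to 1 exactly at threshold,
#' symmetric around it, and monotonically decaying with distance at a rate
#' set by the slope `rho`.
#'
#' @param u Membrane potential(s).
#' @param theta Firing threshold.
#' @param rho Surrogate slope (> 0), default 5.
#' @return Values in `(0, 1]`.
#' @export
surrogate_derivative <- function(u, theta, rho = 5) {
  stopifnot(rho > 0)
  1 / (1 + rho * abs(u - theta))^2
}

#' Backward pass: pseudo-gradients of the loss with respect to the weights
#'
#' Reverse-time accumulation of the error signals through the recorded state
#' trajectories. Within each spiking layer, for `n = T..1`:
#'
#' * `dL/dI[n] = (1 - alpha) * dL/dU[n+1] + beta * dL/dI[n+1]`
#' * `dL/ds[n] = upstream[n] + V' dL/dI[n]` (recurrent term at the same step)
#' * `dL/dU[n] = dL/ds[n] * f'(U[n]) + alpha * (1 - s[n]) * dL/dU[n+1]`
#'
#' with `f'` the fast-sigmoid surrogate and the reset factor `(1 - s[n])`
#' treated as a constant (no gradient flows through the reset's own spike).
#' Weight gradients accumulate over time,
#' `dL/dW = sum_n dL/dI[n] s_prev[n]'` and `dL/dV = sum_n dL/dI[n] s[n]'`,
#' and the error handed to the layer below is `W' dL/dI[n]`. Max-pooling
#' layers route their incoming error to the argmax (first-index tie-break)
#' input of each block at each step.
#'
#' @param net The `"fs_network"` that produced the trajectories.
#' @param trajectories [forward()] output for the same input.
#' @param input The input tensor (or `n_in x T x B` array) of that forward
#'   pass; needed for the first layer's weight gradient.
#' @param dl_ds_output Error on the output spikes: `C x T x B` array (or
#'   `C x T` for a single trial), from [assign_time_error_to_spikes()] in
#'   first-spike mode or from the per-step rate rule in firing-rate mode.
#' @param rho Surrogate slope.
#' @param ds_bias Scalar added to every spiking layer's `dL/ds` (the
#'   spike-count constraint gradient); default 0.
#' @return A list of class `"gradient_tape"`: per layer, weight gradients
#'   `dW` / `dV` and error trajectories `ds`, `dU`, `dI` (pooling layers:
#'   `ds` only).
#' @export
backward <- function(net, trajectories, input, dl_ds_output, rho = 5,
                     ds_bias = 0) {
  T <- attr(trajectories, "T")
  B <- attr(trajectories, "B")
  if (length(trajectories) != length(net$layers)) {
    abort("trajectories do not match network depth")
  }
  n_in <- prod(net$input_shape)
  x <- array(as.numeric(input), dim = c(n_in, T, B))
  C <- net$layers[[length(net$layers)]]$Q
  up <- array(as.numeric(dl_ds_output), dim = c(C, T, B))

  tape <- vector("list", length(net$layers))
  for (li in rev(seq_along(net$layers))) {
    lay <- net$layers[[li]]
    prev_S <- if (li == 1) x else trajectories[[li - 1]]$S
    if (lay$kind == "maxpool") {
      ds <- up
      TB <- T * B
      upf <- matrix(up, lay$Q, TB)
      dprev <- matrix(0, lay$n_in, TB)
      Sf <- matrix(prev_S, lay$n_in, TB)
      for (i in seq_along(lay$blocks)) {
        blk <- lay$blocks[[i]]
        ch <- max.col(t(Sf[blk, , drop = FALSE]), ties.method = "first")
        idx <- cbind(blk[ch], seq_len(TB))
        dprev[idx] <- dprev[idx] + upf[i, ]
      }
      tape[[li]] <- list(ds = ds)
      up <- array(dprev, dim = c(lay$n_in, T, B))
      next
    }
    tr <- trajectories[[li]]
    p <- lay$params
    fprime <- surrogate_derivative(tr$U, p$theta, rho)
    dI <- array(0, dim = c(lay$Q, T, B))
    dsA <- array(0, dim = c(lay$Q, T, B))
    dUA <- array(0, dim = c(lay$Q, T, B))
    dU_next <- matrix(0, lay$Q, B)
    dI_next <- matrix(0, lay$Q, B)
    Vt <- if (!is.null(lay$V)) base::t(lay$V) else NULL
    for (n in T:1) {
      dI_n <- (1 - p$alpha) * dU_next + p$beta * dI_next
      ds_n <- matrix(up[, n, ], lay$Q, B) + ds_bias
      if (!is.null(Vt)) ds_n <- ds_n + Vt %*% dI_n
      dU_n <- ds_n * matrix(fprime[, n, ], lay$Q, B) +
        p$alpha * (1 - matrix(tr$S[, n, ], lay$Q, B)) * dU_next
      dI[, n, ] <- dI_n
      dsA[, n, ] <- ds_n
      dUA[, n, ] <- dU_n
      dU_next <- dU_n
      dI_next <- dI_n
    }
    dIf <- matrix(dI, lay$Q, T * B)
    pSf <- matrix(prev_S, lay$n_in, T * B)
    if (lay$kind == "conv2d") {
      cn <- lay$conn
      vals <- rowSums(dIf[cn$out, , drop = FALSE] * pSf[cn$inp, , drop = FALSE])
      dKv <- numeric(cn$n_k)
      r <- rowsum(vals, cn$k)
      dKv[as.integer(rownames(r))] <- r[, 1]
      dW <- array(dKv, dim = dim(lay$W))
    } else {
      dW <- dIf %*% base::t(pSf)
    }
    dV <- if (!is.null(lay$V)) dIf %*% base::t(matrix(tr$S, lay$Q, T * B)) else NULL
    tape[[li]] <- list(dW = dW, dV = dV, ds = dsA, dU = dUA, dI = dI)
    if (li > 1) {
      Wm <- layer_weight_matrix(lay)
      up <- array(as.matrix(Matrix::t(Wm) %*% dIf), dim = c(lay$n_in, T, B))
    }
  }
  structure(tape, class = "gradient_tape")
}

# Output-spike error for FS training: per trial, compute dL/dt_F from the
# loss, then spread it over steps through the Gaussian window. Returns the
# C x T x B error array plus per-trial losses.
fs_output_error <- function(trajectories, labels, loss_cfg, gw_cfg) {
  T <- attr(trajectories, "T")
  B <- attr(trajectories, "B")
  out <- trajectories[[length(trajectories)]]
  C <- dim(out$S)[1]
  dl <- array(0, dim = c(C, T, B))
  losses <- numeric(B)
  for (b in seq_len(B)) {
    S <- matrix(out$S[, , b], C, T)
    first <- apply(S, 1, function(s) {
      w <- which(s == 1)
      if (length(w) == 0) NA_integer_ else w[1]
    })
    t_f <- ifelse(is.na(first), T + 1, first)
    y <- as.numeric(seq_len(C) == labels[b])
    losses[b] <- fs_loss(t_f, y, loss_cfg, T)
    g <- fs_loss_grad(t_f, y, loss_cfg, T)
    for (i in seq_len(C)) {
      dl[i, , b] <- assign_time_error_to_spikes(g[i], first[i], T, gw_cfg)
    }
  }
  list(dl_ds = dl, losses = losses)
}

# Output-spike error for FR training: dL/ds[n] = dL/df * (1/T) at every step.
fr_output_error <- function(trajectories, labels, loss_cfg) {
  T <- attr(trajectories, "T")
  B <- attr(trajectories, "B")
  out <- trajectories[[length(trajectories)]]
  C <- dim(out$S)[1]
  dl <- array(0, dim = c(C, T, B))
  losses <- numeric(B)
  for (b in seq_len(B)) {
    S <- matrix(out$S[, , b], C, T)
    f <- rowSums(S) / T
    y <- as.numeric(seq_len(C) == labels[b])
    losses[b] <- fr_loss(f, y, loss_cfg)
    dl[, , b] <- matrix(fr_loss_grad(f, y, loss_cfg) / T, C, T)
  }
  list(dl_ds = dl, losses = losses)
}
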