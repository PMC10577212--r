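# Independent scalar-loop reference implementations used as oracles.
# Deliberately unvectorized and written from the recurrences directly, not
# from the package's matrix formulation.

# Naive forward: per-neuron, per-step scalar recurrence.
# x: n_in x T matrix (single trial). Returns list per layer of I,U,S (Q x T).
naive_forward <- function(net, x) {
  T <- ncol(x)
  prev <- x
  out <- list()
  for (li in seq_along(net$layers)) {
    lay <- net$layers[[li]]
    if (lay$kind == "maxpool") {
      S <- matrix(0, lay$Q, T)
      shp <- lay$in_shape
      sz <- lay$size
      C <- shp[1]; H <- shp[2]; W <- shp[3]
      Ho <- H %/% sz; Wo <- W %/% sz
      for (n in 1:T) {
        a_in <- array(prev[, n], dim = c(C, H, W))
        for (c in 1:C) for (ho in 1:Ho) for (wo in 1:Wo) {
          blk <- a_in[c, ((ho - 1) * sz + 1):(ho * sz), ((wo - 1) * sz + 1):(wo * sz)]
          S[c + C * ((ho - 1) + Ho * (wo - 1)), n] <- max(blk)
        }
      }
      out[[li]] <- list(S = S)
      prev <- S
      next
    }
    Q <- lay$Q
    p <- lay$params
    Wm <- naive_weight_matrix(lay)
    I <- matrix(0, Q, T); U <- matrix(0, Q, T); S <- matrix(0, Q, T)
    Iprev <- rep(0, Q); Uprev <- rep(0, Q); Sprev <- rep(0, Q)
    for (n in 1:T) {
      for (i in 1:Q) U[i, n] <- p$alpha * Uprev[i] * (1 - Sprev[i]) + (1 - p$alpha) * Iprev[i]
      for (i in 1:Q) S[i, n] <- if (U[i, n] >= p$theta) 1 else 0
      for (i in 1:Q) {
        drive <- 0
        for (j in seq_len(lay$n_in)) drive <- drive + Wm[i, j] * prev[j, n]
        rec <- 0
        if (!is.null(lay$V)) for (k in 1:Q) rec <- rec + lay$V[i, k] * S[k, n]
        I[i, n] <- p$beta * Iprev[i] + drive + rec
      }
      Iprev <- I[, n]; Uprev <- U[, n]; Sprev <- S[, n]
    }
    out[[li]] <- list(I = I, U = U, S = S)
    prev <- S
  }
  out
}

# Dense feed-forward weight matrix from first principles (conv by explicit
# kernel placement arithmetic, not the package's connectivity table).
naive_weight_matrix <- function(lay) {
  if (lay$kind %in% c("fully_connected", "recurrent_fc")) return(lay$W)
  stopifnot(lay$kind == "conv2d")
  shp <- lay$in_shape
  C <- shp[1]; H <- shp[2]; W <- shp[3]
  k <- lay$kernel; st <- lay$stride
  Ho <- (H - k) %/% st + 1; Wo <- (W - k) %/% st + 1
  Fh <- dim(lay$W)[1]
  M <- matrix(0, Fh * Ho * Wo, C * H * W)
  for (f in 1:Fh) for (ho in 1:Ho) for (wo in 1:Wo) {
    oi <- f + Fh * ((ho - 1) + Ho * (wo - 1))
    for (c in 1:C) for (kh in 1:k) for (kw in 1:k) {
      hi <- (ho - 1) * st + kh
      wi <- (wo - 1) * st + kw
      ii <- c + C * ((hi - 1) + H * (wi - 1))
      M[oi, ii] <- M[oi, ii] + lay$W[f, c, kh, kw]
    }
  }
  M
}

# Naive reverse-accumulation of the pseudo-gradient semantics (single trial).
# traj: naive_forward output; x: n_in x T; dl_out: C x T.
naive_backward <- function(net, traj, x, dl_out, rho = 5, ds_bias = 0) {
  T <- ncol(x)
  L <- length(net$layers)
  up <- dl_out
  tape <- vector("list", L)
  for (li in L:1) {
    lay <- net$layers[[li]]
    prev_S <- if (li == 1) x else traj[[li - 1]]$S
    if (lay$kind == "maxpool") {
      shp <- lay$in_shape
      sz <- lay$size
      C <- shp[1]; H <- shp[2]; W <- shp[3]
      Ho <- H %/% sz; Wo <- W %/% sz
      dprev <- matrix(0, lay$n_in, T)
      for (n in 1:T) {
        for (c in 1:C) for (ho in 1:Ho) for (wo in 1:Wo) {
          oi <- c + C * ((ho - 1) + Ho * (wo - 1))
          idxs <- c()
          for (wq in ((wo - 1) * sz + 1):(wo * sz)) {
            for (hq in ((ho - 1) * sz + 1):(ho * sz)) {
              idxs <- c(idxs, c + C * ((hq - 1) + H * (wq - 1)))
            }
          }
          vals <- prev_S[idxs, n]
          pick <- idxs[which.max(vals)]  # first-index tie-break
          dprev[pick, n] <- dprev[pick, n] + up[oi, n]
        }
      }
      tape[[li]] <- list(ds = up)
      up <- dprev
      next
    }
    Q <- lay$Q
    p <- lay$params
    dI <- matrix(0, Q, T); dU <- matrix(0, Q, T); ds <- matrix(0, Q, T)
    dU_next <- rep(0, Q); dI_next <- rep(0, Q)
    for (n in T:1) {
      for (i in 1:Q) dI[i, n] <- (1 - p$alpha) * dU_next[i] + p$beta * dI_next[i]
      for (i in 1:Q) {
        r <- 0
        if (!is.null(lay$V)) for (k in 1:Q) r <- r + lay$V[k, i] * dI[k, n]
        ds[i, n] <- up[i, n] + ds_bias + r
      }
      for (i in 1:Q) {
        fp <- 1 / (1 + rho * abs(traj[[li]]$U[i, n] - p$theta))^2
        dU[i, n] <- ds[i, n] * fp + p$alpha * (1 - traj[[li]]$S[i, n]) * dU_next[i]
      }
      dU_next <- dU[, n]; dI_next <- dI[, n]
    }
    if (lay$kind == "conv2d") {
      shp <- lay$in_shape
      C <- shp[1]; H <- shp[2]; W <- shp[3]
      k <- lay$kernel; st <- lay$stride
      Ho <- (H - k) %/% st + 1; Wo <- (W - k) %/% st + 1
      Fh <- dim(lay$W)[1]
      dK <- array(0, dim = dim(lay$W))
      for (f in 1:Fh) for (c in 1:C) for (kh in 1:k) for (kw in 1:k) {
        acc <- 0
        for (ho in 1:Ho) for (wo in 1:Wo) {
          oi <- f + Fh * ((ho - 1) + Ho * (wo - 1))
          hi <- (ho - 1) * st + kh
          wi <- (wo - 1) * st + kw
          ii <- c + C * ((hi - 1) + H * (wi - 1))
          acc <- acc + sum(dI[oi, ] * prev_S[ii, ])
        }
        dK[f, c, kh, kw] <- acc
      }
      dW <- dK
    } else {
      dW <- matrix(0, Q, lay$n_in)
      for (i in 1:Q) for (j in seq_len(lay$n_in)) {
        dW[i, j] <- sum(dI[i, ] * prev_S[j, ])
      }
    }
    dV <- NULL
    if (!is.null(lay$V)) {
      dV <- matrix(0, Q, Q)
      for (i in 1:Q) for (k in 1:Q) dV[i, k] <- sum(dI[i, ] * traj[[li]]$S[k, ])
    }
    tape[[li]] <- list(dW = dW, dV = dV, ds = ds, dU = dU, dI = dI)
    if (li > 1) {
      Wm <- naive_weight_matrix(lay)
      dprev <- matrix(0, lay$n_in, T)
      for (j in seq_len(lay$n_in)) for (n in 1:T) {
        dprev[j, n] <- sum(Wm[, j] * dI[, n])
      }
      up <- dprev
    }
  }
  tape
}

# Random small fully connected (optionally recurrent) net for property tests.
random_small_net <- function(n_in, sizes, dt = 0.01, recurrent = TRUE,
                             tau = 0.05, theta = 0.5) {
  layers <- list()
  prev <- n_in
  for (q in sizes) {
    layers[[length(layers) + 1]] <-
      layer_fc(prev, q, neuron_params(tau, theta, dt),
               recurrent = recurrent && runif(1) < 0.7)
    prev <- q
  }
  net <- network(layers, n_in)
  init_weights(net, sample.int(1e6, 1))
}

# Direct scalar evaluation of the first-spike loss without input clamping,
# for finite-difference probes around the sampled points.
fs_loss_unclamped <- function(t_f, y, cfg, T) {
  z <- -cfg$alpha0 * t_f
  ce <- -sum(y * (z - log(sum(exp(z)))))
  pen <- 0
  for (i in seq_along(t_f)) {
    if (y[i] == 1 && t_f[i] > T) {
      pen <- pen + cfg$lambda_t * (exp(cfg$beta0 * t_f[i]) - 1)
    }
  }
  ce + pen
}

rel_err <- function(a, b) {
  d <- max(abs(a - b))
  s <- max(abs(a), abs(b), 1e-12)
  d / s
}

max_tape_rel_err <- function(t1, t2) {
  m <- 0
  for (li in seq_along(t1)) {
    for (f in c("dW", "dV")) {
      if (!is.null(t1[[li]][[f]])) {
        m <- max(m, rel_err(as.numeric(t1[[li]][[f]]), as.numeric(t2[[li]][[f]])))
      }
    }
  }
  m
}
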