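#' Decay coefficients of the discretized CUBA-LIF neuron
#'
#' The exponential-Euler discretization of the current-based leaky
#' integrate-and-fire neuron uses per-step decay factors
#' `alpha = exp(-dt / tau_m)` for the membrane potential and
#' `beta = exp(-dt / tau_s)` for the synaptic current. The model ties the two
#' time constants together (`tau = tau_s = tau_m`), so `alpha == beta` always.
#'
#' @param tau Membrane/synaptic time constant in seconds (> 0).
#' @param dt Simulation step in seconds (> 0).
#' @return Named numeric vector `c(alpha, beta)`, both in (0, 1).
#' @examples
#' decay_coefficients(tau = 0.05, dt = 0.01)  # exp(-0.2)
#' @export
decay_coefficients <- function(tau, dt) {
  if (!is.numeric(tau) || tau <= 0) abort("tau must be positive")
  if (!is.numeric(dt) || dt <= 0) abort("dt must be positive")
  a <- exp(-dt / tau)
  c(alpha = a, beta = a)
}

#' Neuron parameters
#'
#' Bundles the time constant `tau`, firing threshold `theta` and step width
#' `dt` of a layer of CUBA-LIF neurons. The decay factors `alpha` and `beta`
#' are always recomputed from `(tau, dt)`, never set directly. `tau = 0` is
#' accepted as the memoryless limit (`alpha = beta = 0`: the membrane simply
#' relays the previous step's current). The resting potential is fixed at 0.
#'
#' @param tau Time constant in seconds (>= 0; 0 selects the memoryless limit).
#' @param theta Firing threshold (> 0).
#' @param dt Simulation step in seconds (> 0).
#' @return A list of class `"neuron_params"` with fields `tau`, `theta`, `dt`,
#'   `alpha`, `beta`, `u_rest`.
#' @export
neuron_params <- function(tau, theta, dt) {
  if (!is.numeric(tau) || tau < 0) abort("tau must be non-negative")
  if (!is.numeric(theta) || theta <= 0) abort("theta must be positive")
  if (!is.numeric(dt) || dt <= 0) abort("dt must be positive")
  ab <- if (tau == 0) c(alpha = 0, beta = 0) else decay_coefficients(tau, dt)
  structure(list(tau = tau, theta = theta, dt = dt,
                 alpha = unname(ab["alpha"]), beta = unname(ab["beta"]),
                 u_rest = 0),
            class = "neuron_params")
}

new_layer <- function(kind, params, Q, n_in, in_shape, out_shape,
                      W = NULL, V = NULL, extra = list()) {
  structure(c(list(kind = kind, params = params, Q = as.integer(Q),
                   n_in = as.integer(n_in), in_shape = in_shape,
                   out_shape = out_shape, W = W, V = V), extra),
            class = "fs_layer")
}

#' Layer constructors
#'
#' Build the layer types of the network: fully connected (optionally with
#' recurrent within-layer connections), 2-D convolution over polarity x H x W
#' spike maps, and stateless max pooling. Weights are created as zeros; use
#' [init_weights()] to draw Xavier-uniform values.
#'
#' @param n_in,n_out Fan-in / fan-out of a fully connected layer.
#' @param params A [neuron_params()] object.
#' @param recurrent Add a square recurrent weight matrix `V` (self-connections
#'   included)?
#' @return An object of class `"fs_layer"`.
#' @name layers
NULL

#' @rdname layers
#' @export
layer_fc <- function(n_in, n_out, params, recurrent = FALSE) {
  W <- matrix(0, n_out, n_in)
  V <- if (recurrent) matrix(0, n_out, n_out) else NULL
  new_layer(if (recurrent) "recurrent_fc" else "fully_connected",
            params, n_out, n_in, in_shape = n_in, out_shape = n_out,
            W = W, V = V)
}

#' @rdname layers
#' @param in_shape Input shape `c(C, H, W)` of the incoming spike maps.
#' @param filters Number of convolution kernels.
#' @param kernel Kernel side length (square kernels).
#' @param stride Convolution stride.
#' @export
layer_conv2d <- function(in_shape, filters, kernel, stride = 1L, params) {
  stopifnot(length(in_shape) == 3)
  C <- in_shape[1]; H <- in_shape[2]; W <- in_shape[3]
  Ho <- (H - kernel) %/% stride + 1L
  Wo <- (W - kernel) %/% stride + 1L
  if (Ho < 1 || Wo < 1) abort("kernel larger than input plane")
  K <- array(0, dim = c(filters, C, kernel, kernel))
  conn <- conv_connectivity(in_shape, filters, kernel, stride)
  new_layer("conv2d", params, filters * Ho * Wo, prod(in_shape),
            in_shape = in_shape, out_shape = c(filters, Ho, Wo),
            W = K, extra = list(kernel = kernel, stride = stride, conn = conn))
}

#' @rdname layers
#' @param size Pooling block side length.
#' @export
layer_maxpool <- function(in_shape, size = 2L, params = NULL) {
  stopifnot(length(in_shape) == 3)
  C <- in_shape[1]; H <- in_shape[2]; W <- in_shape[3]
  if (H %% size != 0 || W %% size != 0) {
    abort("pooling size must divide the input plane")
  }
  Ho <- H %/% size; Wo <- W %/% size
  blocks <- pool_blocks(in_shape, size)
  new_layer("maxpool", params, C * Ho * Wo, prod(in_shape),
            in_shape = in_shape, out_shape = c(C, Ho, Wo),
            extra = list(size = size, blocks = blocks))
}

# Index triplets (output unit, input unit, kernel element) describing the
# convolution as a sparse matrix over flattened spike maps. Flattening is
# R-native column-major over [C, H, W] arrays.
conv_connectivity <- function(in_shape, filters, kernel, stride) {
  C <- in_shape[1]; H <- in_shape[2]; W <- in_shape[3]
  Ho <- (H - kernel) %/% stride + 1L
  Wo <- (W - kernel) %/% stride + 1L
  flat_in <- function(c, h, w) c + C * ((h - 1L) + H * (w - 1L))
  flat_out <- function(f, h, w) f + filters * ((h - 1L) + Ho * (w - 1L))
  flat_k <- function(f, c, kh, kw) {
    f + filters * ((c - 1L) + C * ((kh - 1L) + kernel * (kw - 1L)))
  }
  g <- expand.grid(f = seq_len(filters), ho = seq_len(Ho), wo = seq_len(Wo),
                   c = seq_len(C), kh = seq_len(kernel), kw = seq_len(kernel))
  hi <- (g$ho - 1L) * stride + g$kh
  wi <- (g$wo - 1L) * stride + g$kw
  list(out = flat_out(g$f, g$ho, g$wo),
       inp = flat_in(g$c, hi, wi),
       k = flat_k(g$f, g$c, g$kh, g$kw),
       n_out = filters * Ho * Wo, n_in = C * H * W,
       n_k = filters * C * kernel * kernel)
}

pool_blocks <- function(in_shape, size) {
  C <- in_shape[1]; H <- in_shape[2]; W <- in_shape[3]
  Ho <- H %/% size; Wo <- W %/% size
  flat_in <- function(c, h, w) c + C * ((h - 1L) + H * (w - 1L))
  blocks <- vector("list", C * Ho * Wo)
  i <- 0L
  for (wo in seq_len(Wo)) for (ho in seq_len(Ho)) for (c in seq_len(C)) {
    # output flat index (column-major over [C, Ho, Wo]) equals this loop order
    i <- c + C * ((ho - 1L) + Ho * (wo - 1L))
    hs <- (ho - 1L) * size + seq_len(size)
    ws <- (wo - 1L) * size + seq_len(size)
    g <- expand.grid(h = hs, w = ws)
    blocks[[i]] <- flat_in(c, g$h, g$w)
  }
  blocks
}

# Effective feed-forward weight matrix of a layer over flattened inputs.
layer_weight_matrix <- function(layer) {
  switch(layer$kind,
    fully_connected = ,
    recurrent_fc = layer$W,
    conv2d = {
      cn <- layer$conn
      sparseMatrix(i = cn$out, j = cn$inp, x = as.vector(layer$W)[cn$k],
                   dims = c(cn$n_out, cn$n_in))
    },
    abort(paste0("layer kind '", layer$kind, "' has no weights")))
}

#' Build a spiking network
#'
#' Chains layers after checking shape compatibility. The first layer consumes
#' the flattened input tensor (counts); subsequent layers consume the binary
#' spikes of their predecessor.
#'
#' @param layers A list of `"fs_layer"` objects.
#' @param input_shape Shape of the input tensor without the time axis:
#'   `c(2, H, W)` for vision or a channel count for audio.
#' @return A list of class `"fs_network"`.
#' @export
network <- function(layers, input_shape) {
  n_prev <- prod(input_shape)
  for (i in seq_along(layers)) {
    if (layers[[i]]$n_in != n_prev) {
      abort(sprintf("layer %d expects fan-in %d but receives %d",
                    i, layers[[i]]$n_in, n_prev))
    }
    n_prev <- layers[[i]]$Q
  }
  structure(list(layers = layers, input_shape = input_shape),
            class = "fs_network")
}

#' Parse an architecture string
#'
#' Builds a network from the compact notation used throughout the package,
#' e.g. `"[2,32,32]-32C5S2-P2-64C3-FC128(R)-10"`: a `[2,32,32]` input,
#' 32 convolution kernels (5 x 5, stride 2), 2 x 2 max pooling, 64 kernels
#' (3 x 3, stride 1), a fully connected layer of 128 neurons with recurrent
#' connections, and 10 output classes. A plain leading integer (e.g. `"700"`)
#' declares an audio input with that many channels. Feature-extraction layers
#' (convolution and pooling in a convolutional net; hidden layers in a fully
#' connected net) receive `tau1`/`theta1`; decision layers (fully connected
#' layers of a convolutional net; the output layer of a fully connected net)
#' receive `tau2`/`theta2`.
#'
#' @param arch Architecture string.
#' @param dt Simulation step in seconds.
#' @param tau1,theta1 Time constant / threshold of feature-extraction layers.
#' @param tau2,theta2 Time constant / threshold of decision layers.
#' @return An uninitialized [network()]; call [init_weights()] before use.
#' @export
parse_architecture <- function(arch, dt, tau1, theta1, tau2 = tau1,
                               theta2 = theta1) {
  tokens <- strsplit(arch, "-", fixed = TRUE)[[1]]
  if (length(tokens) < 2) abort("architecture needs an input and at least one layer")
  p1 <- neuron_params(tau1, theta1, dt)
  p2 <- neuron_params(tau2, theta2, dt)

  inp <- tokens[1]
  if (grepl("^\\[", inp)) {
    input_shape <- as.integer(strsplit(gsub("[][]", "", inp), ",")[[1]])
    if (length(input_shape) != 3) abort("vision input must be [C,H,W]")
  } else {
    input_shape <- as.integer(inp)
  }
  convnet <- any(grepl("^\\d+C\\d+(S\\d+)?$|^P\\d+$", tokens[-1])) &&
    length(input_shape) == 3

  layers <- list()
  cur_shape <- input_shape
  body <- tokens[-1]
  for (i in seq_along(body)) {
    tok <- body[i]
    last <- i == length(body)
    if (grepl("^\\d+C\\d+(S\\d+)?$", tok)) {
      m <- regmatches(tok, regexec("^(\\d+)C(\\d+)(S(\\d+))?$", tok))[[1]]
      filters <- as.integer(m[2]); kern <- as.integer(m[3])
      stride <- if (m[5] == "") 1L else as.integer(m[5])
      lay <- layer_conv2d(cur_shape, filters, kern, stride, p1)
    } else if (grepl("^P\\d+$", tok)) {
      size <- as.integer(sub("^P", "", tok))
      lay <- layer_maxpool(cur_shape, size, p1)
    } else if (grepl("^FC\\d+(\\(R\\))?$", tok)) {
      m <- regmatches(tok, regexec("^FC(\\d+)(\\(R\\))?$", tok))[[1]]
      n_out <- as.integer(m[2]); rec <- m[3] == "(R)"
      # convnet: every FC layer is a decision layer; FC net: only the last
      p <- if (convnet || last) p2 else p1
      lay <- layer_fc(prod(cur_shape), n_out, p, recurrent = rec)
    } else if (grepl("^\\d+$", tok)) {
      lay <- layer_fc(prod(cur_shape), as.integer(tok), p2)
    } else {
      abort(paste0("cannot parse architecture token '", tok, "'"))
    }
    layers[[length(layers) + 1]] <- lay
    cur_shape <- lay$out_shape
  }
  network(layers, input_shape)
}

#' Number of output classes of a network
#' @param net An `"fs_network"`.
#' @return Integer class count (neurons in the last layer).
#' @export
n_classes <- function(net) net$layers[[length(net$layers)]]$Q

#' @export
print.fs_network <- function(x, ...) {
  cat(sprintf("<fs_network: input [%s], %d layers>\n",
              paste(x$input_shape, collapse = "x"), length(x$layers)))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    pr <- if (is.null(l$params)) "" else {
      sprintf(" tau=%g theta=%g", l$params$tau, l$params$theta)
    }
    cat(sprintf("  %d: %s [%s]%s\n", i, l$kind,
                paste(l$out_shape, collapse = "x"), pr))
  }
  invisible(x)
}

#' Save / load network weights
#'
#' Single-file checkpoint holding per-layer feed-forward and recurrent weights
#' together with `tau` and `theta`; the round-trip is bit-exact.
#'
#' @param net An `"fs_network"`.
#' @param path Checkpoint path.
#' @return `path` (write) or the restored network (read).
#' @export
write_checkpoint <- function(net, path) {
  payload <- lapply(net$layers, function(l) {
    list(kind = l$kind, W = l$W, V = l$V,
         tau = if (is.null(l$params)) NULL else l$params$tau,
         theta = if (is.null(l$params)) NULL else l$params$theta)
  })
  saveRDS(list(input_shape = net$input_shape, layers = payload), path,
          version = 3)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(net, path) {
  x <- readRDS(path)
  stopifnot(length(x$layers) == length(net$layers))
  for (i in seq_along(net$layers)) {
    net$layers[[i]]$W <- x$layers[[i]]$W
    net$layers[[i]]$V <- x$layers[[i]]$V
  }
  net
}
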