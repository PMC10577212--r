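#' Spike tensors
#'
#' A spike tensor is the discretized spatio-temporal representation of an
#' event stream: event counts accumulated on a grid of `T` temporal bins of
#' width `dt` seconds. Vision streams become 4-D arrays of size
#' `2 x H x W x T` (channel 1 holds positive-polarity counts, channel 2
#' negative); audio streams become `F x T` matrices. Hidden- and output-layer
#' spike trains reuse the same container with binary values.
#'
#' @param data A numeric array: `[2, H, W, T]` (vision) or `[F, T]` (audio),
#'   non-negative.
#' @param dt Bin width in seconds.
#' @param modality `"vision"` or `"audio"`.
#' @return An array of class `"spike_tensor"` with attributes `dt` and
#'   `modality`.
#' @export
spike_tensor <- function(data, dt, modality = c("vision", "audio")) {
  modality <- match.arg(modality)
  nd <- length(dim(data))
  if (modality == "vision" && (nd != 4 || dim(data)[1] != 2)) {
    abort("vision spike tensor must be a [2, H, W, T] array")
  }
  if (modality == "audio" && nd != 2) abort("audio spike tensor must be an [F, T] matrix")
  if (dt <= 0) abort("dt must be positive")
  if (any(data < 0)) abort("spike tensor values must be non-negative")
  structure(data, dt = dt, modality = modality, class = "spike_tensor")
}

#' Number of time bins of a spike tensor
#' @param tensor A [spike_tensor()].
#' @return Integer `T`.
#' @export
n_bins <- function(tensor) {
  d <- dim(tensor)
  d[length(d)]
}

#' Bin an event stream into a spike tensor
#'
#' Accumulates raw events at temporal resolution `dt`: bin `k` (0-based)
#' covers the half-open interval `[k*dt, (k+1)*dt)`, and each cell holds the
#' number of events falling in that bin. Vision events are routed to polarity
#' channel 1 (`p = +1`) or 2 (`p = -1`). Events at or beyond `T*dt` are
#' dropped. Optional spatial downsampling sums counts over non-overlapping
#' `factor x factor` blocks (zero-padding the bottom/right edge when the frame
#' size is not divisible), so the total in-window event count is preserved.
#'
#' @param stream An [event_stream()].
#' @param dt Bin width in seconds (> 0).
#' @param T Number of temporal bins (>= 1).
#' @param spatial_downsample Integer block size for vision streams (default 1,
#'   no downsampling). Ignored for audio.
#' @return A [spike_tensor()] of counts.
#' @examples
#' ev <- event_stream(data.frame(t = c(0.001, 0.004, 0.011), channel = 0),
#'                    sensor_shape = 1, modality = "audio")
#' as.vector(bin_events(ev, dt = 0.005, T = 3))  # 2, 0, 1
#' @export
bin_events <- function(stream, dt, T, spatial_downsample = 1L) {
  stopifnot(inherits(stream, "event_stream"))
  if (!is.numeric(dt) || dt <= 0) abort("dt must be positive")
  if (!is.numeric(T) || T < 1 || T != floor(T)) abort("T must be a positive integer")
  modality <- attr(stream, "modality")
  shape <- attr(stream, "sensor_shape")
  keep <- stream$t >= 0 & stream$t < T * dt
  ev <- stream[keep, , drop = FALSE]
  bin <- pmin(floor(ev$t / dt), T - 1) + 1L  # guard FP edge t/dt == T on kept rows

  if (modality == "audio") {
    F_ <- shape[1]
    data <- matrix(0, nrow = F_, ncol = T)
    if (nrow(ev) > 0) {
      idx <- cbind(ev$channel + 1L, bin)
      tab <- table(factor(idx[, 1], levels = seq_len(F_)),
                   factor(idx[, 2], levels = seq_len(T)))
      data <- matrix(as.numeric(tab), nrow = F_, ncol = T)
    }
    return(spike_tensor(data, dt, "audio"))
  }

  H <- shape[1]; W <- shape[2]
  f <- as.integer(spatial_downsample)
  if (f < 1) abort("spatial_downsample must be >= 1")
  Hp <- ceiling(H / f) * f; Wp <- ceiling(W / f) * f
  Ho <- Hp %/% f; Wo <- Wp %/% f
  data <- array(0, dim = c(2, Ho, Wo, T))
  if (nrow(ev) > 0) {
    ch <- ifelse(ev$p > 0, 1L, 2L)
    yo <- ev$y %/% f + 1L
    xo <- ev$x %/% f + 1L
    idx <- cbind(ch, yo, xo, bin)
    # accumulate duplicates
    key <- paste(idx[, 1], idx[, 2], idx[, 3], idx[, 4])
    agg <- rowsum(rep(1, nrow(idx)), key)
    first <- !duplicated(key)
    data[idx[first, , drop = FALSE]] <- agg[match(key[first], rownames(agg)), 1]
  }
  spike_tensor(data, dt, "vision")
}

#' Extend a spike tensor with an empty sequence
#'
#' Appends `T_E` all-zero time bins to the end of the tensor, enlarging the
#' simulation window so that output spikes delayed past the stimulus can still
#' fall inside the observable range during training. Original bins are
#' unchanged; the total event count is invariant.
#'
#' @param tensor A [spike_tensor()].
#' @param T_E Number of empty bins to append (>= 0).
#' @return A [spike_tensor()] with `T' = T + T_E` bins.
#' @export
extend_window <- function(tensor, T_E) {
  stopifnot(inherits(tensor, "spike_tensor"))
  if (!is.numeric(T_E) || T_E < 0 || T_E != floor(T_E)) {
    abort("T_E must be a non-negative integer")
  }
  if (T_E == 0) return(tensor)
  d <- dim(tensor)
  nd <- length(d)
  d2 <- d; d2[nd] <- d[nd] + T_E
  out <- array(0, dim = d2)
  idx <- lapply(d, seq_len)
  out <- do.call(`[<-`, c(list(out), idx, list(value = as.array(tensor))))
  spike_tensor(out, attr(tensor, "dt"), attr(tensor, "modality"))
}

#' Serialize a spike tensor
#'
#' Writes a single-file container holding the `data` array together with its
#' `dt` and `modality` attributes, using R's native serialization; the
#' round-trip through [read_spike_tensor()] is bit-exact.
#'
#' @param tensor A [spike_tensor()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spike_tensor <- function(tensor, path) {
  stopifnot(inherits(tensor, "spike_tensor"))
  saveRDS(list(data = unclass_tensor(tensor), dt = attr(tensor, "dt"),
               T = n_bins(tensor), modality = attr(tensor, "modality")),
          path, version = 3)
  invisible(path)
}

#' Read a serialized spike tensor
#' @param path Path written by [write_spike_tensor()].
#' @return A [spike_tensor()].
#' @export
read_spike_tensor <- function(path) {
  x <- readRDS(path)
  spike_tensor(x$data, x$dt, x$modality)
}

unclass_tensor <- function(tensor) {
  attributes(tensor)[c("dt", "modality", "class")] <- NULL
  tensor
}

#' @export
print.spike_tensor <- function(x, ...) {
  cat(sprintf("<spike_tensor: %s, dims [%s], dt = %g s, total count %g>\n",
              attr(x, "modality"), paste(dim(x), collapse = "x"),
              attr(x, "dt"), sum(x)))
  invisible(x)
}
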