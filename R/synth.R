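#' Synthetic event-dataset specification
#'
#' Describes a labeled synthetic event dataset with controllable temporal
#' structure, emulating the two regimes seen in real neuromorphic data:
#'
#' * `"repetitive"` (gesture-like vision): each class is a fixed
#'   spatio-temporal template of active pixels repeated every `period` steps,
#'   so the discriminative signal recurs periodically;
#' * `"nonrepetitive"` (spoken-digit-like audio): each class is a single
#'   linear sweep across the frequency channels, traversed once per trial at
#'   a class-specific tempo and direction, so *when* channels are active is
#'   as informative as *which* are active.
#'
#' Event counts per (cell, bin) are Poisson with mean `signal_rate` on active
#' cells, on top of Poisson `noise_rate` background everywhere; event times
#' get Gaussian jitter of `jitter` steps. Generation is deterministic given
#' `seed`.
#'
#' @param modality `"audio"` or `"vision"`.
#' @param C Number of classes (>= 2).
#' @param n_per_class Trials per class.
#' @param T Number of time bins per trial.
#' @param dt Bin width in seconds.
#' @param structure `"nonrepetitive"` or `"repetitive"`.
#' @param period Template repetition period in steps (repetitive mode only;
#'   must be `<= T`).
#' @param signal_rate Expected events per active cell per bin.
#' @param noise_rate Expected background events per cell per bin.
#' @param jitter Timing jitter s.d. in steps.
#' @param sensor_shape Channel count `F` (audio) or `c(H, W)` (vision).
#' @param seed RNG seed.
#' @return A list of class `"synth_spec"`.
#' @export
synth_spec <- function(modality = c("audio", "vision"), C = 3,
                       n_per_class = 100, T = 50, dt = 0.01,
                       structure = c("nonrepetitive", "repetitive"),
                       period = NULL, signal_rate = 2, noise_rate = 0.02,
                       jitter = 1, sensor_shape = NULL, seed = 0) {
  modality <- match.arg(modality)
  structure_ <- match.arg(structure)
  if (C < 2) abort("need at least 2 classes")
  if (signal_rate < 0 || noise_rate < 0) abort("rates must be non-negative")
  if (is.null(sensor_shape)) {
    sensor_shape <- if (modality == "audio") 20L else c(8L, 8L)
  }
  if (structure_ == "repetitive") {
    if (is.null(period)) period <- max(2L, T %/% 5L)
    if (period > T) abort("period must not exceed T")
  }
  base::structure(list(modality = modality, C = as.integer(C),
                       n_per_class = as.integer(n_per_class), T = as.integer(T),
                       dt = dt, structure = structure_, period = period,
                       signal_rate = signal_rate, noise_rate = noise_rate,
                       jitter = jitter, sensor_shape = as.integer(sensor_shape),
                       seed = as.integer(seed)),
                  class = "synth_spec")
}

# Active channel of class `cls` at each step (audio, nonrepetitive mode).
# Mimicking spoken words that share initial phonemes, every class opens with
# the same onset sweep over the lowest quarter of the channels for the first
# quarter of the trial; afterwards the trajectory diverges into a
# class-specific piecewise sweep: a class-dependent start offset, direction
# alternating with class, and a class-specific tempo (later classes traverse
# faster and fall silent earlier). Discrimination therefore requires
# integrating past the onset. NA marks silent steps.
sweep_channel <- function(cls, Tn, F_, C = cls) {
  n <- seq_len(Tn)
  L_on <- max(2L, round(Tn / 4))      # shared onset segment
  onset <- floor((n - 1) / (L_on - 1) * (F_ / 4 - 1e-9))
  tempo <- 1 + (cls - 1) / 2          # class 1: 1x, class 2: 1.5x, class 3: 2x
  L <- max(2L, round((Tn - L_on) / tempo))  # class segment duration
  start <- floor((cls - 1) * F_ / max(C, cls))
  pos <- (n - L_on - 1) / max(L - 1, 1)     # class-segment phase in [0, 1]
  step_ch <- floor(pos * (F_ - 1e-9))
  if (cls %% 2 == 0) step_ch <- -step_ch    # even classes sweep downward
  ch <- (start + step_ch) %% F_
  ifelse(n <= L_on, onset, ifelse(n <= L_on + L, ch, NA_real_))
}

# Pixel template of class `cls` for repetitive vision mode: a per-phase set
# of active pixels (a moving diagonal bar, class-specific offset/direction),
# repeated every `period` steps.
vision_template <- function(cls, period, H, W) {
  lapply(seq_len(period), function(ph) {
    d <- if (cls %% 2 == 0) -1 else 1
    off <- (cls - 1) * 2 + ph
    y <- seq_len(H) - 1
    x <- (d * y + off) %% W
    cbind(y = y, x = x)
  })
}

#' Generate a labeled synthetic event dataset
#'
#' Draws every trial of the dataset described by a [synth_spec()]. Each trial
#' is an [event_stream()]; the result is a tibble with one row per trial and
#' the stream in a list column.
#'
#' @param spec A [synth_spec()].
#' @return A tibble of class `"fs_dataset"` (`trial_id, class, stream`) with
#'   the spec attached as attribute `spec`.
#' @examples
#' ds <- generate_events(synth_spec(C = 2, n_per_class = 3, T = 20))
#' table(ds$class)
#' @export
generate_events <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  Tn <- spec$T; dt <- spec$dt
  t_max <- Tn * dt
  audio <- spec$modality == "audio"
  if (audio) {
    F_ <- spec$sensor_shape[1]
    n_cells <- F_
  } else {
    H <- spec$sensor_shape[1]; W <- spec$sensor_shape[2]
    n_cells <- H * W
  }

  paths <- NULL; templates <- NULL
  if (audio) {
    paths <- lapply(seq_len(spec$C), sweep_channel, Tn = Tn, F_ = F_,
                    C = spec$C)
  } else {
    templates <- lapply(seq_len(spec$C), vision_template,
                        period = spec$period, H = H, W = W)
  }

  jitter_t <- function(t0) {
    t <- t0 + rnorm(length(t0), 0, spec$jitter * dt)
    pmin(pmax(t, 0), t_max - 1e-9)
  }

  one_trial <- function(cls) {
    ev <- list()
    # background noise: Poisson(noise_rate) per cell per bin
    n_noise <- rpois(1, spec$noise_rate * n_cells * Tn)
    if (n_noise > 0) {
      tt <- runif(n_noise, 0, t_max)
      if (audio) {
        ev[[1]] <- tibble(t = tt, channel = sample.int(F_, n_noise, TRUE) - 1L)
      } else {
        ev[[1]] <- tibble(t = tt, x = sample.int(W, n_noise, TRUE) - 1L,
                          y = sample.int(H, n_noise, TRUE) - 1L,
                          p = sample(c(-1, 1), n_noise, TRUE))
      }
    }
    if (audio) {
      path <- paths[[cls]]
      for (n in seq_len(Tn)) {
        if (is.na(path[n]) || spec$signal_rate == 0) next
        k <- rpois(1, spec$signal_rate)
        if (k == 0) next
        t0 <- (n - 1) * dt + runif(k, 0, dt)
        ev[[length(ev) + 1]] <- tibble(t = jitter_t(t0),
                                       channel = rep(path[n], k))
      }
    } else {
      tmpl <- templates[[cls]]
      for (n in seq_len(Tn)) {
        cells <- tmpl[[(n - 1) %% spec$period + 1]]
        k <- rpois(nrow(cells), spec$signal_rate)
        tot <- sum(k)
        if (tot == 0) next
        rows <- rep(seq_len(nrow(cells)), k)
        t0 <- (n - 1) * dt + runif(tot, 0, dt)
        ev[[length(ev) + 1]] <- tibble(t = jitter_t(t0),
                                       x = cells[rows, "x"],
                                       y = cells[rows, "y"],
                                       p = sample(c(-1, 1), tot, TRUE))
      }
    }
    events <- if (length(ev) == 0) {
      if (audio) tibble(t = numeric(), channel = numeric()) else
        tibble(t = numeric(), x = numeric(), y = numeric(), p = numeric())
    } else {
      dplyr::bind_rows(ev)
    }
    event_stream(events, spec$sensor_shape, spec$modality)
  }

  rows <- list()
  id <- 0L
  for (cls in seq_len(spec$C)) {
    for (r in seq_len(spec$n_per_class)) {
      id <- id + 1L
      rows[[id]] <- tibble(trial_id = id, class = cls,
                           stream = list(one_trial(cls)))
    }
  }
  out <- dplyr::bind_rows(rows)
  base::structure(out, spec = spec,
                  class = c("fs_dataset", class(tibble())))
}

#' Stratified train/test split
#'
#' Splits a generated dataset into disjoint train and test subsets with the
#' same class proportions, deterministically for a given seed.
#'
#' @param dataset An `"fs_dataset"` from [generate_events()].
#' @param fraction Fraction of each class assigned to the training set
#'   (0 < fraction < 1).
#' @param seed RNG seed for the within-class shuffles.
#' @return A list with elements `train` and `test`, each an `"fs_dataset"`.
#' @export
train_test_split <- function(dataset, fraction, seed = 0) {
  if (fraction <= 0 || fraction >= 1) abort("fraction must be in (0, 1)")
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  counts <- table(dataset$class)
  if (any(counts < 2)) abort("every class needs at least 2 trials to split")
  tr_idx <- integer(0)
  for (cls in sort(unique(dataset$class))) {
    idx <- which(dataset$class == cls)
    n_tr <- round(fraction * length(idx))
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
    tr_idx <- c(tr_idx, sample(idx, n_tr))
  }
  tr_idx <- sort(tr_idx)
  spec <- attr(dataset, "spec")
  mk <- function(d) base::structure(d, spec = spec,
                                    class = c("fs_dataset", class(tibble())))
  list(train = mk(dataset[tr_idx, ]),
       test = mk(dataset[-tr_idx, ]))
}

#' Bin a dataset into stacked input tensors
#'
#' Bins every trial's event stream with [bin_events()] and stacks the results
#' into a single `[n_in, T, N]` array ready for [train()] / [evaluate()].
#'
#' @param dataset An `"fs_dataset"`.
#' @param dt Bin width in seconds (defaults to the generator's `dt`).
#' @param T Number of bins (defaults to the generator's `T`).
#' @param spatial_downsample Block size for vision data.
#' @return A list: `x` (input array with attribute `dt`) and `labels`.
#' @export
bin_dataset <- function(dataset, dt = NULL, T = NULL, spatial_downsample = 1L) {
  spec <- attr(dataset, "spec")
  if (is.null(dt)) dt <- spec$dt
  if (is.null(T)) T <- spec$T
  tensors <- lapply(dataset$stream, bin_events, dt = dt, T = T,
                    spatial_downsample = spatial_downsample)
  list(x = stack_tensors(tensors), labels = as.integer(dataset$class))
}

#' Write a dataset to a directory of CSV event files
#'
#' Emits one CSV per trial (`trial_<id>.csv` in the package event format)
#' plus a `labels.csv` manifest (`trial_id, class, file`).
#'
#' @param dataset An `"fs_dataset"`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sprintf("trial_%04d.csv", dataset$trial_id)
  for (i in seq_len(nrow(dataset))) {
    write_events(dataset$stream[[i]], file.path(dir, files[i]))
  }
  manifest <- data.frame(trial_id = dataset$trial_id,
                         class = dataset$class, file = files)
  utils::write.csv(manifest, file.path(dir, "labels.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
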