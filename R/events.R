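#' Event streams
#'
#' An event stream is the raw output of an asynchronous neuromorphic sensor:
#' a table of timestamped events. Vision sensors (DVS-style) emit events with
#' pixel coordinates and a polarity (+1 for a brightness increase, -1 for a
#' decrease); audio sensors (silicon cochleas) emit events on frequency
#' channels without polarity. `event_stream()` validates a plain data frame of
#' events and returns a tibble of class `"event_stream"` carrying the sensor
#' geometry as attributes.
#'
#' Columns are `t, x, y, p` for vision (`x` is the column index, `y` the row
#' index, both 0-based) and `t, channel` for audio (`channel` 0-based). Times
#' are in seconds. Events are sorted by time on construction; coordinates must
#' lie strictly inside the sensor shape and polarity must be +1 or -1.
#'
#' @param events A data frame with columns `t, x, y, p` (vision) or
#'   `t, channel` (audio). A zero-row data frame is a valid empty stream.
#' @param sensor_shape Integer vector: `c(H, W)` (rows, cols) for vision, or a
#'   single channel count `F` for audio.
#' @param modality `"vision"` or `"audio"`.
#' @return A tibble of class `"event_stream"` with attributes `sensor_shape`
#'   and `modality`, sorted by `t`.
#' @examples
#' ev <- event_stream(
#'   data.frame(t = c(0.02, 0.01), x = c(3, 0), y = c(2, 1), p = c(1, -1)),
#'   sensor_shape = c(4, 4), modality = "vision"
#' )
#' ev$t  # sorted
#' @export
event_stream <- function(events, sensor_shape, modality = c("vision", "audio")) {
  modality <- match.arg(modality)
  events <- as_tibble(events)
  req <- if (modality == "vision") c("t", "x", "y", "p") else c("t", "channel")
  missing_cols <- setdiff(req, names(events))
  if (length(missing_cols) > 0) {
    abort(paste0("event table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  events <- events[req]
  if (modality == "vision") {
    if (length(sensor_shape) != 2 || any(sensor_shape < 1)) {
      abort("vision sensor_shape must be c(H, W) with positive entries")
    }
  } else {
    if (length(sensor_shape) != 1 || sensor_shape < 1) {
      abort("audio sensor_shape must be a single positive channel count")
    }
  }
  sensor_shape <- as.integer(sensor_shape)
  validate_events(events, sensor_shape, modality)
  events <- events[order(events$t), , drop = FALSE]
  structure(events,
    sensor_shape = sensor_shape, modality = modality,
    class = c("event_stream", class(tibble())))
}

validate_events <- function(events, sensor_shape, modality, line_offset = NA) {
  where <- function(i) {
    if (is.na(line_offset)) paste0("event ", i) else paste0("line ", i + line_offset)
  }
  bad <- which(!is.finite(events$t) | events$t < 0)
  if (length(bad) > 0) abort(paste0("invalid timestamp at ", where(bad[1])))
  if (modality == "vision") {
    H <- sensor_shape[1]; W <- sensor_shape[2]
    bad <- which(!is.finite(events$x) | events$x != floor(events$x) |
                   events$x < 0 | events$x >= W)
    if (length(bad) > 0) {
      abort(paste0("x coordinate outside [0, ", W - 1, "] at ", where(bad[1])))
    }
    bad <- which(!is.finite(events$y) | events$y != floor(events$y) |
                   events$y < 0 | events$y >= H)
    if (length(bad) > 0) {
      abort(paste0("y coordinate outside [0, ", H - 1, "] at ", where(bad[1])))
    }
    bad <- which(!(events$p %in% c(-1, 1)))
    if (length(bad) > 0) abort(paste0("polarity must be +1 or -1 at ", where(bad[1])))
  } else {
    F_ <- sensor_shape[1]
    bad <- which(!is.finite(events$channel) | events$channel != floor(events$channel) |
                   events$channel < 0 | events$channel >= F_)
    if (length(bad) > 0) {
      abort(paste0("channel outside [0, ", F_ - 1, "] at ", where(bad[1])))
    }
  }
  invisible(TRUE)
}

#' Number of events in a stream
#' @param stream An [event_stream()].
#' @return Integer event count.
#' @export
n_events <- function(stream) nrow(stream)

#' Read an event stream from CSV
#'
#' The on-disk format is a plain CSV with a header naming the columns:
#' `t,x,y,p` for vision or `t,channel` for audio, one event per row, times in
#' seconds as decimals. Malformed rows raise a parse error naming the
#' offending file line; out-of-range coordinates raise a validation error.
#'
#' @param path Path to a CSV event file.
#' @param modality `"vision"` or `"audio"`; must match the file header.
#' @param sensor_shape `c(H, W)` for vision or channel count for audio.
#' @return A validated, time-sorted [event_stream()].
#' @seealso [write_events()] for the inverse; the pair round-trips bit-exactly.
#' @export
read_events <- function(path, modality = c("vision", "audio"), sensor_shape) {
  modality <- match.arg(modality)
  if (!file.exists(path)) abort(paste0("no such event file: ", path))
  req <- if (modality == "vision") c("t", "x", "y", "p") else c("t", "channel")
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(trimws(header), req)) {
    abort(paste0(path, ": header must be '", paste(req, collapse = ","),
                 "' for ", modality, " events"))
  }
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  events <- tibble(!!!lapply(setNames(req, req), function(cn) {
    suppressWarnings(as.numeric(raw[[cn]]))
  }))
  for (cn in req) {
    bad <- which(is.na(events[[cn]]) & !is.na(raw[[cn]]) | is.na(raw[[cn]]))
    if (length(bad) > 0) {
      abort(paste0(path, ": cannot parse column '", cn, "' at line ", bad[1] + 1L))
    }
  }
  validate_events(events, as.integer(sensor_shape), modality, line_offset = 1L)
  event_stream(events, sensor_shape, modality)
}

#' Write an event stream to CSV
#'
#' Times are written with 17 significant digits so that
#' `read_events(write_events(x))` reproduces the stream bit-exactly.
#'
#' @param stream An [event_stream()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(stream, path) {
  stopifnot(inherits(stream, "event_stream"))
  modality <- attr(stream, "modality")
  cols <- if (modality == "vision") c("t", "x", "y", "p") else c("t", "channel")
  lines <- paste(cols, collapse = ",")
  if (nrow(stream) > 0) {
    fmt <- vapply(cols, function(cn) {
      v <- stream[[cn]]
      if (cn == "t") sprintf("%.17g", v) else sprintf("%d", as.integer(v))
    }, character(nrow(stream)))
    fmt <- matrix(fmt, nrow = nrow(stream))
    lines <- c(lines, apply(fmt, 1, paste, collapse = ","))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("<event_stream: %s, %d events, sensor [%s]>\n",
              attr(x, "modality"), nrow(x),
              paste(attr(x, "sensor_shape"), collapse = "x")))
  NextMethod()
}
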