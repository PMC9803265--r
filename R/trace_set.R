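#' Trace sets: tidy containers for normalized fluorescence traces
#'
#' A trace set is a tibble with one row per cell and frame, columns `cell`
#' (integer id), `time` (seconds) and `dff` (background-subtracted
#' fluorescence scaled to the interpolated baseline, so a quiescent cell sits
#' at `dff = 1`). The acquisition frame rate is carried as an attribute so
#' downstream operations (template matching, lagged cross-correlation,
#' state discretization) can convert between frames and seconds.
#'
#' @param x For `as_trace_set()`, a data frame with columns `cell`, `time`,
#'   `dff`; for `trace_matrix()`, a trace set.
#' @param mat A frames x cells numeric matrix.
#' @param frame_rate Acquisition rate in frames per second.
#' @param cells Optional integer cell ids (defaults to column index).
#'
#' @return `new_trace_set()` and `as_trace_set()` return a `trace_set`
#'   tibble; `trace_matrix()` returns a frames x cells matrix with cell ids
#'   as column names; `frame_rate()` returns a scalar.
#' @examples
#' ts <- new_trace_set(matrix(1, nrow = 40, ncol = 2), frame_rate = 20)
#' trace_matrix(ts)[1:3, ]
#' @export
new_trace_set <- function(mat, frame_rate, cells = NULL) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  check_number(frame_rate, "frame_rate", lower = 1e-9)
  if (is.null(cells)) cells <- seq_len(ncol(mat))
  n_frames <- nrow(mat)
  out <- tibble(
    cell = rep(as.integer(cells), each = n_frames),
    time = rep((seq_len(n_frames) - 1L) / frame_rate, times = ncol(mat)),
    dff = as.vector(mat)
  )
  attr(out, "frame_rate") <- frame_rate
  attr(out, "n_frames") <- n_frames
  class(out) <- c("trace_set", class(out))
  out
}

#' @rdname new_trace_set
#' @export
as_trace_set <- function(x, frame_rate = NULL) {
  if (inherits(x, "trace_set") && is.null(frame_rate)) return(x)
  x <- as_tibble(x)
  need <- c("cell", "time", "dff")
  if (!all(need %in% names(x))) {
    abort("A trace set needs columns `cell`, `time` and `dff`.")
  }
  if (is.null(frame_rate)) {
    dt <- sort(unique(x$time))
    if (length(dt) < 2L) abort("Cannot infer `frame_rate` from a single frame.")
    frame_rate <- 1 / stats::median(diff(dt))
  }
  x <- arrange(x, .data$cell, .data$time)
  attr(x, "frame_rate") <- frame_rate
  attr(x, "n_frames") <- length(unique(x$time))
  class(x) <- unique(c("trace_set", class(x)))
  x
}

#' @rdname new_trace_set
#' @export
trace_matrix <- function(x) {
  x <- as_trace_set(x)
  cells <- sort(unique(x$cell))
  times <- sort(unique(x$time))
  x <- arrange(x, .data$cell, .data$time)
  if (nrow(x) != length(cells) * length(times)) {
    abort("Trace set is ragged: every cell must be sampled at every frame.")
  }
  mat <- matrix(x$dff, nrow = length(times), ncol = length(cells))
  colnames(mat) <- cells
  mat
}

#' @rdname new_trace_set
#' @export
frame_rate <- function(x) {
  fr <- attr(x, "frame_rate")
  if (is.null(fr)) abort("Object carries no `frame_rate` attribute.")
  fr
}

#' Recording duration of a trace set or spike train set, in seconds
#'
#' @param x A `trace_set` or `spike_trains` object.
#' @return Duration in seconds.
#' @export
recording_duration <- function(x) {
  if (inherits(x, "trace_set")) {
    return(attr(x, "n_frames") / frame_rate(x))
  }
  d <- attr(x, "duration")
  if (is.null(d)) abort("Object carries no `duration` attribute.")
  d
}
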