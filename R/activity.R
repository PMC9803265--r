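#' Active population fraction
#'
#' Number of active cells over total cell number, in \[0, 1\]. A cell is
#' active if it showed at least one detected transient in the condition.
#'
#' @param flags A logical vector of per-cell activity flags, or a
#'   [classify_active()] tibble.
#' @param condition Condition to evaluate when `flags` is a tibble covering
#'   several conditions.
#' @return A proportion in \[0, 1\].
#' @examples
#' active_population_fraction(c(TRUE, TRUE, TRUE, FALSE))
#' @export
active_population_fraction <- function(flags, condition = NULL) {
  if (inherits(flags, "data.frame")) {
    conds <- unique(flags$condition)
    if (is.null(condition)) {
      if (length(conds) > 1) {
        abort("Several conditions present; specify `condition`.")
      }
      condition <- conds
    }
    flags <- flags$active[flags$condition == condition]
  }
  if (length(flags) == 0) abort("No cells: active fraction is undefined.")
  mean(as.logical(flags))
}

#' Mean event rate over active cells
#'
#' Average number of detected transients per minute, taken over the active
#' cells of the recording (cells without events are excluded from the
#' mean). With no active cells the rate is reported as 0 and flagged via
#' the `"no_active_cells"` attribute.
#'
#' @param events An `event_set` or `spike_trains` tibble with a `cell`
#'   column.
#' @param duration Recording length in seconds (defaults to the object's
#'   attribute).
#' @return Events per minute (scalar).
#' @examples
#' ev <- tibble::tibble(cell = rep(1L, 27))
#' mean_event_rate(ev, duration = 180)  # 9 events/min
#' @export
mean_event_rate <- function(events, duration = NULL) {
  if (is.null(duration)) duration <- attr(events, "duration")
  check_number(duration, "duration", lower = 1e-9)
  if (nrow(events) == 0) {
    return(structure(0, no_active_cells = TRUE))
  }
  per_cell <- table(events$cell)
  mean(as.vector(per_cell)) / (duration / 60)
}

#' Synchronization index from pairwise lagged cross-correlation
#'
#' For each pair of active cells the traces are z-scored and the normalized
#' cross-correlation \eqn{C_{xy}(\tau) = \frac{1}{N-\tau}\sum_n
#' x_{n+\tau} y_n} is evaluated at every lag \eqn{|\tau| \le}
#' `tau_max`; the pair score is the maximum over lags (or the zero-lag
#' value with `method = "zero_lag"`), clipped below at 0 so the index
#' stays in \[0, 1\]. The synchronization index (SI) is the mean pair score
#' over all unordered pairs: 1 for identical traces, ~0 for independent
#' ones. Constant (zero-variance) traces are excluded with a warning.
#'
#' @param traces A trace set; restrict to active cells via `cells`.
#' @param tau_max Maximum lag searched, seconds.
#' @param method `"max_lag"` (default) or `"zero_lag"`.
#' @param cells Optional integer ids of the (active) cells to include.
#'
#' @return An object of class `sync_index`: list with `si`, `pairs`
#'   (symmetric score matrix, unit diagonal), `n_cells`, `excluded`,
#'   `undefined`. `tidy()` gives one row per pair; `glance()` a one-row
#'   summary.
#' @examples
#' tr <- new_trace_set(matrix(rnorm(200), 100, 2), frame_rate = 20)
#' synchronization_index(tr)$si
#' @export
synchronization_index <- function(traces, tau_max = 1,
                                  method = c("max_lag", "zero_lag"),
                                  cells = NULL) {
  method <- match.arg(method)
  traces <- as_trace_set(traces)
  fr <- frame_rate(traces)
  mat <- trace_matrix(traces)
  if (!is.null(cells)) {
    mat <- mat[, colnames(mat) %in% as.character(cells), drop = FALSE]
  }
  sds <- apply(mat, 2, sd)
  if (any(sds == 0)) {
    warn(sprintf("Excluding %d constant trace(s) from the SI computation.",
                 sum(sds == 0)))
    mat <- mat[, sds > 0, drop = FALSE]
  }
  ids <- as.integer(colnames(mat))
  if (ncol(mat) < 2) {
    warn("Fewer than 2 usable cells: SI is undefined.")
    return(structure(list(si = NA_real_, pairs = NULL, n_cells = ncol(mat),
                          excluded = sum(sds == 0), undefined = TRUE),
                     class = "sync_index"))
  }
  pairs <- pair_correlation(mat, max_lag = if (method == "zero_lag") 0L
                            else as.integer(round(tau_max * fr)))
  pairs <- pmin(pmax(pairs, 0), 1)
  diag(pairs) <- 1
  dimnames(pairs) <- list(ids, ids)
  si <- mean(pairs[upper.tri(pairs)])
  structure(list(si = si, pairs = pairs, n_cells = ncol(mat),
                 excluded = sum(sds == 0), undefined = FALSE),
            class = "sync_index")
}

# Symmetric max-over-lag normalized cross-correlation matrix.
# Columns are z-scored with the population SD so identical traces score 1.
pair_correlation <- function(mat, max_lag) {
  n <- nrow(mat)
  z <- scale(mat, center = TRUE, scale = FALSE)
  z <- sweep(z, 2, sqrt(colMeans(z^2)), "/")
  best <- crossprod(z) / n
  best <- pmax(best, t(best))
  lag <- 1L
  while (lag <= max_lag) {
    m <- crossprod(z[(1 + lag):n, , drop = FALSE],
                   z[1:(n - lag), , drop = FALSE]) / (n - lag)
    best <- pmax(best, m, t(m))
    lag <- lag + 1L
  }
  best
}

#' @export
print.sync_index <- function(x, ...) {
  if (x$undefined) cat("<sync_index> undefined (fewer than 2 usable cells)\n")
  else cat(sprintf("<sync_index> SI = %.3f over %d cells\n", x$si, x$n_cells))
  invisible(x)
}

#' @method tidy sync_index
#' @export
tidy.sync_index <- function(x, ...) {
  if (x$undefined) return(tibble(cell_a = integer(), cell_b = integer(),
                                 score = double()))
  idx <- which(upper.tri(x$pairs), arr.ind = TRUE)
  ids <- as.integer(rownames(x$pairs))
  tibble(cell_a = ids[idx[, 1]], cell_b = ids[idx[, 2]],
         score = x$pairs[idx])
}

#' @method glance sync_index
#' @export
glance.sync_index <- function(x, ...) {
  tibble(si = x$si, n_cells = x$n_cells, excluded = x$excluded,
         undefined = x$undefined)
}

#' Island-level activity metrics in one call
#'
#' Convenience wrapper combining [active_population_fraction()],
#' [mean_event_rate()] and [synchronization_index()] for one recording.
#'
#' @param traces A trace set.
#' @param events Detected events for the same recording (defaults to
#'   running [detect_events()] with default settings).
#' @param ... Passed to [synchronization_index()].
#' @return A one-row tibble: `active_fraction`, `event_rate`, `sync_index`,
#'   `n_cells`, `n_active`.
#' @export
activity_metrics <- function(traces, events = NULL, ...) {
  traces <- as_trace_set(traces)
  if (is.null(events)) events <- detect_events(traces)
  total <- attr(events, "n_cells") %||% length(unique(traces$cell))
  active_ids <- sort(unique(events$cell))
  si <- if (length(active_ids) >= 2) {
    synchronization_index(traces, cells = active_ids, ...)$si
  } else NA_real_
  tibble(
    active_fraction = length(active_ids) / total,
    event_rate = mean_event_rate(events,
                                 duration = recording_duration(traces)),
    sync_index = si,
    n_cells = as.integer(total),
    n_active = length(active_ids)
  )
}
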