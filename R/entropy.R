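#' Discretize a cell's activity into a two-state sequence
#'
#' Frames falling within `[onset, onset + window]` of any detected event
#' are labelled active (1); all other frames inactive (0). The default
#' window of 1 s approximates the duration of a calcium transient.
#'
#' @param onsets Event onset times for one cell, seconds.
#' @param n_frames Number of frames in the recording.
#' @param frame_rate Frames per second.
#' @param window Active window per event, seconds.
#' @return An integer vector of 0/1 states, one per frame.
#' @examples
#' sum(discretize_states(10, 400, 20))  # 21 active frames
#' @export
discretize_states <- function(onsets, n_frames, frame_rate, window = 1) {
  check_number(window, "window", lower = 0)
  states <- integer(n_frames)
  t_frames <- (seq_len(n_frames) - 1) / frame_rate
  for (t0 in onsets) {
    states[t_frames >= t0 - 1e-9 & t_frames <= t0 + window + 1e-9] <- 1L
  }
  states
}

#' First-order transition matrix of a binary state sequence
#'
#' Counts consecutive-symbol pairs and normalizes rows. A state that is
#' never visited yields a flagged uniform row rather than an error, so
#' silent cells still produce a defined (zero-entropy) chain.
#'
#' @param states Integer/logical vector of 0/1 states (length >= 2).
#' @return A list of class `transition_matrix`: `P` (2x2 row-stochastic),
#'   `counts`, `flagged` (logical per row: row was unobserved).
#' @examples
#' transition_matrix(rep(c(0L, 1L), 50))$P
#' @export
transition_matrix <- function(states) {
  states <- as.integer(states)
  if (length(states) < 2) abort("Need at least 2 states to count transitions.")
  if (!all(states %in% c(0L, 1L))) abort("States must be coded 0/1.")
  from <- factor(states[-length(states)], levels = c(0L, 1L))
  to <- factor(states[-1L], levels = c(0L, 1L))
  counts <- table(from, to)
  counts <- matrix(as.numeric(counts), 2, 2,
                   dimnames = list(c("0", "1"), c("0", "1")))
  tot <- rowSums(counts)
  flagged <- tot == 0
  P <- counts / ifelse(tot > 0, tot, 1)
  P[flagged, ] <- 0.5
  structure(list(P = P, counts = counts, flagged = flagged),
            class = "transition_matrix")
}

#' Markov entropy of a two-state transition matrix
#'
#' The entropy rate \eqn{E = \sum_i \pi_i \, h(P_{i\cdot})} where
#' \eqn{h} is the Shannon entropy (base 2, with \eqn{0 \log 0 = 0}) of a
#' row and \eqn{\pi} the stationary distribution of the chain. With two
#' states E lies in \[0, 1\]: 0 for deterministic transitions (a fully
#' predictable cell), 1 for fair-coin transitions (a maximally flexible
#' one). `method = "row_mean"` replaces the stationary weights by a plain
#' row average, as a sensitivity variant.
#'
#' @param P A 2x2 row-stochastic matrix or a [transition_matrix()] result.
#' @param method `"stationary"` (entropy rate, default) or `"row_mean"`.
#' @return Entropy in \[0, 1\].
#' @examples
#' markov_entropy(matrix(c(0, 1, 1, 0), 2, 2))        # 0
#' markov_entropy(matrix(0.5, 2, 2))                  # 1
#' @export
markov_entropy <- function(P, method = c("stationary", "row_mean")) {
  method <- match.arg(method)
  if (inherits(P, "transition_matrix")) P <- P$P
  if (!is.matrix(P) || any(dim(P) != 2) || any(P < -1e-9) ||
      any(abs(rowSums(P) - 1) > 1e-6)) {
    abort("`P` must be a 2x2 row-stochastic matrix.")
  }
  h <- apply(P, 1, shannon_entropy)
  if (method == "row_mean") return(mean(h))
  a <- P[1, 2]; b <- P[2, 1]
  if (a + b == 0) return(0)   # identity chain: both rows deterministic
  pi_ <- c(b, a) / (a + b)
  sum(pi_ * h)
}

#' Per-cell Markov entropy across an island
#'
#' Discretizes each cell's event train, fits the two-state transition
#' matrix and reports the per-cell entropy together with the island mean
#' and its standard error. Cells with no events (also the inactive cells
#' of the recording) are excluded from the island mean by default.
#'
#' @param events An `event_set` (or `spike_trains`) tibble.
#' @param n_frames,frame_rate Recording geometry; default from attributes.
#' @param window Active window per event, seconds.
#' @param include_silent Keep event-free cells (entropy 0) in the summary?
#' @param method Passed to [markov_entropy()].
#'
#' @return A list of class `island_entropy`: `cells` (tibble `cell`,
#'   `n_events`, `entropy`), `mean`, `se`, `n`. `tidy()` returns the
#'   per-cell tibble, `glance()` the one-row summary.
#' @examples
#' st <- generate_spike_trains(20, "asynchronous", rate = 10,
#'                             duration = 120, seed = 1)
#' glance(island_entropy(st, frame_rate = 20))
#' @export
island_entropy <- function(events, n_frames = NULL, frame_rate = NULL,
                           window = 1, include_silent = FALSE,
                           method = "stationary") {
  if (is.null(frame_rate)) frame_rate <- attr(events, "frame_rate") %||% 20
  if (is.null(n_frames)) {
    dur <- attr(events, "duration")
    if (is.null(dur)) abort("Provide `n_frames` (or events with a duration attribute).")
    n_frames <- round(dur * frame_rate)
  }
  total <- attr(events, "n_cells") %||% max(events$cell, 0L)
  time_col <- if ("onset" %in% names(events)) "onset" else "time"
  by_cell <- split(events[[time_col]],
                   factor(events$cell, levels = seq_len(total)))
  cells <- tibble(
    cell = seq_len(total),
    n_events = unname(lengths(by_cell)),
    entropy = unname(vapply(by_cell, function(on) {
      markov_entropy(transition_matrix(
        discretize_states(on, n_frames, frame_rate, window)), method = method)
    }, numeric(1)))
  )
  keep <- if (include_silent) cells else filter(cells, .data$n_events > 0)
  structure(list(
    cells = cells,
    mean = if (nrow(keep)) mean(keep$entropy) else NA_real_,
    se = if (nrow(keep) > 1) sd(keep$entropy) / sqrt(nrow(keep)) else NA_real_,
    n = nrow(keep)
  ), class = "island_entropy")
}

#' @export
print.island_entropy <- function(x, ...) {
  cat(sprintf("<island_entropy> mean E = %.3f +/- %.3f SE over %d cells\n",
              x$mean, x$se, x$n))
  invisible(x)
}

#' @method tidy island_entropy
#' @export
tidy.island_entropy <- function(x, ...) x$cells

#' @method glance island_entropy
#' @export
glance.island_entropy <- function(x, ...) {
  tibble(mean_entropy = x$mean, se = x$se, n_cells = x$n)
}

#' Invert the binary entropy function
#'
#' Finds the transition probability `p <= 0.5` with binary entropy
#' `h(p) = target` (base 2); useful for constructing two-state chains with
#' a prescribed analytic entropy.
#'
#' @param target Entropy value in \[0, 1\].
#' @return Probability `p` in \[0, 0.5\].
#' @examples
#' p <- binary_entropy_inverse(0.67)
#' @export
binary_entropy_inverse <- function(target) {
  check_number(target, "target", 0, 1)
  if (target == 0) return(0)
  if (target == 1) return(0.5)
  stats::uniroot(function(p) shannon_entropy(c(p, 1 - p)) - target,
                 c(1e-12, 0.5), tol = 1e-12)$root
}
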