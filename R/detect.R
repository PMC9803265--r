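#' Detect calcium transients by template correlation
#'
#' Scores every position of each cell's dF/F trace by the best Pearson
#' correlation between the (z-scored) trace fragment starting there and
#' any waveform of a template library, making detection invariant to
#' transient amplitude. Events are then accepted by sequential greedy
#' matched pursuit: the highest-scoring position at or above `r_min` is
#' accepted, the best-fitting template (least-squares amplitude) is
#' subtracted from the trace, positions within the `refractory` window
#' are suppressed, the neighbourhood is re-scored on the residual, and
#' the process repeats until no position reaches `r_min`. Subtraction
#' lets transients that ride on a neighbour's rise or decay be recovered
#' once the neighbour is accounted for, and removes decay tails that
#' would otherwise mimic slow templates. Near the end of the recording,
#' truncated fragments (at least `min_tail_s` long) are correlated
#' against the matching initial portion of each template so transients
#' that outlast the recording are still scored.
#'
#' @param traces A trace set (see [new_trace_set()]).
#' @param templates A [template_library()]; defaults to the standard
#'   128-waveform library at the trace frame rate.
#' @param r_min Correlation threshold for detection.
#' @param refractory Minimum separation between accepted onsets, seconds.
#' @param min_tail_s Shortest truncated fragment scored at the trace end,
#'   seconds.
#' @param min_amplitude Smallest accepted fitted transient amplitude, in
#'   dF/F units. Correlation is amplitude-invariant, so an absolute floor
#'   is needed to reject residual shapes far below any real transient
#'   (typical transients are ~0.2 dF/F and larger).
#'
#' @return An `event_set` tibble: `cell`, `onset` (seconds, template
#'   start), `score` (template correlation at acceptance), carrying
#'   `duration`, `n_cells` and `frame_rate` attributes.
#' @examples
#' st <- generate_spike_trains(5, "asynchronous", rate = 6, duration = 60,
#'                             seed = 1)
#' tr <- render_traces(st, seed = 2)
#' ev <- detect_events(tr)
#' @export
detect_events <- function(traces, templates = NULL, r_min = 0.85,
                          refractory = 0.5, min_tail_s = 1,
                          min_amplitude = 0.1) {
  traces <- as_trace_set(traces)
  fr <- frame_rate(traces)
  if (is.null(templates)) templates <- template_library(frame_rate = fr)
  stopifnot(inherits(templates, "template_library"))
  if (abs(templates$frame_rate - fr) > 1e-8) {
    abort("Template library and traces use different frame rates.")
  }
  check_number(r_min, "r_min", -1, 1)
  check_number(refractory, "refractory", lower = 0)
  mat <- trace_matrix(traces)
  n_frames <- nrow(mat)
  len <- nrow(templates$waveforms)
  if (n_frames < len) abort("Traces are shorter than the template length.")
  min_tail <- min(max(3L, round(min_tail_s * fr)), len)
  refrac_frames <- max(1L, round(refractory * fr))

  events <- purrr::map(seq_len(ncol(mat)), function(j) {
    detect_cell(mat[, j], templates$waveforms, r_min, refrac_frames,
                min_tail, fr, min_amplitude)
  })
  cells <- as.integer(colnames(mat))
  out <- tibble(
    cell = rep(cells, vapply(events, nrow, 0L)),
    bind_rows(events)
  )
  attr(out, "duration") <- n_frames / fr
  attr(out, "n_cells") <- length(cells)
  attr(out, "frame_rate") <- fr
  class(out) <- c("event_set", class(out))
  out
}

# Sequential matched pursuit on a single trace.
detect_cell <- function(x, w, r_min, refrac_frames, min_tail, fr,
                        min_amplitude = 0) {
  n <- length(x)
  len <- nrow(w)
  n_pos <- n - min_tail + 1L
  w_c <- sweep(w, 2, colMeans(w))
  w_ss <- colSums(w_c^2)
  score <- score_positions(x, seq_len(n_pos), w, w_c, w_ss, len, n)
  onsets <- integer(0)
  scores <- numeric(0)
  max_events <- n %/% refrac_frames + 1L
  while (length(onsets) < max_events) {
    p <- which.max(score)
    s <- score[p]
    if (!is.finite(s) || s < r_min) break
    # least-squares amplitude of the best-fitting template
    m <- min(len, n - p + 1L)
    frag <- x[p:(p + m - 1L)]
    tw <- w[seq_len(m), , drop = FALSE]
    tw_c <- sweep(tw, 2, colMeans(tw))
    f_c <- frag - mean(frag)
    cors <- as.vector(f_c %*% tw_c) /
      (sqrt(sum(f_c^2)) * sqrt(colSums(tw_c^2)))
    k <- which.max(cors)
    amp <- max(0, sum(f_c * tw_c[, k]) / sum(tw_c[, k]^2))
    if (amp < min_amplitude) {   # residual shape, not a real transient
      score[p] <- -Inf
      next
    }
    onsets <- c(onsets, p)
    scores <- c(scores, s)
    x[p:(p + m - 1L)] <- frag - amp * tw[seq_len(m), k]
    # suppress the refractory window, re-score the affected neighbourhood
    block <- max(1L, p - refrac_frames):min(n_pos, p + refrac_frames)
    score[block] <- -Inf
    touch <- setdiff(max(1L, p - len + 1L):min(n_pos, p + len - 1L), block)
    if (length(touch)) {
      score[touch] <- score_positions(x, touch, w, w_c, w_ss, len, n)
    }
  }
  ord <- order(onsets)
  tibble(onset = (onsets[ord] - 1) / fr, score = scores[ord])
}

# Best-template Pearson correlation at the given template-start positions;
# positions within `len` of the trace end use truncated templates.
score_positions <- function(x, pos, w, w_c, w_ss, len, n) {
  out <- numeric(length(pos))
  full <- pos <= n - len + 1L
  if (any(full)) {
    pf <- pos[full]
    frag <- matrix(x[outer(pf, 0:(len - 1L), "+")], nrow = length(pf))
    num <- frag %*% w_c
    f_mean <- rowMeans(frag)
    f_sd2 <- pmax(rowSums(frag^2) - len * f_mean^2, 0)
    r <- num / sqrt(outer(f_sd2, w_ss))
    r[!is.finite(r)] <- 0
    out[full] <- apply(r, 1, max)
  }
  if (any(!full)) {
    for (i in which(!full)) {
      p <- pos[i]
      frag <- x[p:n]
      m <- length(frag)
      tw <- w[seq_len(m), , drop = FALSE]
      tw_c <- sweep(tw, 2, colMeans(tw))
      f_c <- frag - mean(frag)
      s <- as.vector(f_c %*% tw_c) /
        (sqrt(sum(f_c^2)) * sqrt(colSums(tw_c^2)))
      s[!is.finite(s)] <- 0
      out[i] <- max(s)
    }
  }
  out
}

#' Flag active cells and filter never-active ROIs
#'
#' A cell is active in a condition if it shows at least one detected
#' transient there; cells with no detectable transients in any recorded
#' condition are removed from the analysis population (segmentation
#' artifacts or dead cells).
#'
#' @param events A single `event_set` or a named list of event sets, one
#'   per recorded condition, covering an identical cell population.
#' @param n_cells Total cell count (defaults to the event sets' attribute).
#'
#' @return A tibble with one row per cell and condition: `cell`,
#'   `condition`, `active`, and `retained` (TRUE unless the cell is
#'   event-free in every condition).
#' @examples
#' ev <- tibble::tibble(cell = c(1L, 1L, 3L), onset = c(1, 2, 3),
#'                      score = 0.9)
#' classify_active(ev, n_cells = 4)
#' @export
classify_active <- function(events, n_cells = NULL) {
  if (inherits(events, "data.frame")) events <- list(baseline = events)
  if (is.null(names(events)) || any(!nzchar(names(events)))) {
    names(events) <- paste0("condition_", seq_along(events))
  }
  counts <- vapply(events, function(e) attr(e, "n_cells") %||% NA_integer_,
                   0L)
  if (is.null(n_cells)) {
    n_cells <- counts[!is.na(counts)][1]
    if (is.na(n_cells) || is.null(n_cells)) {
      abort("Provide `n_cells`: event sets carry no cell-count attribute.")
    }
  }
  if (any(!is.na(counts) & counts != n_cells)) {
    abort("Event sets cover different cell populations.")
  }
  flags <- purrr::imap(events, function(e, cond) {
    tibble(cell = seq_len(n_cells),
           condition = cond,
           active = seq_len(n_cells) %in% unique(e$cell))
  })
  out <- bind_rows(flags)
  retained <- out |> group_by(.data$cell) |>
    summarise(retained = any(.data$active))
  left_join(out, retained, by = "cell")
}
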