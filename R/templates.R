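#' Build a library of representative calcium transient waveforms
#'
#' Event detection correlates short trace fragments against a library of
#' difference-of-exponential waveforms spanning a grid of rise and decay
#' time constants (default 8 rise x 16 decay = 128 templates). Templates
#' are peak-normalized and share a fixed length of
#' `ceil(5 * max(decay) * frame_rate)` frames.
#'
#' @param n_rise,n_decay Grid sizes; their product is the library size.
#' @param rise_range,decay_range Ranges (seconds) spanned by the grids.
#' @param frame_rate Sampling rate of the traces to be scanned, fps.
#' @param n_templates Required library size; an error is raised if the grid
#'   product differs.
#'
#' @return A list of class `template_library`: `waveforms` (length x
#'   n_templates matrix, each column peak 1), `params` (tibble `rise`,
#'   `decay`), `frame_rate`.
#' @examples
#' lib <- template_library()
#' ncol(lib$waveforms)  # 128
#' @export
template_library <- function(n_rise = 8, n_decay = 16,
                             rise_range = c(0.02, 0.08),
                             decay_range = c(0.1, 0.4),
                             frame_rate = 20, n_templates = n_rise * n_decay) {
  if (n_rise * n_decay != n_templates) {
    abort(sprintf("Grid of %d x %d templates does not match `n_templates = %d`.",
                  n_rise, n_decay, n_templates))
  }
  rises <- if (n_rise == 1) mean(rise_range) else
    seq(rise_range[1], rise_range[2], length.out = n_rise)
  decays <- if (n_decay == 1) mean(decay_range) else
    seq(decay_range[1], decay_range[2], length.out = n_decay)
  params <- tidyr::expand_grid(decay = decays, rise = rises)
  if (any(params$rise >= params$decay)) {
    abort("Every rise constant must be smaller than every decay constant.")
  }
  len <- ceiling(5 * max(decays) * frame_rate)
  t_grid <- (seq_len(len) - 1) / frame_rate
  waveforms <- vapply(seq_len(nrow(params)), function(i) {
    w <- ca_kernel(t_grid, rise = params$rise[i], decay = params$decay[i])
    w / max(w)
  }, numeric(len))
  structure(list(waveforms = waveforms, params = params,
                 frame_rate = frame_rate),
            class = "template_library")
}

#' @export
print.template_library <- function(x, ...) {
  cat(sprintf("<template_library> %d waveforms, %d frames @ %g fps\n",
              ncol(x$waveforms), nrow(x$waveforms), x$frame_rate))
  invisible(x)
}

#' @method tidy template_library
#' @export
tidy.template_library <- function(x, ...) {
  mutate(x$params, template = dplyr::row_number(), .before = 1)
}
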