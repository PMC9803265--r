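#' GCaMP-like calcium transient kernel
#'
#' Difference-of-exponentials waveform `exp(-t/decay) - exp(-t/rise)`,
#' peak-normalized to 1. Defaults follow the order of magnitude of GCaMP6f
#' kinetics (fast rise ~50 ms, decay ~400 ms).
#'
#' @param t Time since event onset, seconds (vectorized; negative times give 0).
#' @param rise,decay Rise and decay time constants, seconds (`rise < decay`).
#' @return Kernel values, unit peak amplitude.
#' @examples
#' ca_kernel(seq(0, 2, by = 0.05))
#' @export
ca_kernel <- function(t, rise = 0.05, decay = 0.4) {
  check_number(rise, "rise", lower = 1e-6)
  check_number(decay, "decay", lower = 1e-6)
  if (rise >= decay) abort("`rise` must be smaller than `decay`.")
  t_peak <- rise * decay / (decay - rise) * log(decay / rise)
  peak <- exp(-t_peak / decay) - exp(-t_peak / rise)
  out <- ifelse(t >= 0, (exp(-t / decay) - exp(-t / rise)) / peak, 0)
  out
}

#' Render ground-truth spike trains as normalized fluorescence traces
#'
#' Each event is convolved with a difference-of-exponentials kernel of unit
#' peak amplitude (in dF/F units) and superimposed on a flat baseline of 1,
#' emulating traces after background subtraction and F/F0 scaling. Optional
#' degradations: additive Gaussian noise, multiplicative slow sinusoidal
#' drift, and multiplicative exponential photobleaching.
#'
#' @param spikes A [generate_spike_trains()] result (tibble `cell`, `time`).
#' @param frame_rate Frames per second of the rendered recording.
#' @param duration Recording length, seconds (defaults to the spike trains').
#' @param rise,decay Kernel time constants, seconds.
#' @param amplitude Transient peak amplitude in dF/F units.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param drift_amp Relative amplitude of a slow sinusoidal baseline drift
#'   (0 disables).
#' @param drift_period Drift period, seconds.
#' @param bleach_tau Photobleaching time constant, seconds (`NULL` disables).
#' @param seed Integer RNG seed for the noise.
#'
#' @return A [new_trace_set()] tibble (`cell`, `time`, `dff`).
#' @examples
#' st <- generate_spike_trains(10, "asynchronous", rate = 6,
#'                             duration = 30, seed = 1)
#' tr <- render_traces(st, noise_sd = 0, seed = 1)
#' @export
render_traces <- function(spikes, frame_rate = 20, duration = NULL,
                          rise = 0.05, decay = 0.4, amplitude = 1,
                          noise_sd = 0.02, drift_amp = 0, drift_period = 60,
                          bleach_tau = NULL, seed = NULL) {
  if (is.null(duration)) duration <- recording_duration(spikes)
  n_frames <- round(duration * frame_rate)
  ncell <- n_cells(spikes)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(amplitude, "amplitude", lower = 0)
  t_frames <- (seq_len(n_frames) - 1) / frame_rate
  support <- ceiling(21 * decay * frame_rate)   # tail truncated below 1e-9

  mat <- matrix(1, nrow = n_frames, ncol = ncell)
  by_cell <- split(spikes$time, factor(spikes$cell, levels = seq_len(ncell)))
  for (j in seq_len(ncell)) {
    for (t0 in by_cell[[j]]) {
      i0 <- floor(t0 * frame_rate) + 1L
      idx <- i0:min(i0 + support, n_frames)
      idx <- idx[idx >= 1L]
      if (length(idx)) {
        mat[idx, j] <- mat[idx, j] + amplitude * ca_kernel(t_frames[idx] - t0,
                                                           rise, decay)
      }
    }
  }
  if (drift_amp > 0) {
    drift <- 1 + drift_amp * sin(2 * pi * t_frames / drift_period)
    mat <- mat * drift
  }
  if (!is.null(bleach_tau)) {
    mat <- mat * exp(-t_frames / bleach_tau)
  }
  if (noise_sd > 0) {
    mat <- mat + with_seed_if(seed, matrix(rnorm(length(mat), sd = noise_sd),
                                           nrow = n_frames))
  }
  new_trace_set(mat, frame_rate = frame_rate)
}

#' Render a fluorescence movie from an island and its traces
#'
#' Paints each soma as a 2-D Gaussian at its island position on a noisy
#' background; pixel intensity follows the cell's trace. Intended for
#' exercising the segmentation/extraction stages against known ground truth.
#'
#' @param island An [generate_island()] result.
#' @param traces A trace set for the island's cells.
#' @param dims Image dimensions, `c(rows, cols)` in pixels.
#' @param pixel_size Micrometres per pixel.
#' @param cell_sigma Gaussian soma radius, micrometres.
#' @param background Mean background intensity.
#' @param gain Intensity per unit dF/F.
#' @param noise_sd Per-pixel Gaussian noise SD.
#' @param seed Integer RNG seed for pixel noise.
#'
#' @return A `fluorescence_movie`: list with `stack` (rows x cols x frames
#'   array), `frame_rate`, `pixel_size`.
#' @export
render_movie <- function(island, traces, dims = c(128, 128), pixel_size = 4,
                         cell_sigma = 8, background = 20, gain = 100,
                         noise_sd = 1, seed = NULL) {
  stopifnot(inherits(island, "island"))
  mat <- trace_matrix(traces)
  n_frames <- nrow(mat)
  nr <- dims[1]; nc <- dims[2]
  # map island coordinates (um, origin at centre) to pixel grid
  px <- island$cells$x / pixel_size + nc / 2
  py <- island$cells$y / pixel_size + nr / 2
  sig <- cell_sigma / pixel_size
  half <- ceiling(3 * sig)

  footprints <- lapply(seq_len(nrow(island$cells)), function(j) {
    cx <- px[j]; cy <- py[j]
    cols <- max(1, floor(cx - half)):min(nc, ceiling(cx + half))
    rows <- max(1, floor(cy - half)):min(nr, ceiling(cy + half))
    if (!length(rows) || !length(cols)) return(NULL)
    g <- outer(rows, cols, function(r, c) exp(-((r - cy)^2 + (c - cx)^2) / (2 * sig^2)))
    list(rows = rows, cols = cols, g = g)
  })

  stack <- with_seed_if(seed, {
    arr <- array(background + if (noise_sd > 0)
      rnorm(nr * nc * n_frames, sd = noise_sd) else 0, dim = c(nr, nc, n_frames))
    arr
  })
  for (f in seq_len(n_frames)) {
    frame <- stack[, , f]
    for (j in seq_along(footprints)) {
      fp <- footprints[[j]]
      if (is.null(fp)) next
      frame[fp$rows, fp$cols] <- frame[fp$rows, fp$cols] + gain * mat[f, j] * fp$g
    }
    stack[, , f] <- frame
  }
  stack[stack < 0] <- 0
  structure(list(stack = stack, frame_rate = frame_rate(traces),
                 pixel_size = pixel_size),
            class = "fluorescence_movie")
}

#' @export
print.fluorescence_movie <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("<fluorescence_movie> %d x %d px, %d frames @ %g fps\n",
              d[1], d[2], d[3], x$frame_rate))
  invisible(x)
}
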