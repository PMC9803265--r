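#' Generate ground-truth spike trains for an island
#'
#' Two activity regimes are emulated. In the `"asynchronous"` regime each
#' cell fires independently as a stationary renewal process with the target
#' mean rate and an absolute refractory period (default 0.5 s): calcium
#' transients closer than the refractory period are not separable as
#' distinct events by template matching (nor by a human scorer), so the
#' generator's "event" is a discernible transient. Exponential waiting times
#' are rate-corrected so the realized mean rate equals `rate` in
#' expectation. In the `"bursting"` regime population bursts arrive as a
#' Poisson process at `rate` (per cell per minute when participation is
#' full); each burst recruits each cell with probability `participation`
#' and per-cell onset jitter uniform in `[0, jitter]` seconds.
#'
#' @param island An [generate_island()] result, or an integer cell count.
#' @param regime `"asynchronous"` or `"bursting"`.
#' @param rate Target mean event rate, events per minute per cell
#'   (asynchronous) or population-burst rate per minute (bursting).
#' @param duration Recording length in seconds; defaults to the island
#'   configuration.
#' @param participation Per-cell burst participation probability.
#' @param jitter Burst onset jitter window, seconds.
#' @param refractory Minimum separation between events of one cell, seconds.
#' @param seed Integer RNG seed.
#'
#' @return A `spike_trains` tibble with columns `cell`, `time` (seconds,
#'   strictly increasing within cells), carrying `duration`, `regime`,
#'   `n_cells` and `burst_times` attributes.
#' @examples
#' isl <- generate_island(island_config(750, 100, seed = 1))
#' st <- generate_spike_trains(isl, "asynchronous", rate = 12, seed = 2)
#' mean_event_rate(st, duration = recording_duration(st))
#' @export
generate_spike_trains <- function(island, regime = c("asynchronous", "bursting"),
                                  rate, duration = NULL,
                                  participation = 0.9, jitter = 0.05,
                                  refractory = 0.5, seed = NULL) {
  regime <- match.arg(regime)
  if (inherits(island, "island")) {
    n_cells <- nrow(island$cells)
    if (is.null(duration)) duration <- island$config$duration
  } else {
    n_cells <- as.integer(island)
    if (is.null(duration)) abort("Provide `duration` when `island` is a cell count.")
  }
  check_number(rate, "rate", lower = 0)
  check_number(duration, "duration", lower = 1e-9)
  check_number(participation, "participation", 0, 1)
  check_number(jitter, "jitter", lower = 0)
  check_number(refractory, "refractory", lower = 0)
  rate_s <- rate / 60
  if (regime == "asynchronous" && rate_s * refractory >= 1) {
    abort("`rate` is not attainable with this refractory period.")
  }

  burst_times <- numeric(0)
  trains <- with_seed_if(seed, {
    if (regime == "asynchronous") {
      # renewal process: ISI = refractory + Exp(lambda'), with lambda' chosen
      # so E[ISI] = 1/rate  =>  realized mean rate == target rate
      lapply(seq_len(n_cells), function(i) {
        if (rate_s == 0) return(numeric(0))
        lam <- 1 / (1 / rate_s - refractory)
        # start the renewal process a few mean intervals before t = 0 so the
        # observation window sees its stationary regime
        burn <- 3 / rate_s
        total <- duration + burn
        n_chunk <- max(20L, ceiling(rate_s * total + 6 * sqrt(rate_s * total + 1)))
        t_ev <- -burn + cumsum(refractory + rexp(n_chunk, lam))
        while (t_ev[length(t_ev)] < duration) {
          t_ev <- c(t_ev, t_ev[length(t_ev)] +
                      cumsum(refractory + rexp(n_chunk, lam)))
        }
        t_ev[t_ev >= 0 & t_ev < duration]
      })
    } else {
      n_burst <- rpois(1, rate_s * duration)
      burst_times <- sort(runif(n_burst, 0, duration))
      lapply(seq_len(n_cells), function(i) {
        take <- runif(length(burst_times)) < participation
        t_ev <- burst_times[take] + runif(sum(take), 0, jitter)
        sort(t_ev[t_ev < duration])
      })
    }
  })

  out <- tibble(
    cell = rep(seq_len(n_cells), lengths(trains)),
    time = unlist(trains) %||% numeric(0)
  )
  attr(out, "duration") <- duration
  attr(out, "regime") <- regime
  attr(out, "n_cells") <- n_cells
  attr(out, "burst_times") <- burst_times
  class(out) <- c("spike_trains", class(out))
  out
}

#' Build a spike train set from explicit event times
#'
#' Constructor for ground-truth trains specified by hand (e.g. islands
#' with a prescribed number of silent cells).
#'
#' @param x A data frame with columns `cell` (integer in
#'   `1..n_cells`) and `time` (seconds).
#' @param n_cells Total cell count, including silent cells.
#' @param duration Recording length, seconds.
#' @param regime Label stored with the trains.
#' @param burst_times Optional population burst onsets, seconds.
#' @return A `spike_trains` tibble (see [generate_spike_trains()]).
#' @examples
#' as_spike_trains(data.frame(cell = 1L, time = 5), n_cells = 3,
#'                 duration = 30)
#' @export
as_spike_trains <- function(x, n_cells, duration, regime = "custom",
                            burst_times = numeric(0)) {
  x <- as_tibble(x)
  if (!all(c("cell", "time") %in% names(x))) {
    abort("Need columns `cell` and `time`.")
  }
  check_number(duration, "duration", lower = 1e-9)
  if (nrow(x) && (any(x$cell < 1) || any(x$cell > n_cells))) {
    abort("`cell` ids must lie in 1..n_cells.")
  }
  if (nrow(x) && (any(x$time < 0) || any(x$time > duration))) {
    abort("Event times must lie in [0, duration].")
  }
  out <- arrange(x[, c("cell", "time")], .data$cell, .data$time)
  out$cell <- as.integer(out$cell)
  attr(out, "duration") <- duration
  attr(out, "regime") <- regime
  attr(out, "n_cells") <- as.integer(n_cells)
  attr(out, "burst_times") <- burst_times
  class(out) <- c("spike_trains", class(out))
  out
}

#' Number of cells covered by a spike train set
#' @param x A `spike_trains` object (or events tibble carrying `n_cells`).
#' @return Integer cell count.
#' @export
n_cells <- function(x) {
  n <- attr(x, "n_cells")
  if (is.null(n)) n <- length(unique(x$cell))
  as.integer(n)
}
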