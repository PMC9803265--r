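#' Probabilistic cascade model of island activity
#'
#' A discrete-time branching process on the island's structural graph,
#' standing in for the living circuit so ablation experiments can be
#' simulated with known ground truth. In each time bin a non-refractory
#' cell fires spontaneously with probability `p_spont`, or is recruited
#' along each structural edge from an excitatory neighbour that fired in
#' the previous bin with probability `p_exc`; each inhibitory neighbour
#' active in the previous bin multiplies the firing probability by
#' `1 - p_inh_block`. Raising the effective excitation/inhibition ratio
#' (larger `p_exc`, smaller `p_inh_block`) pushes the circuit from sparse
#' asynchronous firing towards synchronous low-entropy bursting;
#' `bicuculline()` emulates pharmacological removal of inhibition by
#' scaling `p_inh_block` towards 0.
#'
#' @param p_spont Per-cell spontaneous firing probability per bin.
#' @param p_exc Transmission probability along an excitatory edge.
#' @param p_inh_block Multiplicative suppression per active inhibitory
#'   neighbour, in \[0, 1\] (0 = no inhibition).
#' @param refractory Refractory period, in bins (>= 1).
#' @param bin_width Bin width, seconds.
#' @return A list of class `cascade_model`.
#' @examples
#' cascade_model(p_spont = 0.002, p_exc = 0.05)
#' @export
cascade_model <- function(p_spont = 0.001, p_exc = 0.05, p_inh_block = 0.5,
                          refractory = 10, bin_width = 0.05) {
  check_number(p_spont, "p_spont", 0, 1)
  check_number(p_exc, "p_exc", 0, 1)
  check_number(p_inh_block, "p_inh_block", 0, 1)
  check_number(refractory, "refractory", lower = 1)
  check_number(bin_width, "bin_width", lower = 1e-6)
  structure(list(p_spont = p_spont, p_exc = p_exc, p_inh_block = p_inh_block,
                 refractory = as.integer(refractory), bin_width = bin_width),
            class = "cascade_model")
}

#' @rdname cascade_model
#' @param preset `"flexible"` — weak coupling with high spontaneous drive,
#'   yielding asynchronous, high-entropy activity whose loss under ablation
#'   is gradual; or `"rigid"` — strong recurrent coupling with sparse
#'   spontaneous seeds, yielding synchronous population bursts that collapse
#'   once ablation pushes the circuit below its percolation threshold.
#' @export
cascade_preset <- function(preset = c("flexible", "rigid")) {
  preset <- match.arg(preset)
  switch(preset,
    flexible = cascade_model(p_spont = 0.01, p_exc = 0.01,
                             p_inh_block = 0.5),
    rigid = cascade_model(p_spont = 2e-5, p_exc = 0.3, p_inh_block = 0.5)
  )
}

#' @rdname cascade_model
#' @param model A `cascade_model`.
#' @param strength Fraction of inhibitory blockade removed, in \[0, 1\]
#'   (1 = complete disinhibition).
#' @export
bicuculline <- function(model, strength = 1) {
  stopifnot(inherits(model, "cascade_model"))
  check_number(strength, "strength", 0, 1)
  model$p_inh_block <- model$p_inh_block * (1 - strength)
  model
}

#' Simulate island activity under the cascade model
#'
#' @param island An [generate_island()] result.
#' @param model A [cascade_model()].
#' @param duration Simulated recording length, seconds.
#' @param alive Logical vector of surviving cells (ablated cells neither
#'   fire nor transmit); default all alive.
#' @param seed Integer RNG seed.
#' @return A `spike_trains` tibble (event time = bin start, seconds) over
#'   all island cells; ablated cells contribute no events.
#' @examples
#' isl <- generate_island(island_config(750, 120, seed = 1))
#' st <- simulate_cascade(isl, cascade_model(p_spont = 0.002), 60, seed = 2)
#' @export
simulate_cascade <- function(island, model, duration = NULL, alive = NULL,
                             seed = NULL) {
  stopifnot(inherits(island, "island"), inherits(model, "cascade_model"))
  if (is.null(duration)) duration <- island$config$duration
  n <- nrow(island$cells)
  if (is.null(alive)) alive <- rep(TRUE, n)
  stopifnot(length(alive) == n)
  n_bins <- round(duration / model$bin_width)
  is_exc <- island$cells$type == "excitatory"
  adj <- island$adjacency
  a_exc <- adj * rep(as.numeric(is_exc & alive), each = n)   # columns = presyn
  a_inh <- adj * rep(as.numeric(!is_exc & alive), each = n)

  with_seed_if(seed, {
    fired_at <- rep(-Inf, n)
    prev <- rep(FALSE, n)
    times <- vector("list", 256)
    cells <- vector("list", 256)
    k <- 0L
    for (b in seq_len(n_bins)) {
      k_exc <- if (any(prev)) as.vector(a_exc %*% prev) else numeric(n)
      m_inh <- if (any(prev)) as.vector(a_inh %*% prev) else numeric(n)
      p <- 1 - (1 - model$p_spont) * (1 - model$p_exc)^k_exc
      if (model$p_inh_block > 0) p <- p * (1 - model$p_inh_block)^m_inh
      eligible <- alive & (b - fired_at > model$refractory)
      fire <- eligible & (runif(n) < p)
      if (any(fire)) {
        k <- k + 1L
        if (k > length(times)) {
          length(times) <- 2L * length(times)
          length(cells) <- 2L * length(cells)
        }
        times[[k]] <- rep((b - 1) * model$bin_width, sum(fire))
        cells[[k]] <- which(fire)
        fired_at[fire] <- b
      }
      prev <- fire
    }
    out <- tibble(cell = unlist(cells[seq_len(k)]) %||% integer(0),
                  time = unlist(times[seq_len(k)]) %||% numeric(0))
  })
  out <- arrange(out, .data$cell, .data$time)
  attr(out, "duration") <- duration
  attr(out, "regime") <- "cascade"
  attr(out, "n_cells") <- n
  attr(out, "burst_times") <- numeric(0)
  class(out) <- c("spike_trains", class(out))
  out
}

#' Simulate a sequential microablation experiment
#'
#' Reproduces the sequential injury protocol: a baseline recording, then
#' repeated rounds in which `step_size` randomly selected surviving cells
#' are permanently inactivated and a post-injury recording is acquired,
#' until `max_injured_fraction` of the population has been ablated (a final
#' partial step is taken if fewer than `step_size` cells remain).
#'
#' @param island An [generate_island()] result.
#' @param model A [cascade_model()].
#' @param step_size Cells ablated per injury round (protocol default 5).
#' @param max_injured_fraction Stop once this fraction of the population
#'   has been ablated (protocol default 0.75).
#' @param baseline_duration Baseline recording length, seconds.
#' @param step_duration Post-injury recording length, seconds.
#' @param seed Integer RNG seed (per-stage substreams are derived from it).
#'
#' @return A list of class `injury_experiment` with elements `baseline`
#'   (spike trains), `steps` (list of `ablated` ids + `spikes` per round),
#'   `island`, and the protocol parameters.
#' @examples
#' isl <- generate_island(island_config(750, 120, seed = 1))
#' exp <- simulate_ablation_experiment(isl, cascade_model(p_spont = 0.002),
#'                                     baseline_duration = 30,
#'                                     step_duration = 15, seed = 2)
#' @export
simulate_ablation_experiment <- function(island, model, step_size = 5,
                                         max_injured_fraction = 0.75,
                                         baseline_duration = 180,
                                         step_duration = 60, seed = NULL) {
  stopifnot(inherits(island, "island"), inherits(model, "cascade_model"))
  check_number(step_size, "step_size", lower = 1)
  check_number(max_injured_fraction, "max_injured_fraction", 0, 1)
  n <- nrow(island$cells)
  if (is.null(seed)) seed <- sample.int(2^31 - 2, 1)

  baseline <- simulate_cascade(island, model, baseline_duration,
                               seed = derive_seed(seed, 0L))
  alive <- rep(TRUE, n)
  steps <- list()
  max_ablate <- floor(max_injured_fraction * n)
  step_i <- 0L
  while (sum(!alive) < max_ablate) {
    step_i <- step_i + 1L
    k <- min(step_size, max_ablate - sum(!alive), sum(alive))
    if (k < 1) break
    survivors <- which(alive)
    ablated <- with_seed_if(derive_seed(seed, step_i * 2L - 1L),
                            sort(survivors[sample.int(length(survivors), k)]))
    alive[ablated] <- FALSE
    spikes <- simulate_cascade(island, model, step_duration, alive = alive,
                               seed = derive_seed(seed, step_i * 2L))
    steps[[step_i]] <- list(ablated = ablated, spikes = spikes)
  }
  structure(list(baseline = baseline, steps = steps, island = island,
                 model = model, step_size = step_size,
                 baseline_duration = baseline_duration,
                 step_duration = step_duration, seed = seed),
            class = "injury_experiment")
}

#' @export
print.injury_experiment <- function(x, ...) {
  n_abl <- sum(lengths(lapply(x$steps, `[[`, "ablated")))
  cat(sprintf("<injury_experiment> %d cells, %d injury rounds, %d ablated (%.0f%%)\n",
              nrow(x$island$cells), length(x$steps), n_abl,
              100 * n_abl / nrow(x$island$cells)))
  invisible(x)
}
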