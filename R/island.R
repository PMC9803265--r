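#' Configure a synthetic neuronal island
#'
#' An island is a circular micro-culture of a few hundred cortical neurons
#' confined to an adhesion disc. The configuration mirrors the experimental
#' design space: disc diameter 750--1300 um and plating density 50--400
#' cells/mm^2, with roughly 80% excitatory / 20% inhibitory neurons.
#'
#' @param diameter Island diameter in micrometres.
#' @param cell_density Plating density in cells per mm^2.
#' @param inhibitory_fraction Fraction of inhibitory neurons, in \[0, 1\].
#' @param duration Recording duration in seconds.
#' @param frame_rate Acquisition rate in frames per second.
#' @param seed Integer RNG seed; `NULL` uses the session RNG.
#'
#' @return A list of class `island_config`. The derived cell count
#'   `n_cells = round(density * pi d^2 / 4)` must be at least 2.
#' @examples
#' island_config(diameter = 750, cell_density = 100, seed = 1)
#' @export
island_config <- function(diameter, cell_density, inhibitory_fraction = 0.2,
                          duration = 180, frame_rate = 20, seed = NULL) {
  check_number(diameter, "diameter", lower = 1)
  check_number(cell_density, "cell_density", lower = 0)
  check_number(inhibitory_fraction, "inhibitory_fraction", 0, 1)
  check_number(duration, "duration", lower = 1e-9)
  check_number(frame_rate, "frame_rate", lower = 1e-9)
  n_frames <- duration * frame_rate
  if (abs(n_frames - round(n_frames)) > 1e-8) {
    abort("`duration * frame_rate` must be a whole number of frames.")
  }
  area_mm2 <- pi * (diameter / 1000)^2 / 4
  n_cells <- round(cell_density * area_mm2)
  if (n_cells < 2) {
    abort("Configuration yields fewer than 2 cells; increase `diameter` or `cell_density`.")
  }
  structure(
    list(
      diameter = diameter, cell_density = cell_density,
      inhibitory_fraction = inhibitory_fraction,
      duration = duration, frame_rate = frame_rate,
      area_mm2 = area_mm2, n_cells = as.integer(n_cells),
      seed = if (!is.null(seed)) as.integer(seed) else NULL
    ),
    class = "island_config"
  )
}

#' Generate an island layout with a distance-decay structural graph
#'
#' Places `n_cells` somata uniformly at random inside the adhesion disc with
#' a minimum pairwise separation (so rendered somata do not overlap), labels
#' ~20% of them inhibitory, and draws an undirected structural connectivity
#' graph in which the connection probability decays exponentially with
#' somatic distance. With a fixed distance rule, mean structural degree
#' scales with plating density, as in the cultures the simulator emulates.
#'
#' @param config An [island_config()].
#' @param min_separation Minimum distance between somata, um.
#' @param connect_prob Connection probability at zero distance.
#' @param decay_length Length constant of the distance decay, um.
#'
#' @return A list of class `island` with elements `cells` (tibble: `cell`,
#'   `x`, `y`, `type`), `adjacency` (symmetric 0/1 matrix, zero diagonal)
#'   and `config`.
#' @examples
#' isl <- generate_island(island_config(750, 100, seed = 1))
#' isl$cells
#' @export
generate_island <- function(config, min_separation = 15,
                            connect_prob = 0.6, decay_length = 300) {
  stopifnot(inherits(config, "island_config"))
  check_number(min_separation, "min_separation", lower = 0)
  check_number(connect_prob, "connect_prob", 0, 1)
  check_number(decay_length, "decay_length", lower = 1e-9)
  n <- config$n_cells
  radius <- config$diameter / 2

  with_seed_if(config$seed, {
    xs <- numeric(n)
    ys <- numeric(n)
    placed <- 0L
    tries <- 0L
    max_tries <- 20000L * n
    while (placed < n && tries < max_tries) {
      tries <- tries + 1L
      # uniform point in the disc
      r <- radius * sqrt(runif(1))
      th <- runif(1, 0, 2 * pi)
      x <- r * cos(th); y <- r * sin(th)
      if (placed == 0L ||
          min((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2) >=
            min_separation^2) {
        placed <- placed + 1L
        xs[placed] <- x; ys[placed] <- y
      }
    }
    if (placed < n) {
      abort("Could not place all somata with the requested minimum separation.")
    }
    type <- rep("excitatory", n)
    n_inh <- round(config$inhibitory_fraction * n)
    if (n_inh > 0) type[sample.int(n, n_inh)] <- "inhibitory"

    d <- as.matrix(stats::dist(cbind(xs, ys)))
    p <- connect_prob * exp(-d / decay_length)
    diag(p) <- 0
    u <- matrix(0, n, n)
    upper <- upper.tri(u)
    u[upper] <- runif(sum(upper))
    adj <- matrix(0L, n, n)
    adj[upper] <- as.integer(u[upper] < p[upper])
    adj <- adj + t(adj)
  })

  cells <- tibble(cell = seq_len(n), x = xs, y = ys, type = type)
  structure(list(cells = cells, adjacency = adj, config = config),
            class = "island")
}

#' @export
print.island <- function(x, ...) {
  cat(sprintf(
    "<island> %d cells (%.0f%% inhibitory), diameter %g um, density %g cells/mm^2\n",
    nrow(x$cells), 100 * mean(x$cells$type == "inhibitory"),
    x$config$diameter, x$config$cell_density))
  cat(sprintf("  structural edges: %d (mean degree %.1f)\n",
              sum(x$adjacency) / 2, mean(rowSums(x$adjacency))))
  invisible(x)
}

#' @method tidy island
#' @export
tidy.island <- function(x, ...) x$cells

#' Structural edge list of an island
#'
#' @param island An [generate_island()] result.
#' @return A tibble with columns `from`, `to` (one row per undirected edge).
#' @export
island_edges <- function(island) {
  stopifnot(inherits(island, "island"))
  idx <- which(upper.tri(island$adjacency) & island$adjacency > 0, arr.ind = TRUE)
  tibble(from = as.integer(idx[, 1]), to = as.integer(idx[, 2]))
}
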