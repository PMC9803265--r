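#' Binary functional connectivity from surrogate-thresholded correlations
#'
#' Scores every cell pair by the maximum lagged cross-correlation (the
#' same pair score as [synchronization_index()]) and keeps an edge when
#' the observed score exceeds the `1 - alpha` quantile of a null
#' distribution built from circular-shift surrogates: in each surrogate
#' every trace is rotated by an independent uniform offset of at least
#' `min_shift` seconds, which preserves each trace's autocorrelation while
#' destroying pairwise alignment. A fixed absolute threshold can be used
#' instead via `threshold`.
#'
#' @param traces A trace set (restrict to active cells via `cells`).
#' @param cells Optional integer ids of cells to include.
#' @param tau_max Maximum lag searched, seconds.
#' @param alpha Per-pair false-positive rate of the surrogate test.
#' @param n_surrogate Number of circular-shift surrogates.
#' @param min_shift Minimum rotation, seconds.
#' @param threshold Absolute pair-score threshold; when given, surrogates
#'   are skipped.
#' @param seed Integer RNG seed for the surrogate offsets.
#'
#' @return A list of class `fc_network`: `adjacency` (binary symmetric,
#'   zero diagonal), `scores` (pair score matrix), `cells`, `n`, plus the
#'   thresholding parameters.
#' @examples
#' tr <- new_trace_set(matrix(rnorm(400), 100, 4), frame_rate = 20)
#' net <- functional_connectivity(tr, n_surrogate = 20, seed = 1)
#' fc_density(net)
#' @export
functional_connectivity <- function(traces, cells = NULL, tau_max = 1,
                                    alpha = 0.05, n_surrogate = 100,
                                    min_shift = 5, threshold = NULL,
                                    seed = NULL) {
  traces <- as_trace_set(traces)
  fr <- frame_rate(traces)
  mat <- trace_matrix(traces)
  if (!is.null(cells)) {
    mat <- mat[, colnames(mat) %in% as.character(cells), drop = FALSE]
  }
  sds <- apply(mat, 2, sd)
  if (any(sds == 0)) {
    warn(sprintf("Excluding %d constant trace(s) from the FC computation.",
                 sum(sds == 0)))
    mat <- mat[, sds > 0, drop = FALSE]
  }
  n <- ncol(mat)
  if (n < 2) abort("Functional connectivity needs at least 2 usable cells.")
  ids <- as.integer(colnames(mat))
  n_frames <- nrow(mat)
  max_lag <- as.integer(round(tau_max * fr))
  scores <- pmin(pmax(pair_correlation(mat, max_lag), 0), 1)
  diag(scores) <- 1

  if (is.null(threshold)) {
    check_number(alpha, "alpha", 0, 1)
    check_number(n_surrogate, "n_surrogate", lower = 1)
    shift_min <- round(min_shift * fr)
    if (2 * shift_min >= n_frames) {
      abort("Recording too short for the requested minimum surrogate shift.")
    }
    null_scores <- with_seed_if(seed, {
      arr <- array(NA_real_, dim = c(n, n, n_surrogate))
      for (m in seq_len(n_surrogate)) {
        offs <- sample(shift_min:(n_frames - shift_min), n, replace = TRUE)
        shifted <- mat
        for (j in seq_len(n)) {
          o <- offs[j]
          shifted[, j] <- mat[c((o + 1):n_frames, 1:o), j]
        }
        arr[, , m] <- pair_correlation(shifted, max_lag)
      }
      arr
    })
    crit <- apply(null_scores, c(1, 2), quantile, probs = 1 - alpha,
                  names = FALSE)
    adj <- (scores > crit) * 1L
  } else {
    check_number(threshold, "threshold", 0, 1)
    adj <- (scores >= threshold) * 1L
  }
  diag(adj) <- 0L
  adj <- pmax(adj, t(adj))   # already symmetric; defensive
  dimnames(adj) <- list(ids, ids)
  structure(list(adjacency = adj, scores = scores, cells = ids, n = n,
                 alpha = if (is.null(threshold)) alpha else NA_real_,
                 n_surrogate = if (is.null(threshold)) n_surrogate else 0L,
                 threshold = threshold),
            class = "fc_network")
}

#' @export
print.fc_network <- function(x, ...) {
  cat(sprintf("<fc_network> %d nodes, %d edges (density %.3f)\n",
              x$n, sum(x$adjacency) / 2, fc_density(x)))
  invisible(x)
}

#' @method tidy fc_network
#' @export
tidy.fc_network <- function(x, ...) {
  idx <- which(upper.tri(x$adjacency) & x$adjacency > 0, arr.ind = TRUE)
  tibble(from = x$cells[idx[, 1]], to = x$cells[idx[, 2]],
         score = x$scores[idx])
}

#' @method glance fc_network
#' @export
glance.fc_network <- function(x, ...) {
  tibble(n_nodes = x$n, n_edges = sum(x$adjacency) / 2,
         fc_density = fc_density(x))
}

fc_adjacency <- function(network) {
  if (inherits(network, "fc_network")) network$adjacency
  else if (is.matrix(network)) network
  else abort("Expected an `fc_network` or an adjacency matrix.")
}

fc_igraph <- function(network) {
  igraph::graph_from_adjacency_matrix(fc_adjacency(network),
                                      mode = "undirected", diag = FALSE)
}

#' Functional connectivity density
#'
#' Number of undirected edges over the number of possible edges
#' `N (N - 1) / 2`, in \[0, 1\].
#'
#' @param network An `fc_network` or a binary symmetric adjacency matrix.
#' @return A proportion in \[0, 1\].
#' @examples
#' fc_density(matrix(1, 3, 3) - diag(3))  # complete triangle: 1
#' @export
fc_density <- function(network) {
  adj <- fc_adjacency(network)
  n <- nrow(adj)
  if (n < 2) abort("FC density needs at least 2 nodes.")
  sum(adj[upper.tri(adj)]) / (n * (n - 1) / 2)
}

#' Characteristic path length
#'
#' Mean shortest-path length over all ordered pairs of distinct nodes.
#' Unreachable pairs are excluded from the mean (the convention of the
#' standard brain-connectivity toolboxes) and their fraction is reported
#' in the `"unreachable_fraction"` attribute. A graph with no edges has no
#' defined paths: `NA` is returned with a warning.
#'
#' @param network An `fc_network` or adjacency matrix.
#' @return Mean shortest path (scalar, attribute `unreachable_fraction`).
#' @examples
#' p3 <- rbind(c(0,1,0), c(1,0,1), c(0,1,0))
#' characteristic_path_length(p3)  # 4/3
#' @export
characteristic_path_length <- function(network) {
  g <- fc_igraph(network)
  n <- igraph::vcount(g)
  if (n < 2) abort("Characteristic path length needs at least 2 nodes.")
  if (igraph::ecount(g) == 0) {
    warn("Graph has no edges: characteristic path length is undefined.")
    return(structure(NA_real_, unreachable_fraction = 1))
  }
  comp_sizes <- igraph::components(g)$csize
  reachable <- sum(comp_sizes * (comp_sizes - 1))
  value <- igraph::mean_distance(g, unconnected = TRUE)
  structure(value, unreachable_fraction = 1 - reachable / (n * (n - 1)))
}

#' Mean clustering coefficient
#'
#' Per-node clustering `C_i = 2 t_i / (k_i (k_i - 1))` (with `t_i`
#' triangles through node i and `C_i = 0` for degree < 2), averaged over
#' all nodes.
#'
#' @param network An `fc_network` or adjacency matrix.
#' @return Mean clustering coefficient in \[0, 1\].
#' @examples
#' clustering_coefficient(matrix(1, 3, 3) - diag(3))  # triangle: 1
#' @export
clustering_coefficient <- function(network) {
  g <- fc_igraph(network)
  if (igraph::vcount(g) < 1) abort("Clustering needs at least 1 node.")
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' Reference a graph metric to random control networks
#'
#' Scales a raw metric by its mean over `n_null` uniformly sampled random
#' graphs with the same number of nodes and edges (Erdos-Renyi G(n, m)),
#' the standard normalization for path length and clustering in functional
#' connectivity studies. Null draws on which the metric is undefined are
#' skipped and counted.
#'
#' @param network An `fc_network` or adjacency matrix.
#' @param metric A function mapping a graph (adjacency matrix) to a
#'   scalar, e.g. [clustering_coefficient()] or
#'   [characteristic_path_length()].
#' @param n_null Size of the null ensemble (default 1000).
#' @param seed Integer RNG seed for the ensemble.
#'
#' @return A list of class `null_reference`: `scaled` (raw / null mean),
#'   `raw`, `null_mean`, `null_sd`, `n_used`, `n_skipped`.
#' @examples
#' k5 <- matrix(1, 5, 5) - diag(5)
#' null_reference(k5, clustering_coefficient, n_null = 50, seed = 1)$scaled
#' @export
null_reference <- function(network, metric, n_null = 1000, seed = NULL) {
  check_number(n_null, "n_null", lower = 1)
  adj <- fc_adjacency(network)
  n <- nrow(adj)
  m <- sum(adj[upper.tri(adj)])
  raw <- suppressWarnings(as.numeric(metric(adj)))
  nulls <- with_seed_if(seed, {
    vapply(seq_len(n_null), function(i) {
      g <- igraph::sample_gnm(n, m)
      suppressWarnings(as.numeric(metric(igraph::as_adjacency_matrix(
        g, sparse = FALSE))))
    }, numeric(1))
  })
  used <- nulls[is.finite(nulls)]
  if (!length(used)) abort("Metric undefined on every null network.")
  null_mean <- mean(used)
  structure(list(scaled = raw / null_mean, raw = raw, null_mean = null_mean,
                 null_sd = sd(used), n_used = length(used),
                 n_skipped = n_null - length(used)),
            class = "null_reference")
}

#' @export
print.null_reference <- function(x, ...) {
  cat(sprintf("<null_reference> raw %.4f / null %.4f (sd %.4f, n=%d) => scaled %.4f\n",
              x$raw, x$null_mean, x$null_sd, x$n_used, x$scaled))
  invisible(x)
}

#' Raw and null-referenced graph metrics of a functional network
#'
#' @param network An `fc_network` or adjacency matrix.
#' @param n_null Null-ensemble size.
#' @param seed Integer RNG seed.
#' @return A one-row tibble: `fc_density`, `char_path_raw`,
#'   `char_path_scaled`, `clustering_raw`, `clustering_scaled`,
#'   `unreachable_fraction`.
#' @export
network_metrics <- function(network, n_null = 1000, seed = NULL) {
  adj <- fc_adjacency(network)
  cp <- characteristic_path_length(adj)
  cc <- clustering_coefficient(adj)
  cp_null <- null_reference(adj, characteristic_path_length, n_null,
                            seed = if (is.null(seed)) NULL else derive_seed(seed, 1L))
  cc_null <- null_reference(adj, clustering_coefficient, n_null,
                            seed = if (is.null(seed)) NULL else derive_seed(seed, 2L))
  tibble(
    fc_density = fc_density(adj),
    char_path_raw = as.numeric(cp),
    char_path_scaled = cp_null$scaled,
    clustering_raw = cc,
    clustering_scaled = cc_null$scaled,
    unreachable_fraction = attr(cp, "unreachable_fraction")
  )
}
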