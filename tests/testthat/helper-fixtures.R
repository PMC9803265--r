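# Shared fixtures and independent oracles.

# Trace with kernels inserted at known onsets (frame-aligned by default).
insert_kernel_trace <- function(onsets, duration = 60, frame_rate = 20,
                                amplitude = 1, rise = 0.05, decay = 0.4,
                                noise_sd = 0, baseline = 1, seed = NULL) {
  st <- as_spike_trains(data.frame(cell = rep(1L, length(onsets)),
                                   time = onsets),
                        n_cells = 1, duration = duration)
  render_traces(st, frame_rate = frame_rate, rise = rise, decay = decay,
                amplitude = amplitude, noise_sd = noise_sd, seed = seed)
}

# Match detections to ground truth within a tolerance; returns counts.
match_events <- function(truth, detected, tol = 0.25) {
  used <- rep(FALSE, length(detected))
  tp <- 0L
  for (t in truth) {
    j <- which(!used & abs(detected - t) <= tol)
    if (length(j)) {
      used[j[which.min(abs(detected[j] - t))]] <- TRUE
      tp <- tp + 1L
    }
  }
  list(tp = tp, fp = length(detected) - tp, fn = length(truth) - tp)
}

# Brute-force all-pairs shortest paths by breadth-first search.
bfs_path_matrix <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ] > 0))))
      nxt <- nxt[!is.finite(d[s, nxt])]
      if (!length(nxt)) break
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

# Brute-force characteristic path length (unreachable pairs excluded).
brute_char_path <- function(adj) {
  d <- bfs_path_matrix(adj)
  vals <- d[row(d) != col(d)]
  finite <- vals[is.finite(vals)]
  if (!length(finite)) return(NA_real_)
  mean(finite)
}

# Brute-force mean local clustering by triangle enumeration.
brute_clustering <- function(adj) {
  n <- nrow(adj)
  ci <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    t_i <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (adj[nb[a], nb[b]] > 0) t_i <- t_i + 1
      }
    }
    2 * t_i / (k * (k - 1))
  }, numeric(1))
  mean(ci)
}

# Symmetric random binary adjacency on n nodes with edge probability p.
random_adjacency <- function(n, p) {
  adj <- matrix(0L, n, n)
  up <- upper.tri(adj)
  adj[up] <- rbinom(sum(up), 1, p)
  adj + t(adj)
}
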