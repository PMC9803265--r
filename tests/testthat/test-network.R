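test_that("identical traces give a complete functional graph", {
  x <- rnorm(1200)
  tr <- new_trace_set(cbind(x, x, x, x), frame_rate = 20)
  net <- functional_connectivity(tr, n_surrogate = 30, seed = 1)
  expect_true(all(net$adjacency[upper.tri(net$adjacency)] == 1))
  expect_equal(fc_density(net), 1)
})

test_that("independent noise yields edge density near alpha", {
  dens <- vapply(1:8, function(s) {
    set.seed(s)
    mat <- matrix(rnorm(1200 * 12), 1200, 12)
    net <- functional_connectivity(new_trace_set(mat, 20),
                                   n_surrogate = 60, alpha = 0.05,
                                   min_shift = 5, seed = s)
    fc_density(net)
  }, numeric(1))
  expect_lt(abs(mean(dens) - 0.05), 0.04)
})

test_that("an absolute threshold mode bypasses the surrogates", {
  x <- rnorm(600)
  tr <- new_trace_set(cbind(x, x, rnorm(600)), frame_rate = 20)
  net <- functional_connectivity(tr, threshold = 0.9)
  expect_equal(net$adjacency[1, 2], 1L)
  expect_equal(net$adjacency[1, 3], 0L)
})

test_that("fc_density follows the undirected edge-count formula", {
  k10 <- matrix(1, 10, 10) - diag(10)
  expect_equal(fc_density(k10), 1)
  three <- rbind(c(0, 1, 1), c(1, 0, 0), c(1, 0, 0))
  expect_equal(fc_density(three), 2 / 3, tolerance = 1e-12)
  expect_equal(fc_density(matrix(0, 4, 4)), 0)
  expect_error(fc_density(matrix(0, 1, 1)), "at least 2")
})

test_that("characteristic path length matches hand-computed cases", {
  k5 <- matrix(1, 5, 5) - diag(5)
  expect_equal(as.numeric(characteristic_path_length(k5)), 1)
  p3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  expect_equal(as.numeric(characteristic_path_length(p3)), 4 / 3)
  # two disconnected dyads: reachable pairs all at distance 1, 2/3 unreachable
  dyads <- matrix(0, 4, 4)
  dyads[1, 2] <- dyads[2, 1] <- dyads[3, 4] <- dyads[4, 3] <- 1
  cp <- characteristic_path_length(dyads)
  expect_equal(as.numeric(cp), 1)
  expect_equal(attr(cp, "unreachable_fraction"), 2 / 3, tolerance = 1e-12)
  expect_warning(cp0 <- characteristic_path_length(matrix(0, 3, 3)),
                 "undefined")
  expect_true(is.na(cp0))
})

test_that("clustering coefficient matches canonical graphs", {
  tri <- matrix(1, 3, 3) - diag(3)
  expect_equal(clustering_coefficient(tri), 1)
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(clustering_coefficient(star), 0)
  expect_equal(clustering_coefficient(matrix(1, 7, 7) - diag(7)), 1)
})

test_that("graph metrics agree with brute-force oracles on graphs up to N = 8", {
  set.seed(10)
  for (i in 1:30) {
    n <- sample(2:8, 1)
    adj <- random_adjacency(n, runif(1, 0.2, 0.8))
    expect_equal(clustering_coefficient(adj), brute_clustering(adj),
                 tolerance = 1e-12)
    oracle <- brute_char_path(adj)
    if (is.na(oracle)) {
      expect_warning(val <- characteristic_path_length(adj), "undefined")
      expect_true(is.na(val))
    } else {
      expect_equal(as.numeric(characteristic_path_length(adj)), oracle,
                   tolerance = 1e-12)
    }
  }
})

test_that("a complete graph has scaled metrics exactly 1 against G(n, m) nulls", {
  k20 <- matrix(1, 20, 20) - diag(20)
  ref_c <- null_reference(k20, clustering_coefficient, n_null = 200, seed = 3)
  ref_p <- null_reference(k20, characteristic_path_length, n_null = 200,
                          seed = 4)
  expect_identical(ref_c$scaled, 1)
  expect_identical(ref_p$scaled, 1)
  expect_equal(ref_c$null_sd, 0)
})

test_that("a modular two-clique graph is more clustered than its nulls", {
  adj <- matrix(0, 8, 8)
  adj[1:4, 1:4] <- 1
  adj[5:8, 5:8] <- 1
  diag(adj) <- 0
  adj[4, 5] <- adj[5, 4] <- 1
  ref <- null_reference(adj, clustering_coefficient, n_null = 300, seed = 5)
  expect_gt(ref$scaled, 1)
})

test_that("null referencing is deterministic under a fixed seed", {
  set.seed(20)
  adj <- random_adjacency(12, 0.4)
  a <- null_reference(adj, clustering_coefficient, n_null = 100, seed = 9)
  b <- null_reference(adj, clustering_coefficient, n_null = 100, seed = 9)
  expect_identical(a$scaled, b$scaled)
  expect_identical(a$null_mean, b$null_mean)
})

test_that("degenerate inputs surface as errors, not silent NaN", {
  empty <- matrix(0, 6, 6)
  expect_error(suppressWarnings(
    null_reference(empty, characteristic_path_length, n_null = 20, seed = 1)),
    "undefined on every null")
})

test_that("asynchronous islands produce near-random scaled graph metrics", {
  # independent traces produce i.i.d. edges, i.e. an Erdos-Renyi-like FC
  # graph; a moderate alpha keeps the graph dense enough for both metrics
  # to be well defined
  st <- generate_spike_trains(25, "asynchronous", rate = 12, duration = 120,
                              seed = 12)
  tr <- render_traces(st, seed = 13)
  net <- functional_connectivity(tr, alpha = 0.25, n_surrogate = 60,
                                 seed = 14)
  expect_gte(sum(net$adjacency) / 2, 10)
  nm <- network_metrics(net, n_null = 200, seed = 15)
  expect_gt(nm$clustering_scaled, 0.5)
  expect_lt(nm$clustering_scaled, 2)
  expect_gt(nm$char_path_scaled, 0.5)
  expect_lt(nm$char_path_scaled, 2)
})
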