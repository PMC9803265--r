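# Build a movie with bright discs at known centres on a flat background.
disc_movie <- function(centres, radius = 3, dims = c(64, 64), n_frames = 5,
                       background = 10, brightness = 100) {
  stack <- array(background, dim = c(dims, n_frames))
  for (k in seq_len(nrow(centres))) {
    for (r in seq_len(dims[1])) {
      for (cc in seq_len(dims[2])) {
        if ((r - centres[k, 1])^2 + (cc - centres[k, 2])^2 <= radius^2) {
          stack[r, cc, ] <- brightness
        }
      }
    }
  }
  as_movie(stack, frame_rate = 20)
}

test_that("movie containers validate their geometry and intensities", {
  expect_error(as_movie(matrix(0, 2, 2), 20), "rows x cols x frames")
  expect_error(as_movie(array(0, c(4, 4, 1)), 20), "at least 2 frames")
  expect_error(as_movie(array(-1, c(4, 4, 3)), 20), "non-negative")
})

test_that("an all-zero movie yields no ROIs, with a warning", {
  mv <- as_movie(array(0, c(32, 32, 3)), 20)
  expect_warning(mask <- segment_rois(mv), "no ROIs|No connected")
  expect_equal(nrow(mask$rois), 0)
})

test_that("disjoint bright discs are segmented with accurate centroids", {
  centres <- as.matrix(expand.grid(row = c(12, 32, 52), col = c(12, 32)))
  centres <- rbind(centres, c(52, 52))  # 7 discs
  mv <- disc_movie(centres)
  mask <- segment_rois(mv, min_area = 10, max_area = 100)
  expect_equal(nrow(mask$rois), nrow(centres))
  # match each truth centre to the nearest centroid (0-based -> +1)
  for (k in seq_len(nrow(centres))) {
    d <- sqrt((mask$rois$row + 1 - centres[k, 1])^2 +
                (mask$rois$col + 1 - centres[k, 2])^2)
    expect_lt(min(d), 1)
  }
})

test_that("ROIs outside the area bounds are filtered out", {
  centres <- matrix(c(16, 16, 48, 48), 2, 2, byrow = TRUE)
  mv <- disc_movie(centres, radius = 3)
  tiny <- disc_movie(matrix(c(32, 32), 1, 2), radius = 1)
  mv$stack <- pmax(mv$stack, tiny$stack)
  mask <- segment_rois(mv, min_area = 10, max_area = 100)
  expect_equal(nrow(mask$rois), 2)
})

test_that("8-connectivity merges diagonally touching pixels", {
  m <- matrix(FALSE, 8, 8)
  m[2, 2] <- m[3, 3] <- m[4, 4] <- TRUE
  labels <- caislands:::label_components_8(m)
  expect_equal(max(labels), 1)
})

test_that("trace extraction recovers ROI and background intensities", {
  mv <- disc_movie(matrix(c(16, 16), 1, 2), radius = 3, background = 2,
                   brightness = 10)
  mask <- segment_rois(mv, min_area = 5, max_area = 200)
  raw <- extract_traces(mv, mask)
  expect_equal(unname(raw$F[, 1]), rep(10, 5))
  expect_equal(raw$background, rep(2, 5), tolerance = 1e-12)
  # spatially uniform movie: every trace equals the frame value
  mv2 <- as_movie(array(rep(c(5, 6, 7), each = 16), c(4, 4, 3)), 20)
  mask2 <- structure(list(label_image = matrix(c(1L, rep(0L, 15)), 4, 4),
                          rois = tibble::tibble(roi = 1L, row = 0, col = 0,
                                                area = 1L)),
                     class = "roi_mask")
  raw2 <- extract_traces(mv2, mask2)
  expect_equal(unname(raw2$F[, 1]), c(5, 6, 7))
  expect_equal(raw2$full_field, c(5, 6, 7))
})

test_that("normalization gives dff = 1 on constant baselines", {
  raw <- structure(list(F = matrix(200, 100, 2), background = rep(100, 100),
                        full_field = rep(150, 100), frame_rate = 20),
                   class = "raw_trace_set")
  ts <- normalize_traces(raw)
  expect_true(all(abs(ts$dff - 1) < 1e-12))
})

test_that("normalization flattens a slow bleaching trend", {
  decay <- exp(-(0:599) / 20 / 300)          # 30-s recording, gentle bleach
  raw <- structure(list(F = matrix(100 * decay, 600, 1),
                        background = rep(0, 600),
                        full_field = 100 * decay, frame_rate = 20),
                   class = "raw_trace_set")
  ts <- normalize_traces(raw, window = 10)
  expect_true(all(abs(ts$dff - 1) < 0.05))
})

test_that("single transient on a flat baseline scales as 1 + amplitude/baseline", {
  f0 <- 50
  x <- rep(f0, 400)
  x[200:220] <- f0 + 25
  raw <- structure(list(F = matrix(x, 400, 1), background = rep(0, 400),
                        full_field = x, frame_rate = 20),
                   class = "raw_trace_set")
  ts <- normalize_traces(raw, window = 10)
  expect_equal(max(ts$dff), 1 + 25 / f0, tolerance = 1e-6)
})

test_that("normalization rejects non-positive baselines, naming the ROI", {
  raw <- structure(list(F = matrix(0, 100, 1), background = rep(10, 100),
                        full_field = rep(0, 100), frame_rate = 20),
                   class = "raw_trace_set")
  expect_error(normalize_traces(raw), "ROI 1")
})

test_that("the extract-normalize chain is invariant to intensity rescaling", {
  isl <- generate_island(island_config(400, 250, seed = 10))
  st <- generate_spike_trains(isl, "asynchronous", rate = 10, duration = 15,
                              seed = 11)
  tr <- render_traces(st, noise_sd = 0.01, seed = 12)
  mv <- render_movie(isl, tr, dims = c(96, 96), pixel_size = 5,
                     background = 20, gain = 60, noise_sd = 0.5, seed = 13)
  mask <- segment_rois(mv, min_area = 4, max_area = 300)
  dff1 <- trace_matrix(normalize_traces(extract_traces(mv, mask), window = 5))
  mv2 <- mv
  mv2$stack <- mv2$stack * 3.7
  dff2 <- trace_matrix(normalize_traces(extract_traces(mv2, mask), window = 5))
  expect_equal(dff1, dff2, tolerance = 1e-10)
})

test_that("segmentation recovers most cells of a rendered island movie and
           extracted traces track the ground-truth signal", {
  isl <- generate_island(island_config(420, 250, seed = 20), min_separation = 25)
  st <- generate_spike_trains(isl, "asynchronous", rate = 12, duration = 20,
                              seed = 21)
  tr <- render_traces(st, noise_sd = 0.01, seed = 22)
  mv <- render_movie(isl, tr, dims = c(110, 110), pixel_size = 4,
                     cell_sigma = 7, background = 20, gain = 80,
                     noise_sd = 0.5, seed = 23)
  mask <- segment_rois(mv, min_area = 4, max_area = 400)
  expect_gte(nrow(mask$rois), ceiling(0.95 * nrow(isl$cells)))
  # match ROIs to ground-truth cells via position, then correlate traces
  ts <- normalize_traces(extract_traces(mv, mask), window = 5)
  dff <- trace_matrix(ts)
  truth <- trace_matrix(tr)
  px <- isl$cells$x / 4 + 55
  py <- isl$cells$y / 4 + 55
  cors <- vapply(seq_len(nrow(mask$rois)), function(k) {
    d <- sqrt((mask$rois$row[k] + 1 - py)^2 + (mask$rois$col[k] + 1 - px)^2)
    j <- which.min(d)
    cor(dff[, k], truth[, j])
  }, numeric(1))
  expect_gt(mean(cors > 0.95), 0.9)
})
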