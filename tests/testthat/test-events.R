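test_that("the default template library has 128 peak-normalized waveforms", {
  lib <- template_library()
  expect_equal(ncol(lib$waveforms), 128)
  expect_equal(nrow(lib$params), 128)
  expect_true(all(abs(apply(lib$waveforms, 2, max) - 1) < 1e-12))
  expect_equal(nrow(lib$waveforms), ceiling(5 * max(lib$params$decay) * 20))
  expect_error(template_library(n_rise = 3, n_decay = 5, n_templates = 128),
               "does not match")
})

test_that("a 1 x 1 grid reduces to the kernel itself", {
  lib <- template_library(n_rise = 1, n_decay = 1, rise_range = c(0.05, 0.05),
                          decay_range = c(0.4, 0.4))
  k <- ca_kernel((seq_len(nrow(lib$waveforms)) - 1) / 20)
  expect_equal(lib$waveforms[, 1], k / max(k), tolerance = 1e-12)
})

test_that("a single inserted kernel is detected once, at the right time", {
  tr <- insert_kernel_trace(30, duration = 60, noise_sd = 0)
  ev <- detect_events(tr)
  expect_equal(nrow(ev), 1)
  expect_lte(abs(ev$onset - 30), 2 / 20)
  expect_gte(ev$score, 0.99)
})

test_that("pure noise produces no detections at the default threshold", {
  n_events <- vapply(1:10, function(s) {
    tr <- new_trace_set(matrix(rnorm(3600 * 10, mean = 1, sd = 0.02),
                               3600, 10), frame_rate = 20)
    nrow(detect_events(tr))
  }, numeric(1))
  expect_true(all(n_events == 0))
})

test_that("27 well-separated kernels give 27 events and 9 events/min", {
  onsets <- seq(2, 178, length.out = 27)
  tr <- insert_kernel_trace(onsets, duration = 180, noise_sd = 0.02,
                            seed = 5)
  ev <- detect_events(tr)
  expect_equal(nrow(ev), 27)
  expect_equal(mean_event_rate(ev), 9)
})

test_that("raising the threshold never increases the event count", {
  st <- generate_spike_trains(3, "asynchronous", rate = 15, duration = 120,
                              seed = 6)
  tr <- render_traces(st, seed = 7)
  counts <- vapply(c(0.6, 0.75, 0.85, 0.95),
                   function(r) nrow(detect_events(tr, r_min = r)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("events near the end of the recording are still detected", {
  tr <- insert_kernel_trace(c(50, 58.5), duration = 60, noise_sd = 0.02,
                            seed = 8)
  ev <- detect_events(tr)
  expect_equal(nrow(ev), 2)
  expect_lte(abs(ev$onset[2] - 58.5), 0.15)
})

test_that("detection reaches F1 >= 0.9 at default SNR for rates up to 20/min", {
  for (rate in c(6, 20)) {
    st <- generate_spike_trains(15, "asynchronous", rate = rate,
                                duration = 120, seed = rate)
    tr <- render_traces(st, seed = rate + 1)
    ev <- detect_events(tr)
    truth <- split(st$time, factor(st$cell, levels = 1:15))
    det <- split(ev$onset, factor(ev$cell, levels = 1:15))
    m <- lapply(1:15, function(i) match_events(truth[[i]], det[[i]]))
    tp <- sum(vapply(m, `[[`, 0L, "tp"))
    fp <- sum(vapply(m, `[[`, 0L, "fp"))
    fn <- sum(vapply(m, `[[`, 0L, "fn"))
    f1 <- 2 * tp / (2 * tp + fp + fn)
    expect_gte(f1, 0.9)
  }
})

test_that("the detected mean rate matches the generative rate within 10%", {
  st <- generate_spike_trains(30, "asynchronous", rate = 12, duration = 180,
                              seed = 31)
  tr <- render_traces(st, seed = 32)
  ev <- detect_events(tr)
  expect_lt(abs(mean_event_rate(ev) - 12) / 12, 0.1)
})

test_that("active-cell bookkeeping flags and filters never-active cells", {
  ev1 <- as_spike_trains(data.frame(cell = c(1L, 2L, 3L),
                                    time = c(1, 2, 3)), 4, 10)
  names(ev1)[2] <- "onset"
  ev2 <- as_spike_trains(data.frame(cell = 2L, time = 5), 4, 10)
  names(ev2)[2] <- "onset"
  flags <- classify_active(list(baseline = ev1, drug = ev2))
  expect_equal(nrow(flags), 8)
  expect_true(all(flags$retained[flags$cell %in% 1:3]))
  expect_false(any(flags$retained[flags$cell == 4]))
  # cell 1 active in baseline only, still retained
  expect_true(flags$active[flags$cell == 1 & flags$condition == "baseline"])
  expect_false(flags$active[flags$cell == 1 & flags$condition == "drug"])
  expect_equal(active_population_fraction(flags, "baseline"), 0.75)
  # mismatched populations error out
  ev3 <- as_spike_trains(data.frame(cell = 1L, time = 1), 6, 10)
  names(ev3)[2] <- "onset"
  expect_error(classify_active(list(ev1, ev3)), "different cell populations")
})
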