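fake_experiment <- function(baseline_cells, step_active, step_ablate,
                            n_cells, duration = 60) {
  mk <- function(cells) {
    st <- as_spike_trains(
      data.frame(cell = cells, time = seq_along(cells)),
      n_cells = n_cells, duration = duration)
    st
  }
  list(baseline = mk(baseline_cells),
       steps = purrr::map2(step_ablate, step_active, function(ab, ac) {
         list(ablated = ab, spikes = mk(ac))
       }))
}

test_that("resilience curves follow the bookkeeping rules", {
  # baseline: 8 of 10 active; step 1 ablates 2 active cells
  ex <- fake_experiment(1:8, list(c(3:8)), list(c(1L, 2L)), n_cells = 10)
  cv <- build_resilience_curve(ex)
  expect_equal(cv$injured_fraction, c(0, 0.2))
  expect_equal(cv$active_fraction, c(1, 0.75))
  expect_s3_class(cv, "resilience_curve")
  # no injury steps: single point (0, 1)
  ex0 <- fake_experiment(1:5, list(), list(), n_cells = 10)
  cv0 <- build_resilience_curve(ex0)
  expect_equal(nrow(cv0), 1)
  expect_equal(unlist(cv0[1, c("injured_fraction", "active_fraction")]),
               c(injured_fraction = 0, active_fraction = 1))
})

test_that("ablating already-silent cells leaves the active fraction unchanged", {
  ex <- fake_experiment(1:6, list(1:6), list(c(9L, 10L)), n_cells = 10)
  cv <- build_resilience_curve(ex)
  expect_equal(cv$active_fraction, c(1, 1))
})

test_that("ablated cells count as inactive even if they appear in a recording", {
  ex <- fake_experiment(1:6, list(1:6), list(c(1L, 2L)), n_cells = 10)
  cv <- build_resilience_curve(ex)
  expect_equal(cv$active_fraction[2], 4 / 6)
})

test_that("overlapping ablation sets are rejected", {
  ex <- fake_experiment(1:6, list(1:6, 1:6), list(c(1L, 2L), c(2L, 3L)),
                        n_cells = 10)
  expect_error(build_resilience_curve(ex), "disjoint")
})

test_that("silencing threshold picks the first step at or below epsilon", {
  cv <- tibble::tibble(injured_fraction = c(0, 0.2, 0.4),
                       active_fraction = c(1, 0.5, 0))
  expect_equal(silencing_threshold(cv), 0.4)
  expect_equal(silencing_threshold(cv, epsilon = 0.5), 0.2)
  never <- tibble::tibble(injured_fraction = c(0, 0.5),
                          active_fraction = c(1, 0.4))
  expect_warning(th <- silencing_threshold(never), "undefined")
  expect_true(is.na(th))
  # threshold is non-increasing in epsilon
  eps <- c(0, 0.1, 0.3, 0.5)
  ths <- vapply(eps, function(e) suppressWarnings(
    silencing_threshold(cv, epsilon = e)), numeric(1))
  expect_true(all(diff(ths[!is.na(ths)]) <= 0))
})

test_that("half-activity threshold interpolates the first crossing", {
  cv <- tibble::tibble(injured_fraction = c(0, 0.1, 0.2),
                       active_fraction = c(1, 0.8, 0.4))
  expect_equal(half_activity_threshold(cv), 0.175)
  expect_equal(half_activity_threshold(cv, interpolate = FALSE), 0.2)
  # a step exactly at 0.5 is returned as-is
  cv2 <- tibble::tibble(injured_fraction = c(0, 0.3),
                        active_fraction = c(1, 0.5))
  expect_equal(half_activity_threshold(cv2), 0.3)
  # starting below the level returns 0 with a warning
  cv3 <- tibble::tibble(injured_fraction = c(0, 0.1),
                        active_fraction = c(0.4, 0.2))
  expect_warning(th3 <- half_activity_threshold(cv3), "0")
  expect_equal(th3, 0)
  cv4 <- tibble::tibble(injured_fraction = c(0, 0.9),
                        active_fraction = c(1, 0.8))
  expect_warning(th4 <- half_activity_threshold(cv4), "undefined")
  expect_true(is.na(th4))
})

test_that("independent cells lose activity linearly with injury", {
  isl <- generate_island(island_config(750, 150, seed = 30))
  model <- cascade_model(p_spont = 0.02, p_exc = 0)
  devs <- c()
  halves <- c()
  sils <- c()
  for (s in 1:8) {
    ex <- simulate_ablation_experiment(isl, model, max_injured_fraction = 1,
                                       baseline_duration = 30,
                                       step_duration = 30, seed = s)
    cv <- build_resilience_curve(ex)
    devs <- c(devs, cv$active_fraction - (1 - cv$injured_fraction))
    halves <- c(halves, suppressWarnings(half_activity_threshold(cv)))
    sils <- c(sils, suppressWarnings(silencing_threshold(cv)))
  }
  expect_lt(mean(abs(devs)), 0.05)
  expect_lt(abs(mean(halves) - 0.5), 0.1)
  expect_lt(abs(mean(sils, na.rm = TRUE) - 1), 0.1)
})

test_that("coupled cascades collapse: half-threshold precedes silencing", {
  isl <- generate_island(island_config(900, 150, seed = 31))
  pairs <- vapply(1:10, function(s) {
    ex <- simulate_ablation_experiment(isl, cascade_preset("rigid"),
                                       max_injured_fraction = 1,
                                       baseline_duration = 60,
                                       step_duration = 30, seed = s)
    # a silent baseline leaves resilience undefined for that island
    cv <- tryCatch(build_resilience_curve(ex), error = function(e) NULL)
    if (is.null(cv)) return(c(NA_real_, NA_real_))
    c(suppressWarnings(half_activity_threshold(cv)),
      suppressWarnings(silencing_threshold(cv)))
  }, numeric(2))
  ok <- is.finite(pairs[1, ]) & is.finite(pairs[2, ])
  expect_true(all(pairs[1, ok] <= pairs[2, ok]))
  expect_gt(mean(pairs[2, ok] - pairs[1, ok]), 0)
})

test_that("flexible (high-entropy) circuits tolerate more injury than rigid ones", {
  isl <- generate_island(island_config(900, 150, seed = 32))
  half_of <- function(model, s) {
    ex <- simulate_ablation_experiment(isl, model, max_injured_fraction = 1,
                                       baseline_duration = 60,
                                       step_duration = 30, seed = s)
    cv <- tryCatch(build_resilience_curve(ex), error = function(e) NULL)
    if (is.null(cv)) return(NA_real_)
    suppressWarnings(half_activity_threshold(cv))
  }
  flex <- vapply(1:8, function(s) half_of(cascade_preset("flexible"), s),
                 numeric(1))
  rigid <- vapply(1:8, function(s) half_of(cascade_preset("rigid"), s),
                  numeric(1))
  expect_gt(mean(flex, na.rm = TRUE), mean(rigid, na.rm = TRUE))
})

test_that("predictor correlations behave like OLS", {
  s <- tibble::tibble(half_activity_threshold = c(0.1, 0.2, 0.3, 0.4),
                      baseline_rate = c(2, 4, 6, 8))
  fit <- suppressWarnings(predictor_correlation(s, "baseline_rate"))
  expect_equal(fit$r.squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 0.05, tolerance = 1e-12)
  # duplicated rows leave R^2 unchanged
  fit2 <- suppressWarnings(
    predictor_correlation(dplyr::bind_rows(s, s), "baseline_rate"))
  expect_equal(fit2$r.squared, fit$r.squared, tolerance = 1e-12)
  # independent predictor: R^2 near zero
  set.seed(6)
  big <- tibble::tibble(half_activity_threshold = runif(200),
                        baseline_rate = rnorm(200))
  expect_lt(predictor_correlation(big, "baseline_rate")$r.squared, 0.05)
  expect_warning(
    out <- predictor_correlation(
      tibble::tibble(half_activity_threshold = c(0.1, 0.2, 0.3),
                     baseline_rate = c(1, 1, 1)), "baseline_rate"),
    "Constant")
  expect_true(is.na(out$r.squared))
  expect_error(predictor_correlation(s[1:2, ], "baseline_rate"), "at least 3")
})

test_that("FC time courses are expressed relative to baseline", {
  tc <- fc_timecourse(c(baseline = 0.4, post = 0.4, h6 = 0.3, h20 = 0.2))
  expect_equal(tc$relative_density, c(1, 1, 0.75, 0.5))
  expect_warning(tc0 <- fc_timecourse(c(baseline = 0, post = 0.2)),
                 "undefined")
  expect_true(all(is.na(tc0$relative_density)))
})
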