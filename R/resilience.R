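#' Build an activity-versus-injury resilience curve
#'
#' For each injury step, computes the cumulative injured fraction
#' (ablated cells over the baseline population) and the active fraction
#' (cells with at least one event among the survivors, over the baseline
#' active count; ablated cells count as inactive). The curve starts at
#' (0, 1) for the baseline recording.
#'
#' @param experiment A [simulate_ablation_experiment()] result, or a list
#'   with elements `baseline` (events/spike trains), `steps` (each a list
#'   with `ablated` ids and `spikes`/`events`), and a known cell count.
#' @param activity_fn Function mapping a recording to the integer ids of
#'   active cells; the default treats any cell with >= 1 event as active.
#' @param island_id,density_group Optional labels carried into the curve.
#'
#' @return A `resilience_curve` tibble: `step`, `injured_fraction`
#'   (non-decreasing), `active_fraction`, `n_active`, plus label columns.
#' @examples
#' isl <- generate_island(island_config(750, 120, seed = 1))
#' ex <- simulate_ablation_experiment(isl, cascade_model(p_spont = 0.003),
#'                                    baseline_duration = 30,
#'                                    step_duration = 15, seed = 2)
#' build_resilience_curve(ex)
#' @export
build_resilience_curve <- function(experiment,
                                   activity_fn = function(rec) unique(rec$cell),
                                   island_id = NA_character_,
                                   density_group = NA_character_) {
  stopifnot(is.list(experiment))
  baseline <- experiment$baseline
  n_total <- attr(baseline, "n_cells") %||% nrow(experiment$island$cells)
  if (is.null(n_total)) abort("Cannot determine the baseline population size.")
  base_active <- unique(activity_fn(baseline))
  if (length(base_active) == 0) {
    abort("Baseline recording has no active cells; resilience is undefined.")
  }
  ablated <- integer(0)
  rows <- list(tibble(step = 0L, injured_fraction = 0,
                      active_fraction = 1,
                      n_active = length(base_active)))
  for (i in seq_along(experiment$steps)) {
    st <- experiment$steps[[i]]
    if (any(st$ablated %in% ablated)) {
      abort("Ablated sets must be disjoint across steps.")
    }
    ablated <- c(ablated, st$ablated)
    rec <- st$spikes %||% st$events
    act <- setdiff(unique(activity_fn(rec)), ablated)
    rows[[i + 1L]] <- tibble(
      step = i,
      injured_fraction = length(ablated) / n_total,
      active_fraction = length(act) / length(base_active),
      n_active = length(act)
    )
  }
  out <- bind_rows(rows)
  out$island_id <- island_id
  out$density_group <- density_group
  class(out) <- c("resilience_curve", class(out))
  out
}

#' Injury level at which activity is fully silenced
#'
#' Smallest injured fraction whose active fraction is at or below
#' `epsilon` (default 0: literal silence). `NA` (flagged by a warning) if
#' the curve never reaches it.
#'
#' @param curve A [build_resilience_curve()] tibble.
#' @param epsilon Activity level counted as silence.
#' @return Injured fraction in \[0, 1\], or `NA` if never silenced.
#' @examples
#' cv <- tibble::tibble(injured_fraction = c(0, .2, .4),
#'                      active_fraction = c(1, .5, 0))
#' silencing_threshold(cv)  # 0.4
#' @export
silencing_threshold <- function(curve, epsilon = 0) {
  check_number(epsilon, "epsilon", 0, 1)
  hit <- which(curve$active_fraction <= epsilon + 1e-12)
  if (!length(hit)) {
    warn("Activity never collapsed below `epsilon`: silencing threshold undefined.")
    return(NA_real_)
  }
  min(curve$injured_fraction[hit])
}

#' Injury level at which half the baseline activity is lost
#'
#' Linearly interpolates the first downward crossing of
#' `active_fraction = 0.5` (the half-activity point); with
#' `interpolate = FALSE` the first step at or below 0.5 is returned. A
#' curve that starts below 0.5 returns 0 with a warning; a curve that
#' never crosses returns `NA` with a warning.
#'
#' @param curve A [build_resilience_curve()] tibble.
#' @param level Activity level of the crossing (default 0.5).
#' @param interpolate Interpolate between the bracketing steps?
#' @return Injured fraction in \[0, 1\], or `NA`.
#' @examples
#' cv <- tibble::tibble(injured_fraction = c(0, .1, .2),
#'                      active_fraction = c(1, .8, .4))
#' half_activity_threshold(cv)  # 0.175
#' @export
half_activity_threshold <- function(curve, level = 0.5, interpolate = TRUE) {
  check_number(level, "level", 0, 1)
  af <- curve$active_fraction
  inj <- curve$injured_fraction
  if (af[1] <= level) {
    warn("Curve starts at or below the target level; threshold reported as 0.")
    return(0)
  }
  below <- which(af <= level)
  if (!length(below)) {
    warn("Activity never dropped to the target level: threshold undefined.")
    return(NA_real_)
  }
  k <- min(below)
  if (af[k] == level || !interpolate) return(inj[k])
  inj[k - 1] + (inj[k] - inj[k - 1]) * (af[k - 1] - level) / (af[k - 1] - af[k])
}

#' Summarize an ablation experiment into resilience statistics
#'
#' @param experiment A [simulate_ablation_experiment()] result.
#' @param ... Passed to [build_resilience_curve()].
#' @param epsilon Silence level for [silencing_threshold()].
#' @return A one-row tibble: `silencing_threshold`,
#'   `half_activity_threshold`, `baseline_rate` (events/min over active
#'   cells), `baseline_entropy` (island mean Markov entropy).
#' @export
resilience_summary <- function(experiment, ..., epsilon = 0) {
  curve <- build_resilience_curve(experiment, ...)
  base <- experiment$baseline
  dur <- attr(base, "duration")
  ent <- island_entropy(base, frame_rate = attr(base, "frame_rate") %||% 20)
  tibble(
    silencing_threshold = suppressWarnings(silencing_threshold(curve, epsilon)),
    half_activity_threshold = suppressWarnings(half_activity_threshold(curve)),
    baseline_rate = mean_event_rate(base, duration = dur),
    baseline_entropy = ent$mean
  )
}

#' Correlation between a baseline predictor and injury resilience
#'
#' Ordinary least squares of the half-activity injury threshold on a
#' baseline circuit property (event rate or Markov entropy), across
#' islands.
#'
#' @param summaries A tibble with columns `half_activity_threshold` and
#'   the predictor (e.g. from [resilience_summary()] row-bound across
#'   islands).
#' @param predictor Column name: `"baseline_rate"` or
#'   `"baseline_entropy"` (any numeric column is accepted).
#' @return A one-row tibble: `r.squared`, `slope`, `intercept`, `n`.
#'   A constant predictor gives `NA` with a warning.
#' @examples
#' s <- tibble::tibble(half_activity_threshold = c(.1, .2, .3),
#'                     baseline_rate = c(2, 4, 6))
#' predictor_correlation(s, "baseline_rate")
#' @export
predictor_correlation <- function(summaries, predictor = "baseline_rate") {
  if (!predictor %in% names(summaries)) {
    abort(sprintf("Column `%s` not found.", predictor))
  }
  d <- summaries[is.finite(summaries$half_activity_threshold) &
                   is.finite(summaries[[predictor]]), ]
  if (nrow(d) < 3) abort("Need at least 3 islands with defined thresholds.")
  if (sd(d[[predictor]]) == 0) {
    warn("Constant predictor: R^2 undefined.")
    return(tibble(r.squared = NA_real_, slope = NA_real_,
                  intercept = NA_real_, n = nrow(d)))
  }
  fit <- lm(d$half_activity_threshold ~ d[[predictor]])
  tibble(r.squared = summary(fit)$r.squared,
         slope = coef(fit)[[2]], intercept = coef(fit)[[1]],
         n = nrow(d))
}

#' Post-injury functional connectivity time course
#'
#' FC density at each follow-up time point divided by the baseline FC
#' density over the same surviving-cell population.
#'
#' @param densities Named numeric vector or tibble column of FC densities
#'   ordered in time, the first being baseline.
#' @return A tibble: `timepoint`, `fc_density`, `relative_density`.
#' @examples
#' fc_timecourse(c(baseline = 0.4, post = 0.4, h6 = 0.3, h20 = 0.2))
#' @export
fc_timecourse <- function(densities) {
  if (inherits(densities, "data.frame")) {
    stopifnot("fc_density" %in% names(densities))
    vals <- densities$fc_density
    labs <- densities$timepoint %||% seq_along(vals)
  } else {
    vals <- as.numeric(densities)
    labs <- names(densities) %||% seq_along(vals)
  }
  if (length(vals) < 1) abort("Need at least a baseline density.")
  if (vals[1] <= 0) {
    warn("Baseline FC density is 0: relative time course undefined.")
    return(tibble(timepoint = labs, fc_density = vals,
                  relative_density = NA_real_))
  }
  tibble(timepoint = labs, fc_density = vals,
         relative_density = vals / vals[1])
}
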