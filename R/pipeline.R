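pipeline_defaults <- function() {
  list(
    seed = 1L,
    output_dir = NULL,
    input = list(type = "synthetic", traces_csv = NULL, frame_rate = NULL),
    synthetic = list(diameter = 750, cell_density = 150,
                     inhibitory_fraction = 0.2, duration = 180,
                     frame_rate = 20, regime = "asynchronous", rate = 12,
                     participation = 0.9, jitter = 0.05, noise_sd = 0.02),
    detection = list(r_min = 0.85, refractory = 0.5),
    activity = list(tau_max = 1),
    entropy = list(window = 1),
    network = list(alpha = 0.05, n_surrogate = 100, min_shift = 5,
                   n_null = 1000),
    injury = list(enabled = FALSE, step_size = 5,
                  max_injured_fraction = 0.75, step_duration = 60,
                  p_spont = 0.002, p_exc = 0.05, p_inh_block = 0.5)
  )
}

#' Assemble and validate a pipeline configuration
#'
#' Merges user settings over the documented defaults and rejects unknown
#' keys, so typos fail loudly before any computation. Configurations can
#' also be read from YAML or JSON files.
#'
#' @param ... Named settings; nested sections are lists, e.g.
#'   `synthetic = list(rate = 6)`.
#' @param path For `read_pipeline_config()`, a YAML or JSON file.
#' @return A validated config list of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config(seed = 7, synthetic = list(rate = 6))
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  defaults <- pipeline_defaults()
  merged <- merge_config(defaults, user, path = "config")
  structure(merged, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  parsed <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(pipeline_config, parsed)
}

merge_config <- function(base, user, path) {
  if (is.null(user)) return(base)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    abort(sprintf("Unknown configuration key(s) under `%s`: %s",
                  path, paste0(unknown, collapse = ", ")))
  }
  for (k in names(user)) {
    if (is.list(base[[k]]) && !is.null(base[[k]])) {
      base[[k]] <- merge_config(base[[k]], as.list(user[[k]]),
                                paste0(path, "$", k))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Run the full island analysis pipeline
#'
#' Executes ingestion (synthetic generation or trace CSV), event
#' detection, activity metrics, per-cell Markov entropy, functional
#' network construction with null-referenced graph metrics, and — when
#' the injury section is enabled — a simulated sequential-ablation
#' experiment with its resilience summary. All stage seeds are derived
#' from `config$seed`, so a fixed configuration reproduces its outputs
#' bit for bit. When `output_dir` is set, artifacts (traces, events,
#' metrics, network, resilience curve) and a JSON manifest with the
#' parameter echo are written there.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result`: `traces`, `events`,
#'   `activity` (one-row tibble), `entropy`, `network`,
#'   `network_metrics`, and optionally `experiment`, `resilience_curve`,
#'   `resilience_summary`; plus `manifest`.
#' @examples
#' \donttest{
#' res <- run_pipeline(pipeline_config(
#'   seed = 1,
#'   synthetic = list(cell_density = 80, duration = 60),
#'   network = list(n_surrogate = 20, n_null = 100)))
#' res$activity
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- as.integer(config$seed)
  island <- NULL

  if (config$input$type == "synthetic") {
    sy <- config$synthetic
    island <- generate_island(island_config(
      diameter = sy$diameter, cell_density = sy$cell_density,
      inhibitory_fraction = sy$inhibitory_fraction,
      duration = sy$duration, frame_rate = sy$frame_rate,
      seed = derive_seed(seed, 1L)))
    spikes <- generate_spike_trains(
      island, regime = sy$regime, rate = sy$rate, duration = sy$duration,
      participation = sy$participation, jitter = sy$jitter,
      seed = derive_seed(seed, 2L))
    traces <- render_traces(spikes, frame_rate = sy$frame_rate,
                            noise_sd = sy$noise_sd,
                            seed = derive_seed(seed, 3L))
  } else if (config$input$type == "traces_csv") {
    if (is.null(config$input$traces_csv)) {
      abort("Config key `input$traces_csv` is required for CSV input.")
    }
    spikes <- NULL
    traces <- read_traces_csv(config$input$traces_csv,
                              frame_rate = config$input$frame_rate)
  } else {
    abort(sprintf("Unknown input type `%s`.", config$input$type))
  }

  events <- detect_events(traces,
                          r_min = config$detection$r_min,
                          refractory = config$detection$refractory)
  flags <- classify_active(events)
  activity <- activity_metrics(traces, events,
                               tau_max = config$activity$tau_max)
  entropy <- island_entropy(events, window = config$entropy$window)

  active_ids <- sort(unique(events$cell))
  network <- NULL
  net_metrics <- NULL
  if (length(active_ids) >= 2) {
    network <- functional_connectivity(
      traces, cells = active_ids, tau_max = config$activity$tau_max,
      alpha = config$network$alpha,
      n_surrogate = config$network$n_surrogate,
      min_shift = config$network$min_shift,
      seed = derive_seed(seed, 4L))
    net_metrics <- tryCatch(
      network_metrics(network, n_null = config$network$n_null,
                      seed = derive_seed(seed, 5L)),
      error = function(e) NULL)
  }

  experiment <- curve <- summary_row <- NULL
  if (isTRUE(config$injury$enabled)) {
    if (is.null(island)) {
      abort("Injury simulation requires synthetic input (an island layout).")
    }
    inj <- config$injury
    model <- cascade_model(p_spont = inj$p_spont, p_exc = inj$p_exc,
                           p_inh_block = inj$p_inh_block)
    experiment <- simulate_ablation_experiment(
      island, model, step_size = inj$step_size,
      max_injured_fraction = inj$max_injured_fraction,
      baseline_duration = config$synthetic$duration,
      step_duration = inj$step_duration, seed = derive_seed(seed, 6L))
    curve <- build_resilience_curve(experiment)
    summary_row <- resilience_summary(experiment)
  }

  manifest <- list(
    package = "caislands",
    version = as.character(utils::packageVersion("caislands")),
    seed = seed,
    config = unclass(config),
    n_cells = attr(events, "n_cells"),
    n_events = nrow(events)
  )
  result <- structure(
    list(traces = traces, spikes = spikes, events = events, flags = flags,
         activity = activity, entropy = entropy, network = network,
         network_metrics = net_metrics, experiment = experiment,
         resilience_curve = curve, resilience_summary = summary_row,
         manifest = manifest),
    class = "pipeline_result")

  if (!is.null(config$output_dir)) write_pipeline_outputs(result, config)
  result
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$output_dir, f)
  write_traces_csv(result$traces, p("traces.csv"))
  write_events_csv(result$events, p("events.csv"))
  utils::write.csv(result$activity, p("activity_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(tidy(result$entropy), p("entropy.csv"), row.names = FALSE)
  if (!is.null(result$network)) {
    write_network_csv(result$network, p("network_edges.csv"))
    write_network_graphml(result$network, p("network.graphml"))
  }
  if (!is.null(result$network_metrics)) {
    utils::write.csv(result$network_metrics, p("network_metrics.csv"),
                     row.names = FALSE)
  }
  if (!is.null(result$resilience_curve)) {
    utils::write.csv(result$resilience_curve, p("resilience_curve.csv"),
                     row.names = FALSE)
    utils::write.csv(result$resilience_summary, p("resilience_summary.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(config$output_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  cells: %d, events: %d\n", x$manifest$n_cells,
              x$manifest$n_events))
  print(x$activity)
  invisible(x)
}

#' Density category of an island
#'
#' The three plating-density bins used throughout the analysis:
#' low < 175, medium 175--250, high > 250 cells/mm^2, with the boundary
#' values 175 and 250 assigned to the upper bin (lower-inclusive rule).
#'
#' @param density Numeric vector of densities, cells/mm^2.
#' @return Factor with levels `low`, `medium`, `high`.
#' @examples
#' density_bin(c(100, 175, 200, 250, 300))
#' @export
density_bin <- function(density) {
  cut(density, breaks = c(-Inf, 175, 250, Inf),
      labels = c("low", "medium", "high"), right = FALSE)
}

#' Summarize island metrics by density category
#'
#' Bins islands into the low/medium/high density groups and reports the
#' mean and standard error of every numeric metric per group. Hypothesis
#' testing across groups is left to standard routines (`aov()`,
#' `kruskal.test()`, ...) on the same tidy table.
#'
#' @param metrics A tidy tibble, one row per island, containing a
#'   `cell_density` column and numeric metric columns.
#' @return A tibble: `density_group`, `metric`, `mean`, `se`, `n`
#'   (`se` is `NA` when a group has a single island; empty groups appear
#'   with `n = 0`).
#' @examples
#' m <- tibble::tibble(cell_density = c(100, 120, 300),
#'                     event_rate = c(12, 14, 0.7))
#' summarize_groups(m)
#' @export
summarize_groups <- function(metrics) {
  if (!"cell_density" %in% names(metrics)) {
    abort("`metrics` must contain a `cell_density` column.")
  }
  metrics <- mutate(metrics, density_group = density_bin(.data$cell_density))
  value_cols <- setdiff(names(metrics)[vapply(metrics, is.numeric, TRUE)],
                        "cell_density")
  long <- tidyr::pivot_longer(metrics, dplyr::all_of(value_cols),
                              names_to = "metric", values_to = "value")
  out <- long |>
    group_by(.data$density_group, .data$metric, .drop = FALSE) |>
    summarise(
      mean = mean(.data$value, na.rm = TRUE),
      se = if (sum(is.finite(.data$value)) > 1)
        sd(.data$value, na.rm = TRUE) / sqrt(sum(is.finite(.data$value)))
      else NA_real_,
      n = sum(is.finite(.data$value)),
      .groups = "drop")
  out$mean[out$n == 0] <- NA_real_
  out
}
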