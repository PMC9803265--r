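#' Read and write pipeline artifacts
#'
#' Traces travel as wide CSV (first column `time`, one column per cell),
#' events as tidy CSV (`cell`, `onset_s`, `score`), spike trains and
#' metrics as JSON, functional networks as GraphML or edge-list CSV.
#'
#' @param traces,events,spikes,network Objects to write.
#' @param path Output file path.
#' @param frame_rate Frames per second (when reading traces).
#' @return Readers return the parsed object; writers return `path`
#'   invisibly.
#' @name pipeline-io
NULL

#' @rdname pipeline-io
#' @export
write_traces_csv <- function(traces, path) {
  mat <- trace_matrix(traces)
  fr <- frame_rate(traces)
  df <- data.frame(time = (seq_len(nrow(mat)) - 1) / fr, mat)
  names(df) <- c("time", paste0("cell_", colnames(mat)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_traces_csv <- function(path, frame_rate = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time") abort("Expected a `time` first column.")
  if (is.null(frame_rate)) frame_rate <- 1 / stats::median(diff(df$time))
  mat <- as.matrix(df[, -1, drop = FALSE])
  cells <- as.integer(sub("^cell_", "", colnames(mat)))
  if (anyNA(cells)) cells <- seq_len(ncol(mat))
  new_trace_set(unname(mat), frame_rate = frame_rate, cells = cells)
}

#' @rdname pipeline-io
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(
    data.frame(cell_id = events$cell, onset_s = events$onset,
               score = events$score),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
write_spikes_json <- function(spikes, path) {
  by_cell <- split(spikes$time, factor(spikes$cell,
                                       levels = seq_len(n_cells(spikes))))
  jsonlite::write_json(
    list(duration = recording_duration(spikes),
         regime = attr(spikes, "regime") %||% "unknown",
         burst_times = attr(spikes, "burst_times") %||% numeric(0),
         spike_times = unname(by_cell)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(fc_igraph(network), path, format = "graphml")
  invisible(path)
}

#' @rdname pipeline-io
#' @export
write_network_csv <- function(network, path) {
  utils::write.csv(tidy(network), path, row.names = FALSE)
  invisible(path)
}
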