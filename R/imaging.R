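#' Fluorescence movie containers and TIFF I/O
#'
#' A movie is a `rows x cols x frames` intensity array with a frame rate
#' and optional pixel size. Pixel coordinates are 0-based `(row, col)`;
#' frame `i` corresponds to time `(i - 1) / frame_rate`.
#'
#' @param stack A 3-D numeric array (rows x cols x frames), finite and
#'   non-negative, with at least 2 frames.
#' @param frame_rate Frames per second.
#' @param pixel_size Micrometres per pixel (optional).
#' @param path TIFF file path.
#' @param movie A `fluorescence_movie`.
#' @param scale Intensity corresponding to full scale when writing 16-bit
#'   TIFF (defaults to the stack maximum).
#' @return `as_movie()`/`read_movie_tiff()` return a
#'   `fluorescence_movie`; `write_movie_tiff()` returns `path` invisibly.
#' @export
as_movie <- function(stack, frame_rate, pixel_size = NULL) {
  if (!is.array(stack) || length(dim(stack)) != 3) {
    abort("`stack` must be a rows x cols x frames array.")
  }
  if (dim(stack)[3] < 2) abort("A movie needs at least 2 frames.")
  if (any(!is.finite(stack)) || any(stack < 0)) {
    abort("Movie intensities must be finite and non-negative.")
  }
  check_number(frame_rate, "frame_rate", lower = 1e-9)
  structure(list(stack = stack, frame_rate = frame_rate,
                 pixel_size = pixel_size),
            class = "fluorescence_movie")
}

#' @rdname as_movie
#' @export
read_movie_tiff <- function(path, frame_rate, pixel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  stack <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) stack[, , i] <- pages[[i]]
  as_movie(stack, frame_rate, pixel_size)
}

#' @rdname as_movie
#' @export
write_movie_tiff <- function(movie, path, scale = NULL) {
  stopifnot(inherits(movie, "fluorescence_movie"))
  if (is.null(scale)) scale <- max(movie$stack)
  if (scale <= 0) scale <- 1
  frames <- lapply(seq_len(dim(movie$stack)[3]), function(i) {
    pmin(movie$stack[, , i] / scale, 1)
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16)
  invisible(path)
}

#' Segment cell bodies from a movie's maximum-intensity projection
#'
#' Binarizes the recording with a global threshold (default: Otsu's
#' method on the time-maximum projection), labels 8-connected components
#' of the binary projection, and filters them by area. Finding no
#' components is reported with a warning, not an error.
#'
#' @param movie A `fluorescence_movie`.
#' @param threshold Absolute intensity threshold; `NULL` for Otsu.
#' @param min_area,max_area ROI area bounds, px^2.
#' @return A list of class `roi_mask`: `label_image` (0 = background,
#'   k = ROI k), `rois` (tibble: `roi`, `row`, `col` 0-based centroids,
#'   `area`).
#' @export
segment_rois <- function(movie, threshold = NULL, min_area = 20,
                         max_area = 500) {
  stopifnot(inherits(movie, "fluorescence_movie"))
  proj <- apply(movie$stack, c(1, 2), max)
  if (is.null(threshold)) {
    rng <- range(proj)
    if (rng[2] <= rng[1]) {
      warn("Flat projection: no ROIs found.")
      return(empty_roi_mask(dim(proj)))
    }
    scaled <- (proj - rng[1]) / (rng[2] - rng[1])
    threshold <- rng[1] + (rng[2] - rng[1]) *
      EBImage::otsu(EBImage::Image(scaled))
  }
  mask <- proj > threshold
  labels <- label_components_8(mask)
  if (max(labels) == 0) {
    warn("No connected components above threshold.")
    return(empty_roi_mask(dim(proj)))
  }
  areas <- tabulate(labels[labels > 0])
  keep <- which(areas >= min_area & areas <= max_area)
  if (!length(keep)) {
    warn("No ROI passed the area filter.")
    return(empty_roi_mask(dim(proj)))
  }
  relab <- integer(length(areas))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(mask), ncol(mask))
  sel <- labels > 0 & relab[pmax(labels, 1)] > 0
  out[sel] <- relab[labels[sel]]
  rois <- purrr::map_dfr(seq_along(keep), function(k) {
    idx <- which(out == k, arr.ind = TRUE)
    tibble(roi = k, row = mean(idx[, 1]) - 1, col = mean(idx[, 2]) - 1,
           area = nrow(idx))
  })
  structure(list(label_image = out, rois = rois), class = "roi_mask")
}

empty_roi_mask <- function(dims) {
  structure(list(label_image = matrix(0L, dims[1], dims[2]),
                 rois = tibble(roi = integer(), row = double(),
                               col = double(), area = integer())),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d ROIs on a %d x %d field\n",
              nrow(x$rois), nrow(x$label_image), ncol(x$label_image)))
  invisible(x)
}

#' @method tidy roi_mask
#' @export
tidy.roi_mask <- function(x, ...) x$rois

# 8-connected component labelling of a logical matrix.
label_components_8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  labels <- matrix(0L, nr, nc)
  if (!length(fg)) return(labels)
  node <- matrix(0L, nr, nc)
  node[fg] <- seq_along(fg)
  edge_pairs <- function(dr, dc) {
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    a <- mask[r1, c1, drop = FALSE] & mask[r1 + dr, c1 + dc, drop = FALSE]
    if (!any(a)) return(NULL)
    i <- which(a, arr.ind = TRUE)
    cbind(node[cbind(r1[i[, 1]], c1[i[, 2]])],
          node[cbind(r1[i[, 1]] + dr, c1[i[, 2]] + dc)])
  }
  edges <- do.call(rbind, Filter(Negate(is.null), list(
    edge_pairs(0L, 1L), edge_pairs(1L, 0L),
    edge_pairs(1L, 1L), edge_pairs(1L, -1L))))
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  labels[fg] <- as.integer(comp)
  labels
}

#' Extract per-ROI fluorescence traces from a movie
#'
#' Per-frame mean pixel intensity inside each ROI, together with the
#' per-frame background (mean over non-ROI pixels) and the full-field
#' mean. With an empty mask only background and full-field are returned.
#'
#' @param movie A `fluorescence_movie`.
#' @param mask A [segment_rois()] result with matching frame geometry.
#' @return A list of class `raw_trace_set`: `F` (frames x ROIs matrix),
#'   `background`, `full_field` (per-frame vectors), `frame_rate`.
#' @export
extract_traces <- function(movie, mask) {
  stopifnot(inherits(movie, "fluorescence_movie"), inherits(mask, "roi_mask"))
  d <- dim(movie$stack)
  if (!all(dim(mask$label_image) == d[1:2])) {
    abort("Mask and movie frame dimensions differ.")
  }
  lab <- as.vector(mask$label_image)
  n_roi <- nrow(mask$rois)
  n_frames <- d[3]
  fmat <- matrix(NA_real_, n_frames, max(n_roi, 0))
  background <- full_field <- numeric(n_frames)
  in_roi <- lab > 0
  for (f in seq_len(n_frames)) {
    v <- as.vector(movie$stack[, , f])
    full_field[f] <- mean(v)
    background[f] <- if (any(!in_roi)) mean(v[!in_roi]) else NA_real_
    if (n_roi > 0) {
      sums <- rowsum(v[in_roi], lab[in_roi])
      fmat[f, ] <- sums[, 1] / tabulate(lab[in_roi], nbins = n_roi)
    }
  }
  structure(list(F = fmat, background = background, full_field = full_field,
                 frame_rate = movie$frame_rate),
            class = "raw_trace_set")
}

#' Background-subtract and baseline-normalize raw traces
#'
#' Subtracts the per-frame background from each ROI trace, estimates the
#' per-cell baseline F0 as a rolling low percentile (default 10th over
#' 30-s windows) linearly interpolated to every frame, and returns
#' `dff = (F - F_background) / F0`. A constant-baseline recording yields
#' `dff = 1` everywhere.
#'
#' @param raw An [extract_traces()] result (or a frames x cells matrix
#'   with `frame_rate` supplied).
#' @param window Baseline window length, seconds.
#' @param percentile Baseline percentile in (0, 1).
#' @param frame_rate Required if `raw` is a bare matrix.
#' @return A [new_trace_set()] tibble.
#' @export
normalize_traces <- function(raw, window = 30, percentile = 0.1,
                             frame_rate = NULL) {
  if (inherits(raw, "raw_trace_set")) {
    fmat <- raw$F
    bg <- raw$background
    if (anyNA(bg)) bg <- rep(0, length(raw$full_field))
    frame_rate <- raw$frame_rate
  } else {
    fmat <- as.matrix(raw)
    bg <- rep(0, nrow(fmat))
    if (is.null(frame_rate)) abort("Provide `frame_rate` for matrix input.")
  }
  check_number(percentile, "percentile", 1e-6, 1)
  n_frames <- nrow(fmat)
  y <- fmat - bg
  w <- max(2L, round(window * frame_rate))
  dff <- matrix(NA_real_, n_frames, ncol(fmat))
  for (j in seq_len(ncol(fmat))) {
    f0 <- rolling_percentile(y[, j], w, percentile)
    if (any(f0 <= 0)) {
      abort(sprintf("Baseline F0 is non-positive for ROI %d.", j))
    }
    dff[, j] <- y[, j] / f0
  }
  new_trace_set(dff, frame_rate = frame_rate)
}

# Low percentile over non-overlapping windows, linearly interpolated back
# to every frame.
rolling_percentile <- function(x, w, p) {
  n <- length(x)
  starts <- seq(1L, n, by = w)
  centers <- pmin(starts + (w - 1) / 2, n)
  vals <- vapply(starts, function(s) {
    quantile(x[s:min(s + w - 1L, n)], probs = p, names = FALSE)
  }, numeric(1))
  if (length(vals) == 1L) return(rep(vals, n))
  approx(centers, vals, xout = seq_len(n), rule = 2)$y
}
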