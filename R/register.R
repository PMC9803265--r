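#' Rigid registration of ROI masks across recording sessions
#'
#' Estimates the rigid transform (rotation about the image centre plus
#' integer translation) that maximizes the intensity correlation between a
#' reference image and a moving image, applies it to the moving ROI mask,
#' and matches transformed ROI centroids to reference centroids by nearest
#' neighbour within `match_radius`, yielding a cell-identity map across
#' sessions. Rotation is searched on a grid (coarse step `angle_step`,
#' then a 5x finer local refinement); translation by FFT cross-correlation.
#'
#' @param reference,moving Intensity images (e.g. maximum-intensity
#'   projections) as matrices, or `roi_mask` objects (their binarized
#'   label images are then used as intensity).
#' @param moving_mask The `roi_mask` to carry along (defaults to `moving`
#'   when that is a mask).
#' @param reference_mask Reference `roi_mask` for centroid matching
#'   (defaults to `reference` when that is a mask).
#' @param max_angle Largest rotation searched, degrees.
#' @param angle_step Coarse rotation grid step, degrees.
#' @param match_radius Centroid matching radius, pixels.
#' @param cor_floor Registration fails (error) if the best achievable
#'   intensity correlation is below this floor.
#'
#' @return A list of class `registration`: `transform` (list `angle`
#'   degrees, `dy`, `dx` pixels, `correlation`), `aligned_mask` (the
#'   transformed `roi_mask`, when a mask was supplied), `cell_map`
#'   (tibble `moving_roi`, `reference_roi`, `distance`).
#' @export
register_mask <- function(reference, moving, moving_mask = NULL,
                          reference_mask = NULL, max_angle = 6,
                          angle_step = 0.5, match_radius = 10,
                          cor_floor = 0.2) {
  if (inherits(reference, "roi_mask")) {
    reference_mask <- reference_mask %||% reference
    reference <- (reference$label_image > 0) * 1
  }
  if (inherits(moving, "roi_mask")) {
    moving_mask <- moving_mask %||% moving
    moving <- (moving$label_image > 0) * 1
  }
  if (!all(dim(reference) == dim(moving))) {
    abort("Reference and moving images must share dimensions.")
  }

  search <- function(angles, best) {
    for (a in angles) {
      rot <- rigid_transform_image(moving, a, 0, 0)
      fit <- best_translation(reference, rot)
      if (fit$cor > best$cor) best <- list(angle = a, dy = fit$dy,
                                           dx = fit$dx, cor = fit$cor)
    }
    best
  }
  coarse <- seq(-max_angle, max_angle, by = angle_step)
  coarse <- coarse[order(abs(coarse))]       # ties resolve to smaller rotations
  best <- search(coarse, list(angle = 0, dy = 0, dx = 0, cor = -Inf))
  fine <- seq(best$angle - angle_step, best$angle + angle_step,
              by = angle_step / 5)
  fine <- fine[order(abs(fine))]
  best <- search(setdiff(fine, best$angle), best)
  if (best$cor < cor_floor) {
    abort(sprintf("Registration failed: best correlation %.3f below floor %.2f.",
                  best$cor, cor_floor))
  }

  aligned_mask <- NULL
  cell_map <- tibble(moving_roi = integer(), reference_roi = integer(),
                     distance = double())
  if (!is.null(moving_mask)) {
    lab <- rigid_transform_image(moving_mask$label_image, best$angle,
                                 best$dy, best$dx)
    ctr <- (dim(lab) + 1) / 2
    th <- best$angle * pi / 180
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    pts <- as.matrix(moving_mask$rois[, c("row", "col")]) + 1  # 1-based
    new_pts <- t(rot %*% (t(pts) - ctr) + ctr + c(best$dy, best$dx))
    rois <- mutate(moving_mask$rois, row = new_pts[, 1] - 1,
                   col = new_pts[, 2] - 1)
    aligned_mask <- structure(list(label_image = lab, rois = rois),
                              class = "roi_mask")
    if (!is.null(reference_mask) && nrow(reference_mask$rois) > 0 &&
        nrow(rois) > 0) {
      cell_map <- match_centroids(rois, reference_mask$rois, match_radius)
    }
  }
  structure(list(transform = list(angle = best$angle, dy = best$dy,
                                  dx = best$dx, correlation = best$cor),
                 aligned_mask = aligned_mask, cell_map = cell_map),
            class = "registration")
}

#' @export
print.registration <- function(x, ...) {
  cat(sprintf("<registration> angle %.2f deg, shift (%d, %d) px, r = %.3f; %d cells mapped\n",
              x$transform$angle, x$transform$dy, x$transform$dx,
              x$transform$correlation, nrow(x$cell_map)))
  invisible(x)
}

# Nearest-neighbour rigid warp: rotate about the image centre by `angle`
# degrees, then shift by (dy, dx) pixels. Works for label images too.
rigid_transform_image <- function(img, angle, dy, dx) {
  nr <- nrow(img); nc <- ncol(img)
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  th <- angle * pi / 180
  # inverse map: output pixel -> source pixel
  rr <- rep(seq_len(nr), times = nc) - ctr[1] - dy
  cc <- rep(seq_len(nc), each = nr) - ctr[2] - dx
  sr <- round(cos(th) * rr + sin(th) * cc + ctr[1])
  sc <- round(-sin(th) * rr + cos(th) * cc + ctr[2])
  ok <- sr >= 1 & sr <= nr & sc >= 1 & sc <= nc
  out <- img
  out[] <- 0
  out[ok] <- img[cbind(sr[ok], sc[ok])]
  out
}

# Best integer translation via FFT cross-correlation, scored by Pearson
# correlation of the circularly shifted images.
best_translation <- function(ref, mov) {
  a <- ref - mean(ref)
  b <- mov - mean(mov)
  cc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE)) / length(a)
  peak <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  wrap <- function(k, n) ifelse(k - 1 > n / 2, k - 1 - n, k - 1)
  dy <- unname(wrap(peak[1], nrow(ref)))
  dx <- unname(wrap(peak[2], ncol(ref)))
  denom <- sqrt(sum(a^2) * sum(b^2))
  list(dy = dy, dx = dx,
       cor = if (denom > 0) max(cc) / denom else 0)
}

# Greedy mutual nearest-neighbour centroid matching within a radius.
match_centroids <- function(moving_rois, reference_rois, radius) {
  mv <- as.matrix(moving_rois[, c("row", "col")])
  rf <- as.matrix(reference_rois[, c("row", "col")])
  d <- outer(rowSums(mv^2), rowSums(rf^2), "+") - 2 * mv %*% t(rf)
  d <- sqrt(pmax(d, 0))
  cand <- which(d <= radius, arr.ind = TRUE)
  if (!nrow(cand)) {
    return(tibble(moving_roi = integer(), reference_roi = integer(),
                  distance = double()))
  }
  ord <- order(d[cand])
  cand <- cand[ord, , drop = FALSE]
  used_m <- used_r <- integer(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!(cand[i, 1] %in% used_m) && !(cand[i, 2] %in% used_r)) {
      keep[i] <- TRUE
      used_m <- c(used_m, cand[i, 1])
      used_r <- c(used_r, cand[i, 2])
    }
  }
  cand <- cand[keep, , drop = FALSE]
  tibble(moving_roi = moving_rois$roi[cand[, 1]],
         reference_roi = reference_rois$roi[cand[, 2]],
         distance = d[cand])
}
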