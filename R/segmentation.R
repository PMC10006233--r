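#' Weighted DBSCAN over positive-weight pixels
#'
#' Density-based clustering of image pixels where each pixel carries a sample
#' weight (its modified intensity). A pixel is a core point iff the sum of
#' weights over all positive-weight pixels at manhattan distance `<= eps`
#' (itself included) reaches `min_weight`. Clusters are maximal
#' density-connected sets of core points; a non-core pixel within `eps` of a
#' core pixel joins the cluster of the nearest core point (ties broken toward
#' the lowest cluster id). Remaining pixels are noise (label 0). Cluster ids
#' are assigned deterministically by the row-major position of each cluster's
#' first member pixel, so the result does not depend on any input ordering.
#'
#' @param weights Numeric H x W matrix; pixels with weight > 0 are the input
#'   points, everything else is background.
#' @param eps Neighborhood radius in pixels, manhattan metric (default 2).
#' @param min_weight Minimum neighborhood weight sum for a core point
#'   (default 4; equals classical `min_samples` when all weights are 1).
#' @return Integer label matrix (0 = background/noise, 1..K = clusters).
#' @export
weighted_dbscan <- function(weights, eps = 2, min_weight = 4) {
  if (!is.matrix(weights)) stop("weights must be a 2-D matrix")
  stopifnot(eps > 0, min_weight > 0)
  if (any(weights < 0)) stop("weights must be nonnegative")
  .dbscan_grid_cpp(weights, eps, min_weight)
}

#' Detect local intensity maxima on a background-corrected channel
#'
#' A pixel is a maximum candidate if its value is positive and not smaller
#' than any of its 8 neighbors (a `(2 * footprint_radius + 1)^2` neighborhood
#' in general). Connected plateaus of equal-valued candidates are merged and
#' represented by their lexicographically smallest (row, col) coordinate.
#'
#' @param img_bc Background-corrected numeric matrix or [channel_image()].
#' @param footprint_radius Neighborhood radius in pixels (default 1, i.e. the
#'   3 x 3 footprint).
#' @return Integer matrix with columns `row`, `col` (0-based), one row per
#'   maximum, ordered lexicographically.
#' @export
detect_local_maxima <- function(img_bc, footprint_radius = 1) {
  m <- if (inherits(img_bc, "channel_image")) img_bc$data else img_bc
  if (!is.matrix(m)) stop("maxima detection expects a 2-D image")
  H <- nrow(m); W <- ncol(m)
  r <- as.integer(footprint_radius)
  p <- matrix(-Inf, H + 2L * r, W + 2L * r)
  p[r + (1:H), r + (1:W)] <- m
  nmax <- matrix(-Inf, H, W)
  for (dr in -r:r) for (dc in -r:r) {
    if (dr == 0L && dc == 0L) next
    nmax <- pmax(nmax, p[r + (1:H) + dr, r + (1:W) + dc, drop = FALSE])
  }
  cand <- (m > 0) & (m >= nmax)
  if (!any(cand)) return(cbind(row = integer(0), col = integer(0)))
  # merge plateaus: connected candidates are equal-valued by construction
  comp <- .label_components_cpp(cand, 8L)
  idx <- which(comp > 0)
  rows <- (idx - 1L) %% H
  cols <- (idx - 1L) %/% H
  # lexicographically smallest (row, col) per component
  ord <- order(comp[idx], rows, cols)
  first <- !duplicated(comp[idx][ord])
  out <- cbind(row = rows[ord][first], col = cols[ord][first])
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' Split clusters containing several local maxima
#'
#' Clusters holding two or more detected maxima are replaced by one cluster
#' per maximum; each pixel of the original cluster joins its nearest
#' contained maximum (Euclidean distance, ties broken toward the
#' lexicographically smaller maximum coordinate). Clusters with zero or one
#' contained maxima are left unchanged. Labels are re-compacted to 1..K'
#' ordered by each cluster's first member pixel in row-major order. The
#' union of labeled pixels is conserved.
#'
#' @param labels Integer label matrix from [weighted_dbscan()].
#' @param maxima Integer matrix with 0-based `row`, `col` columns from
#'   [detect_local_maxima()].
#' @return Integer label matrix with split clusters.
#' @export
split_clusters <- function(labels, maxima) {
  if (!is.matrix(labels)) stop("labels must be a 2-D matrix")
  H <- nrow(labels); W <- ncol(labels)
  if (length(maxima) && (any(maxima < 0) || any(maxima[, 1] >= H) ||
                         any(maxima[, 2] >= W)))
    stop("maxima coordinates out of image bounds")
  out <- labels
  if (length(maxima)) {
    # sort maxima lexicographically so the tie rule is "first wins"
    maxima <- maxima[order(maxima[, 1], maxima[, 2]), , drop = FALSE]
    mlab <- labels[maxima[, 1] + 1L + H * maxima[, 2]]
    keep <- mlab > 0
    mlab <- mlab[keep]
    maxima <- maxima[keep, , drop = FALSE]
    counts <- table(mlab)
    multi <- as.integer(names(counts)[counts >= 2])
    if (length(multi)) {
      next_id <- max(labels) + 1L
      for (k in multi) {
        idx <- which(labels == k)
        prow <- (idx - 1L) %% H
        pcol <- (idx - 1L) %/% H
        mk <- maxima[mlab == k, , drop = FALSE]
        # squared Euclidean distance pixel x maximum
        d2 <- outer(prow, mk[, 1], `-`)^2 + outer(pcol, mk[, 2], `-`)^2
        assign <- max.col(-d2, ties.method = "first")
        new_ids <- next_id + seq_len(nrow(mk)) - 1L
        out[idx] <- new_ids[assign]
        next_id <- next_id + nrow(mk)
      }
    }
  }
  compact_labels(out)
}

# re-number labels to 1..K by row-major position of first member pixel
compact_labels <- function(labels) {
  idx <- which(labels > 0)
  if (!length(idx)) return(labels)
  H <- nrow(labels)
  rows <- (idx - 1L) %% H
  cols <- (idx - 1L) %/% H
  rowmajor <- rows * ncol(labels) + cols
  ids <- labels[idx]
  first <- vapply(split(rowmajor, ids), min, numeric(1))
  remap <- integer(max(ids))
  remap[as.integer(names(first))[order(first)]] <- seq_along(first)
  labels[idx] <- remap[ids]
  labels
}

#' Segment one channel into candidate marker-positive regions
#'
#' Runs the full per-channel segmentation: background subtraction, percentile
#' weight transform, weighted DBSCAN, local-maxima detection on the
#' background-corrected image, and maxima-based cluster splitting.
#'
#' @param channel Hot-pixel-cleaned numeric matrix or [channel_image()].
#' @param config A [pipeline_config()].
#' @return List with `labels` (final label map), `regions`
#'   (via [labelmap_to_regions()]), `weights`, `background_corrected`,
#'   `maxima`, and `n_clusters_pre_split`.
#' @export
segment_channel <- function(channel, config = pipeline_config()) {
  nm <- if (inherits(channel, "channel_image")) channel$name else NA_character_
  bc <- subtract_background(channel, config$blur_sigma)
  bcm <- if (inherits(bc, "channel_image")) bc$data else bc
  w <- compute_weights(bcm, config$low_percentile, config$high_percentile,
                       config$percentile_population)
  lab <- weighted_dbscan(w, config$dbscan_eps, config$dbscan_min_weight)
  mx <- detect_local_maxima(bcm, config$maxima_footprint_radius)
  lab2 <- split_clusters(lab, mx)
  list(labels = lab2,
       regions = labelmap_to_regions(lab2, marker = nm),
       weights = w,
       background_corrected = bcm,
       maxima = mx,
       n_clusters_pre_split = max(lab))
}
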