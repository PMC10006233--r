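#' Mean marker intensity over a cell's pixels
#'
#' Arithmetic mean of the channel values over the cell's (eroded) pixel set,
#' computed on the hot-pixel-cleaned raw channel.
#'
#' @param cell A region/cell with a non-empty 0-based `pixels` matrix.
#' @param channel Numeric matrix or [channel_image()] from the same ROI.
#' @return Mean intensity (counts).
#' @export
mean_intensity <- function(cell, channel) {
  m <- if (inherits(channel, "channel_image")) channel$data else channel
  if (is.null(cell$pixels) || nrow(cell$pixels) == 0)
    stop("cannot quantify a cell with an empty pixel set")
  if (any(cell$pixels[, 1] >= nrow(m)) || any(cell$pixels[, 2] >= ncol(m)))
    stop("cell pixels out of channel bounds")
  mean(m[cell$pixels[, 1] + 1L + nrow(m) * cell$pixels[, 2]])
}

#' Arcsinh transform with a cofactor
#'
#' The standard variance-stabilizing transform for cytometry intensities:
#' `asinh(x / cofactor) = log(x / cofactor + sqrt((x / cofactor)^2 + 1))`.
#'
#' @param x Numeric vector of intensities.
#' @param cofactor Positive divisor (default 5 counts).
#' @return Transformed values (unitless).
#' @export
arcsinh_transform <- function(x, cofactor = 5) {
  if (!is.numeric(cofactor) || length(cofactor) != 1 || cofactor <= 0)
    stop("arcsinh cofactor must be a positive number")
  asinh(x / cofactor)
}

#' Build the per-cell table for a set of segmented ROIs
#'
#' One row per cell carrying ROI metadata, cell type, eroded area, centroid,
#' and raw plus arcsinh-transformed mean intensities for every
#' quantification channel. Rows are ordered by (roi_id, cell_id).
#'
#' @param rois List of entries, each a list with elements `roi` (the
#'   [roi_image()]) and `cells` (typed, eroded, area-filtered regions).
#' @param config A [pipeline_config()]; supplies quantification channels and
#'   the arcsinh cofactor. Quantification uses hot-pixel-cleaned raw
#'   channels, so `rois[[i]]$roi` is expected to be already cleaned.
#' @return A `data.frame` with columns `roi_id`, `sample_id`, `group`,
#'   `cell_id`, `cell_type`, `area`, `centroid_row`, `centroid_col`, then
#'   `mean_<channel>` and `arcsinh_<channel>` per quantification channel.
#' @export
build_cell_table <- function(rois, config = pipeline_config()) {
  qch <- config$quantification_channels
  cols <- c("roi_id", "sample_id", "group", "cell_id", "cell_type", "area",
            "centroid_row", "centroid_col",
            paste0("mean_", qch), paste0("arcsinh_", qch))
  empty <- as.data.frame(setNames(
    c(list(character(0), character(0), character(0), integer(0),
           character(0), integer(0)),
      rep(list(numeric(0)), 2 + 2 * length(qch))), cols))
  if (!length(rois)) return(empty)
  out <- lapply(rois, function(entry) {
    roi <- entry$roi
    cells <- entry$cells
    if (!length(cells)) return(NULL)
    chans <- lapply(qch, function(nm) roi_channel(roi, nm))
    ids <- seq_along(cells)
    df <- data.frame(
      roi_id = roi$roi_id, sample_id = roi$sample_id, group = roi$group,
      cell_id = ids,
      cell_type = vapply(cells, `[[`, character(1), "cell_type"),
      area = vapply(cells, `[[`, integer(1), "area"),
      centroid_row = vapply(cells, function(cl) mean(cl$pixels[, 1]), numeric(1)),
      centroid_col = vapply(cells, function(cl) mean(cl$pixels[, 2]), numeric(1)),
      stringsAsFactors = FALSE)
    for (j in seq_along(qch)) {
      mi <- vapply(cells, mean_intensity, numeric(1), chans[[j]])
      df[[paste0("mean_", qch[j])]] <- mi
      df[[paste0("arcsinh_", qch[j])]] <-
        arcsinh_transform(mi, config$arcsinh_cofactor)
    }
    df
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (anyDuplicated(out[c("roi_id", "cell_id")]))
    stop("duplicate (roi_id, cell_id) in cell table")
  out[order(out$roi_id, out$cell_id), , drop = FALSE]
}
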