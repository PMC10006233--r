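#' @useDynLib imcseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile t.test cor rpois rlnorm rnorm runif setNames
#' @importFrom utils read.csv write.csv write.table packageVersion
NULL

# Coordinate convention used throughout: 0-based (row, col); row 0 is the top
# image row. Areas are pixel counts; 1 px corresponds to 1 um by default.

#' Construct a single-channel intensity image
#'
#' A `channel_image` wraps one H x W matrix of nonnegative, finite detector
#' counts together with its channel (marker) name.
#'
#' @param name Channel identifier, e.g. `"Vimentin"`.
#' @param data Numeric matrix of nonnegative finite intensities.
#' @return An object of class `channel_image` with elements `name` and `data`.
#' @export
channel_image <- function(name, data) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("channel data must be a numeric matrix (2-D image)")
  if (nrow(data) < 1L || ncol(data) < 1L)
    stop("channel image must have H >= 1 and W >= 1")
  if (any(!is.finite(data)) || any(data < 0))
    stop("channel intensities must be finite and >= 0")
  structure(list(name = as.character(name), data = data),
            class = "channel_image")
}

#' Construct a multi-channel ROI image
#'
#' Bundles the channel stack of one laser-ablated region of interest with its
#' identifiers and group label. All channels must share the same H x W shape
#' and have unique names.
#'
#' @param roi_id,sample_id Identifier strings.
#' @param group Group label (free string, e.g. `"HC-LN"` or `"CLL-LN"`).
#' @param channels List of [channel_image()] objects.
#' @param pixel_size_um Pixel edge length in micrometers (default 1).
#' @return An object of class `roi_image`.
#' @export
roi_image <- function(roi_id, sample_id, group, channels, pixel_size_um = 1) {
  if (!length(channels)) stop("an ROI needs at least one channel")
  channels <- lapply(channels, function(ch) {
    if (!inherits(ch, "channel_image")) stop("channels must be channel_image objects")
    ch
  })
  dims <- vapply(channels, function(ch) dim(ch$data), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all channels in an ROI must share the same H x W shape")
  nms <- vapply(channels, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("channel names must be unique within an ROI")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be positive")
  names(channels) <- nms
  structure(list(roi_id = as.character(roi_id),
                 sample_id = as.character(sample_id),
                 group = as.character(group),
                 pixel_size_um = pixel_size_um,
                 channels = channels),
            class = "roi_image")
}

#' @export
print.roi_image <- function(x, ...) {
  d <- dim(x$channels[[1]]$data)
  cat(sprintf("roi_image %s (sample %s, group %s): %d x %d px, channels: %s\n",
              x$roi_id, x$sample_id, x$group, d[1], d[2],
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Get a channel matrix from an ROI
#'
#' @param roi A [roi_image()].
#' @param name Channel name; an error names the channel if it is missing.
#' @return The channel's intensity matrix.
#' @export
roi_channel <- function(roi, name) {
  if (!name %in% names(roi$channels))
    stop(sprintf("required channel '%s' is missing from ROI '%s'", name, roi$roi_id))
  roi$channels[[name]]$data
}

#' Pipeline configuration
#'
#' Houses every numeric constant of the segmentation and quantification
#' procedure; no stage hard-codes a constant. Defaults are the reference
#' settings of the procedure: hot-pixel threshold 50 counts, background blur sigma 40 px,
#' weight percentiles 30 / 99.5, DBSCAN eps 2 px (manhattan) with minimum
#' neighborhood weight 4, three erosion passes, area bounds 10-800 px^2,
#' 30 percent overlap discard, arcsinh cofactor 5.
#'
#' `dbscan_leaf_size` is retained for completeness of the parameter set
#' but is a tree-search performance knob with no effect on DBSCAN output; it
#' is result-neutral and unused by the grid implementation.
#'
#' @param hot_pixel_threshold Counts by which a pixel must exceed its
#'   8-neighbor maximum to be replaced (default 50).
#' @param blur_sigma Gaussian blur sigma in px for background estimation.
#' @param low_percentile,high_percentile Percentiles (0-100) for the weight
#'   transform floor and ceiling.
#' @param dbscan_eps Neighborhood radius in px, manhattan metric.
#' @param dbscan_min_weight Minimum neighborhood weight sum for a core pixel.
#' @param dbscan_metric Fixed to `"manhattan"`.
#' @param dbscan_leaf_size Result-neutral search parameter, recorded only.
#' @param maxima_footprint_radius Neighborhood radius in px for local-maxima
#'   detection; a maximum must dominate a `(2r+1) x (2r+1)` window. The
#'   default of 4 px is about one cell radius at 1 um/px, so shot-noise
#'   fluctuations inside a single cell do not register as separate peaks;
#'   radius 1 (the bare 3 x 3 footprint) is available for noise-free data.
#' @param erosion_iterations Binary erosion passes with the 3 x 3 cross.
#' @param erosion_element `"cross"` (4-connected, default) or `"square"`.
#' @param min_area,max_area Inclusive area bounds in px^2 after erosion.
#' @param overlap_discard_fraction Vimentin regions overlapping CD31-positive
#'   pixels by strictly more than this fraction of their own area are
#'   discarded (default 0.30).
#' @param arcsinh_cofactor Divisor c in asinh(x / c) (default 5 counts).
#' @param segmentation_channels Channels to segment.
#' @param quantification_channels Channels to quantify per cell.
#' @param percentile_population `"all"` (default) computes weight percentiles
#'   over every pixel; `"nonzero"` over positive pixels only.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(hot_pixel_threshold = 50,
                            blur_sigma = 40,
                            low_percentile = 30,
                            high_percentile = 99.5,
                            dbscan_eps = 2,
                            dbscan_min_weight = 4,
                            dbscan_metric = "manhattan",
                            dbscan_leaf_size = 3,
                            maxima_footprint_radius = 4,
                            erosion_iterations = 3,
                            erosion_element = c("cross", "square"),
                            min_area = 10,
                            max_area = 800,
                            overlap_discard_fraction = 0.30,
                            arcsinh_cofactor = 5,
                            segmentation_channels = c("Vimentin", "CD31", "CD68"),
                            quantification_channels = c("LYN", "THBS1"),
                            percentile_population = c("all", "nonzero")) {
  erosion_element <- match.arg(erosion_element)
  percentile_population <- match.arg(percentile_population)
  dbscan_metric <- match.arg(dbscan_metric, "manhattan")
  stopifnot(hot_pixel_threshold >= 0, blur_sigma > 0,
            low_percentile >= 0, low_percentile < high_percentile,
            high_percentile <= 100,
            dbscan_eps > 0, dbscan_min_weight > 0,
            maxima_footprint_radius >= 1,
            erosion_iterations >= 0,
            min_area <= max_area, min_area >= 0,
            overlap_discard_fraction >= 0, overlap_discard_fraction <= 1,
            arcsinh_cofactor > 0)
  structure(list(hot_pixel_threshold = hot_pixel_threshold,
                 blur_sigma = blur_sigma,
                 low_percentile = low_percentile,
                 high_percentile = high_percentile,
                 dbscan_eps = dbscan_eps,
                 dbscan_min_weight = dbscan_min_weight,
                 dbscan_metric = dbscan_metric,
                 dbscan_leaf_size = dbscan_leaf_size,
                 maxima_footprint_radius = maxima_footprint_radius,
                 erosion_iterations = erosion_iterations,
                 erosion_element = erosion_element,
                 min_area = min_area,
                 max_area = max_area,
                 overlap_discard_fraction = overlap_discard_fraction,
                 arcsinh_cofactor = arcsinh_cofactor,
                 segmentation_channels = segmentation_channels,
                 quantification_channels = quantification_channels,
                 percentile_population = percentile_population),
            class = "pipeline_config")
}

# internal: regions as a list with marker name and 0-based pixel coordinates
new_region <- function(region_id, marker, pixels, shape) {
  # pixels: integer matrix, columns row/col, 0-based
  stopifnot(nrow(pixels) >= 1)
  structure(list(region_id = as.integer(region_id),
                 marker = marker,
                 pixels = pixels,
                 area = nrow(pixels),
                 shape = shape),
            class = "imc_region")
}

#' Convert a label map to a list of regions
#'
#' @param labels Integer matrix, 0 = background, ids 1..K.
#' @param marker Source channel name attached to each region.
#' @return List of regions ordered by id, each with 0-based `pixels`
#'   (two-column row/col matrix), `area`, and `marker`.
#' @export
labelmap_to_regions <- function(labels, marker = NA_character_) {
  shape <- dim(labels)
  idx <- which(labels > 0)
  if (!length(idx)) return(list())
  ids <- labels[idx]
  rows <- (idx - 1L) %% shape[1]
  cols <- (idx - 1L) %/% shape[1]
  ord <- split(seq_along(idx), ids)
  lapply(names(ord), function(k) {
    sel <- ord[[k]]
    new_region(as.integer(k), marker,
               cbind(row = rows[sel], col = cols[sel]), shape)
  })
}

# internal: region list -> label map
regions_to_labelmap <- function(regions, shape) {
  lab <- matrix(0L, shape[1], shape[2])
  for (rg in regions) {
    lab[rg$pixels[, 1] + 1L + shape[1] * rg$pixels[, 2]] <- rg$region_id
  }
  lab
}
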