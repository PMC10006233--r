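#' Run the full segmentation and quantification pipeline on one ROI
#'
#' Stage order: hot-pixel removal on every channel; per segmentation channel
#' background subtraction, weight transform, weighted DBSCAN, local-maxima
#' detection on the background-corrected image and cluster splitting;
#' CD31/Vimentin typing with the overlap-discard rule; binary erosion; area
#' filtering; per-cell mean intensity of the quantification channels on the
#' cleaned raw images and the arcsinh transform. Deterministic for a fixed
#' input and configuration.
#'
#' @param roi A [roi_image()] containing at least the segmentation and
#'   quantification channels.
#' @param config A [pipeline_config()].
#' @param verbose Log per-stage region counts (pre/post splitting, typing,
#'   erosion, area filter) via `message()`.
#' @return List with `cells` (cell-table rows for this ROI), `label_maps`
#'   (final per-marker label maps), `typed_regions` (pre-erosion), and
#'   `stage_counts` (auditable attrition per stage).
#' @export
run_pipeline <- function(roi, config = pipeline_config(), verbose = FALSE) {
  for (nm in unique(c(config$segmentation_channels,
                      config$quantification_channels)))
    roi_channel(roi, nm)  # errors early, naming any missing channel

  cleaned <- roi
  cleaned$channels <- lapply(roi$channels, remove_hot_pixels,
                             threshold = config$hot_pixel_threshold)

  segs <- lapply(config$segmentation_channels, function(nm)
    segment_channel(cleaned$channels[[nm]], config))
  names(segs) <- config$segmentation_channels
  label_maps <- lapply(segs, `[[`, "labels")

  vim <- if ("Vimentin" %in% names(segs)) segs[["Vimentin"]]$regions else list()
  cd31 <- if ("CD31" %in% names(segs)) segs[["CD31"]]$regions else list()
  other <- unlist(lapply(setdiff(names(segs), c("Vimentin", "CD31")),
                         function(nm) segs[[nm]]$regions), recursive = FALSE)
  typed <- assign_cell_types(vim, cd31, config$overlap_discard_fraction,
                             other_regions = other)

  eroded <- lapply(typed, erode_region,
                   iterations = config$erosion_iterations,
                   element = config$erosion_element)
  cells <- filter_by_area(eroded, config$min_area, config$max_area)

  stage_counts <- list(
    regions_pre_split = vapply(segs, `[[`, numeric(1), "n_clusters_pre_split"),
    regions_post_split = vapply(segs, function(s) length(s$regions), numeric(1)),
    typed = length(typed),
    discarded_by_overlap = length(vim) + length(cd31) + length(other) -
      length(typed),
    after_area_filter = length(cells))
  if (verbose) {
    message(sprintf(
      "ROI %s: regions pre-split %s | post-split %s | typed %d (overlap-discarded %d) | final cells %d",
      roi$roi_id,
      paste(stage_counts$regions_pre_split, collapse = "/"),
      paste(stage_counts$regions_post_split, collapse = "/"),
      stage_counts$typed, stage_counts$discarded_by_overlap,
      stage_counts$after_area_filter))
  }

  tab <- build_cell_table(list(list(roi = cleaned, cells = cells)), config)
  list(cells = tab, label_maps = label_maps, typed_regions = typed,
       stage_counts = stage_counts)
}

#' Run the pipeline over a cohort and build the pooled cell table
#'
#' @param rois List of [roi_image()] objects (or `generate_roi()` results,
#'   from which `$roi` is taken).
#' @param config A [pipeline_config()].
#' @param verbose Passed to [run_pipeline()].
#' @return Pooled cell table (`data.frame`) across all ROIs.
#' @export
run_cohort <- function(rois, config = pipeline_config(), verbose = FALSE) {
  tabs <- lapply(rois, function(r) {
    if (!inherits(r, "roi_image")) r <- r$roi
    run_pipeline(r, config, verbose = verbose)$cells
  })
  tabs <- tabs[vapply(tabs, nrow, integer(1)) > 0]
  if (!length(tabs))
    return(build_cell_table(list(), config))
  out <- do.call(rbind, c(tabs, list(make.row.names = FALSE)))
  out[order(out$roi_id, out$cell_id), , drop = FALSE]
}
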