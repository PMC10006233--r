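#' Assign lineage identities from marker-region overlap
#'
#' CD31-positive regions are endothelial cells. A Vimentin-positive region
#' whose overlap with the union of all CD31-positive pixels exceeds
#' `overlap_discard_fraction` of its own area (strictly more) is discarded
#' as a double-positive vessel profile; the remaining Vimentin regions are
#' fibroblasts. Regions of any other marker (e.g. CD68) pass through with
#' type `"unassigned"`.
#'
#' @param vimentin_regions,cd31_regions Region lists from
#'   [labelmap_to_regions()], from the same ROI (identical image shape).
#' @param overlap_discard_fraction Strict discard threshold (default 0.30).
#' @param other_regions Optional region list typed `"unassigned"`.
#' @return List of typed regions: each region gains `cell_type` and, for
#'   Vimentin regions, `cd31_overlap` (the overlap fraction). Discarded
#'   regions are dropped.
#' @export
assign_cell_types <- function(vimentin_regions, cd31_regions,
                              overlap_discard_fraction = 0.30,
                              other_regions = list()) {
  shapes <- lapply(c(vimentin_regions, cd31_regions, other_regions),
                   `[[`, "shape")
  if (length(shapes) > 1 &&
      !all(vapply(shapes, identical, logical(1), shapes[[1]])))
    stop("regions come from differently shaped images")

  endo <- lapply(cd31_regions, function(rg) {
    rg$cell_type <- "endothelial"
    rg
  })

  fibro <- list()
  if (length(vimentin_regions)) {
    shape <- vimentin_regions[[1]]$shape
    cd31_mask <- matrix(FALSE, shape[1], shape[2])
    for (rg in cd31_regions)
      cd31_mask[rg$pixels[, 1] + 1L + shape[1] * rg$pixels[, 2]] <- TRUE
    fibro <- lapply(vimentin_regions, function(rg) {
      ov <- sum(cd31_mask[rg$pixels[, 1] + 1L + shape[1] * rg$pixels[, 2]])
      frac <- ov / rg$area
      if (frac > overlap_discard_fraction) return(NULL)
      rg$cell_type <- "fibroblast"
      rg$cd31_overlap <- frac
      rg
    })
    fibro <- fibro[!vapply(fibro, is.null, logical(1))]
  }

  other <- lapply(other_regions, function(rg) {
    rg$cell_type <- "unassigned"
    rg
  })
  c(endo, fibro, other)
}

# erode a logical mask: `iterations` passes with a 3x3 structuring element,
# pixels outside the image border count as background
erode_mask <- function(mask, iterations,
                       element = c("cross", "square")) {
  element <- match.arg(element)
  offs <- if (element == "cross") {
    list(c(0L, 0L), c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else {
    as.list(data.frame(t(expand.grid(-1:1, -1:1))))
  }
  H <- nrow(mask); W <- ncol(mask)
  for (i in seq_len(iterations)) {
    if (!any(mask)) break
    p <- matrix(FALSE, H + 2L, W + 2L)
    p[2:(H + 1L), 2:(W + 1L)] <- mask
    out <- matrix(TRUE, H, W)
    for (o in offs)
      out <- out & p[(2:(H + 1L)) + o[1], (2:(W + 1L)) + o[2], drop = FALSE]
    mask <- out
  }
  mask
}

#' Erode a region's pixel mask
#'
#' Shrinks the cell area to avoid signal contamination from neighboring
#' cells: `iterations` passes of binary erosion with the 3 x 3 cross
#' (4-connected) structuring element by default. Pixels outside the image
#' border count as background, so regions touching the border erode there
#' too. May return a region with zero pixels.
#'
#' @param region A region (from [labelmap_to_regions()] or typed).
#' @param iterations Number of erosion passes (default 3).
#' @param element `"cross"` (default) or `"square"`.
#' @return The region with eroded `pixels` and updated `area` (possibly 0).
#' @export
erode_region <- function(region, iterations = 3,
                         element = c("cross", "square")) {
  element <- match.arg(element)
  stopifnot(iterations >= 0)
  shape <- region$shape
  px <- region$pixels
  if (iterations == 0 || nrow(px) == 0) return(region)
  # work in a padded bounding box; track image-border adjacency explicitly
  r0 <- min(px[, 1]); r1 <- max(px[, 1])
  c0 <- min(px[, 2]); c1 <- max(px[, 2])
  pad <- iterations
  # clip padding so box rows/cols map to true image rows/cols
  br0 <- max(r0 - pad, 0L); br1 <- min(r1 + pad, shape[1] - 1L)
  bc0 <- max(c0 - pad, 0L); bc1 <- min(c1 + pad, shape[2] - 1L)
  mask <- matrix(FALSE, br1 - br0 + 1L, bc1 - bc0 + 1L)
  mask[cbind(px[, 1] - br0 + 1L, px[, 2] - bc0 + 1L)] <- TRUE
  mask <- erode_mask(mask, iterations, element)
  idx <- which(mask)
  region$pixels <- cbind(row = (idx - 1L) %% nrow(mask) + br0,
                         col = (idx - 1L) %/% nrow(mask) + bc0)
  region$area <- nrow(region$pixels)
  region
}

#' Filter typed cells by eroded area
#'
#' Keeps cells whose area lies within `[min_area, max_area]` inclusive;
#' smaller or larger detections are discarded as likely false detections
#' (this also removes regions emptied by erosion).
#'
#' @param cells List of (typed, eroded) regions.
#' @param min_area,max_area Inclusive bounds in px^2 (defaults 10 and 800).
#' @return Filtered list.
#' @export
filter_by_area <- function(cells, min_area = 10, max_area = 800) {
  stopifnot(min_area <= max_area)
  keep <- vapply(cells, function(rg)
    rg$area >= min_area && rg$area <= max_area, logical(1))
  cells[keep]
}
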