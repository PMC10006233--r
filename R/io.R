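# TIFF + sidecar I/O. Multi-page TIFFs carry one page per channel; a small
# CSV manifest maps page indices to channel names and optionally carries ROI
# metadata. Reading goes through tiff::readTIFF; 32-bit float pages are
# written by a minimal in-package writer because the installed tiff writer
# only encodes integer sample formats.

#' Read an ROI from a multi-page TIFF and channel manifest
#'
#' The manifest is a two-column CSV without header: rows `(page_index,
#' channel_name)` with 1-based page indices, plus optional metadata rows
#' whose first field is one of `roi_id`, `sample_id`, `group`,
#' `pixel_size_um`.
#'
#' @param image_path Multi-page TIFF, one page per channel (uint8/16 or
#'   32-bit float).
#' @param channel_manifest_path Manifest CSV path.
#' @return A [roi_image()] with channels in manifest order.
#' @export
read_roi_tiff <- function(image_path, channel_manifest_path) {
  man <- read.csv(channel_manifest_path, header = FALSE,
                  stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(man) < 2) stop("manifest must have two columns")
  meta_keys <- c("roi_id", "sample_id", "group", "pixel_size_um")
  is_meta <- man[[1]] %in% meta_keys
  meta <- setNames(as.list(man[[2]][is_meta]), man[[1]][is_meta])
  chan <- man[!is_meta, , drop = FALSE]
  page_idx <- suppressWarnings(as.integer(chan[[1]]))
  if (any(is.na(page_idx)))
    stop("manifest channel rows must start with a numeric page index")
  chan_names <- chan[[2]]
  if (anyDuplicated(chan_names)) stop("duplicate channel names in manifest")

  pages <- read_tiff_pages(image_path)
  if (length(pages) != nrow(chan))
    stop(sprintf("TIFF has %d pages but manifest lists %d channels",
                 length(pages), nrow(chan)))
  if (any(page_idx < 1) || any(page_idx > length(pages)) ||
      anyDuplicated(page_idx))
    stop("manifest page indices must be a permutation of 1..n_pages")

  channels <- lapply(seq_along(page_idx), function(i) {
    m <- pages[[page_idx[i]]]
    if (length(dim(m)) == 3) m <- m[, , 1]
    channel_image(chan_names[i], m * 1.0)
  })
  roi_image(roi_id = meta$roi_id %||% "roi",
            sample_id = meta$sample_id %||% (meta$roi_id %||% "roi"),
            group = meta$group %||% "unknown",
            channels = channels,
            pixel_size_um = as.numeric(meta$pixel_size_um %||% 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# read all pages as raw counts: integer formats via as.is = TRUE (undoes the
# [0,1] scaling), float formats as stored (as.is is unsupported there)
read_tiff_pages <- function(path) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) {
                      if (grepl("floating point", conditionMessage(e)))
                        tiff::readTIFF(path, all = TRUE)
                      else stop(e)
                    })
  if (!is.list(pages)) list(pages) else pages
}

#' Write an ROI as a multi-page TIFF plus channel manifest
#'
#' @param roi A [roi_image()].
#' @param image_path Output TIFF path.
#' @param channel_manifest_path Output manifest CSV path.
#' @param encoding `"float32"` (lossless for real-valued counts; default) or
#'   `"uint16"` (integral counts up to 65535).
#' @return Invisibly, the two paths.
#' @export
write_roi_tiff <- function(roi, image_path, channel_manifest_path,
                           encoding = c("float32", "uint16")) {
  encoding <- match.arg(encoding)
  mats <- lapply(roi$channels, `[[`, "data")
  if (encoding == "float32") {
    write_float_tiff(mats, image_path)
  } else {
    if (any(vapply(mats, function(m) any(m > 65535), logical(1))))
      stop("uint16 encoding cannot store counts above 65535")
    tiff::writeTIFF(lapply(mats, function(m) round(m) / 65535), image_path,
                    bits.per.sample = 16L, compression = "none")
  }
  man <- rbind(
    data.frame(k = c("roi_id", "sample_id", "group", "pixel_size_um"),
               v = c(roi$roi_id, roi$sample_id, roi$group,
                     format(roi$pixel_size_um))),
    data.frame(k = as.character(seq_along(mats)), v = names(roi$channels)))
  write.table(man, channel_manifest_path, sep = ",", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(c(image_path, channel_manifest_path))
}

# Minimal uncompressed little-endian multi-page TIFF writer for 32-bit
# float single-sample (grayscale) images. readTIFF(as.is = TRUE) reads the
# values back exactly (within float32 precision).
write_float_tiff <- function(mats, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)                      # little-endian
  writeBin(42L, con, size = 2, endian = "little")     # magic
  # layout: [header 8] then per page: [pixel data][IFD]
  n <- length(mats)
  offs <- 8
  data_off <- ifd_off <- numeric(n)
  nbytes <- ifd_bytes <- numeric(n)
  n_entries <- 9
  for (i in seq_len(n)) {
    nbytes[i] <- length(mats[[i]]) * 4
    ifd_bytes[i] <- 2 + n_entries * 12 + 4
    data_off[i] <- offs
    ifd_off[i] <- offs + nbytes[i]
    offs <- offs + nbytes[i] + ifd_bytes[i]
  }
  writeBin(as.integer(ifd_off[1]), con, size = 4, endian = "little")
  tag <- function(id, type, count, value) {
    writeBin(as.integer(id), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3) { # SHORT packed into 4 bytes
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (i in seq_len(n)) {
    m <- mats[[i]]
    # pixel data, row-major (TIFF scanline order); force double storage so
    # writeBin emits IEEE float32, not int32 bit patterns
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
    writeBin(as.integer(n_entries), con, size = 2, endian = "little")
    tag(256, 4, 1, ncol(m))              # ImageWidth
    tag(257, 4, 1, nrow(m))              # ImageLength
    tag(258, 3, 1, 32)                   # BitsPerSample
    tag(259, 3, 1, 1)                    # Compression: none
    tag(262, 3, 1, 1)                    # Photometric: BlackIsZero
    tag(273, 4, 1, data_off[i])          # StripOffsets
    tag(278, 4, 1, nrow(m))              # RowsPerStrip
    tag(279, 4, 1, nbytes[i])            # StripByteCounts
    tag(339, 3, 1, 3)                    # SampleFormat: IEEE float
    next_ifd <- if (i < n) ifd_off[i + 1] else 0
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Write a label map as a TIFF mask
#'
#' Region ids are stored as pixel values (0 = background) in 16-bit pages;
#' maps with more than 65535 regions fall back to the 32-bit float encoding
#' (exact for integer ids below 2^24).
#'
#' @param labels Integer label matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_label_tiff <- function(labels, path) {
  k <- max(labels)
  if (k > 65535) {
    write_float_tiff(list(labels * 1.0), path)
  } else {
    tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L,
                    compression = "none")
  }
  invisible(path)
}

#' Read a label map written by [write_label_tiff()]
#'
#' @param path TIFF path.
#' @return Integer label matrix.
#' @export
read_label_tiff <- function(path) {
  m <- read_tiff_pages(path)[[1]]
  m <- round(m)
  storage.mode(m) <- "integer"
  m
}

#' Write pipeline outputs for a processed cohort
#'
#' Writes `cells.csv` (one row per cell), `comparisons.csv`, per-ROI
#' per-marker label masks (`mask_<roi>_<marker>.tif`), and a JSON run
#' manifest capturing the full configuration and package version.
#'
#' @param table Cell table from [build_cell_table()]/[run_cohort()].
#' @param comparisons `data.frame` of [compare_groups()] rows (or NULL).
#' @param label_maps Named list `roi_id` -> named list `marker` -> label map
#'   (or NULL).
#' @param out_dir Output directory (created if needed).
#' @param config The [pipeline_config()] used.
#' @return Named character vector of written paths.
#' @export
write_outputs <- function(table, comparisons = NULL, label_maps = NULL,
                          out_dir, config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cells = file.path(out_dir, "cells.csv"))
  write.csv(table, paths["cells"], row.names = FALSE)
  if (!is.null(comparisons)) {
    paths["comparisons"] <- file.path(out_dir, "comparisons.csv")
    write.csv(comparisons, paths["comparisons"], row.names = FALSE)
  }
  for (roi_id in names(label_maps)) {
    for (marker in names(label_maps[[roi_id]])) {
      p <- file.path(out_dir, sprintf("mask_%s_%s.tif", roi_id, marker))
      write_label_tiff(label_maps[[roi_id]][[marker]], p)
      paths[sprintf("mask_%s_%s", roi_id, marker)] <- p
    }
  }
  paths["manifest"] <- file.path(out_dir, "run_manifest.json")
  manifest <- list(package = "imcseg",
                   version = as.character(packageVersion("imcseg")),
                   config = unclass(config))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}

#' Re-load a pipeline configuration from a run manifest
#'
#' @param path `run_manifest.json` written by [write_outputs()].
#' @return A [pipeline_config()] identical to the one used for the run.
#' @export
read_run_manifest <- function(path) {
  manifest <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- manifest$config
  pipeline_config(
    hot_pixel_threshold = cfg$hot_pixel_threshold,
    blur_sigma = cfg$blur_sigma,
    low_percentile = cfg$low_percentile,
    high_percentile = cfg$high_percentile,
    dbscan_eps = cfg$dbscan_eps,
    dbscan_min_weight = cfg$dbscan_min_weight,
    dbscan_leaf_size = cfg$dbscan_leaf_size,
    maxima_footprint_radius = cfg$maxima_footprint_radius,
    erosion_iterations = cfg$erosion_iterations,
    erosion_element = cfg$erosion_element,
    min_area = cfg$min_area,
    max_area = cfg$max_area,
    overlap_discard_fraction = cfg$overlap_discard_fraction,
    arcsinh_cofactor = cfg$arcsinh_cofactor,
    segmentation_channels = cfg$segmentation_channels,
    quantification_channels = cfg$quantification_channels,
    percentile_population = cfg$percentile_population)
}

#' Read a fold-change table for concordance analysis
#'
#' @param path CSV with columns `id` and `log2fc` (header required).
#' @return `data.frame` with those columns.
#' @export
read_fold_changes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "log2fc") %in% names(df)))
    stop("fold-change CSV needs columns 'id' and 'log2fc'")
  df
}

#' Write or read a simulation/pipeline configuration as YAML
#'
#' Flat key-value files mirroring the configuration field names.
#'
#' @param config A [pipeline_config()] or [simulation_config()].
#' @param path YAML file path.
#' @return `write_config`: invisibly `path`. `read_pipeline_config`: a
#'   [pipeline_config()].
#' @export
write_config <- function(config, path) {
  # YAML serializes named atomic vectors as bare sequences, dropping the
  # names; emit them as maps instead so configs round-trip
  as_maps <- function(x) {
    if (is.list(x)) lapply(x, as_maps)
    else if (!is.null(names(x)) && length(x) > 1) as.list(x)
    else x
  }
  yaml::write_yaml(as_maps(unclass(config)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}
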