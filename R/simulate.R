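#' Simulation configuration for synthetic IMC ROIs
#'
#' Describes a synthetic tissue region emulating a Hyperion ablation: a
#' 750 x 750 px field (1 um/px) populated with blob-shaped cells of three
#' lineages. Fibroblasts express Vimentin plus the quantification markers
#' LYN and THBS1; endothelial cells express CD31, a weak Vimentin signal
#' (so the overlap-discard rule is exercised, mirroring Vimentin+CD31+
#' vessels), and LYN/THBS1; "other" cells express CD68 only. All cells
#' carry DNA signal. Per-cell peak amplitudes are lognormal around the
#' type/channel mean; group effects multiply amplitudes for chosen
#' (group, cell type, channel) combinations.
#'
#' @param image_size Integer (H, W) in px; a single number is square.
#' @param n_cells Cells per ROI (default 150).
#' @param min_separation Minimum center-to-center distance in px (default 15).
#' @param type_proportions Named fractions for fibroblast / endothelial /
#'   other; must sum to 1.
#' @param cell_radius_sigma Gaussian blob scale in px (default 4); blobs are
#'   truncated at 3 sigma.
#' @param amplitude_means Named list type -> named numeric vector of peak
#'   amplitudes (counts) per expressed channel.
#' @param amplitude_sdlog Lognormal sdlog of between-cell amplitude spread.
#' @param group_effects Nested named list group -> type -> channel ->
#'   multiplicative amplitude factor. Defaults emulate the expected
#'   directions: in CLL-LN, fibroblast LYN x 1.5 and THBS1 x 0.6.
#' @param background_level Mean background counts per pixel (default 0.3).
#' @param noise_model `"poisson"` (counts; default), `"gaussian"`, or
#'   `"none"`.
#' @param gaussian_sd Noise sd when `noise_model = "gaussian"`.
#' @param hot_pixel_rate Fraction of pixels spiked per channel (default 5e-5).
#' @param hot_pixel_magnitude Added counts per spike (default 150).
#' @param channels Channel names; the set the pipeline expects by default.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(image_size = c(750, 750),
                              n_cells = 150,
                              min_separation = 15,
                              type_proportions = c(fibroblast = 0.5,
                                                   endothelial = 0.3,
                                                   other = 0.2),
                              cell_radius_sigma = 4,
                              amplitude_means = list(
                                fibroblast = c(Vimentin = 25, LYN = 15,
                                               THBS1 = 15, DNA = 20),
                                endothelial = c(CD31 = 25, Vimentin = 8,
                                                LYN = 15, THBS1 = 15, DNA = 20),
                                other = c(CD68 = 25, DNA = 20)),
                              amplitude_sdlog = 0.35,
                              group_effects = list(
                                "CLL-LN" = list(
                                  fibroblast = c(LYN = 1.5, THBS1 = 0.6))),
                              background_level = 0.3,
                              noise_model = c("poisson", "gaussian", "none"),
                              gaussian_sd = 0.5,
                              hot_pixel_rate = 5e-5,
                              hot_pixel_magnitude = 150,
                              channels = c("Vimentin", "CD31", "CD68",
                                           "LYN", "THBS1", "DNA")) {
  noise_model <- match.arg(noise_model)
  # accept list forms (e.g. from YAML maps) for the named-vector fields
  type_proportions <- unlist(type_proportions)
  amplitude_means <- lapply(amplitude_means, unlist)
  if (length(image_size) == 1) image_size <- c(image_size, image_size)
  image_size <- unlist(image_size)
  stopifnot(all(image_size >= 1), n_cells >= 0, min_separation > 0,
            cell_radius_sigma > 0, background_level >= 0,
            hot_pixel_rate >= 0, hot_pixel_rate <= 1,
            hot_pixel_magnitude >= 0, amplitude_sdlog >= 0)
  if (abs(sum(type_proportions) - 1) > 1e-8)
    stop("type proportions must sum to 1")
  if (!all(names(amplitude_means) %in% names(type_proportions)))
    stop("amplitude_means types must match type_proportions")
  structure(list(image_size = as.integer(image_size), n_cells = n_cells,
                 min_separation = min_separation,
                 type_proportions = type_proportions,
                 cell_radius_sigma = cell_radius_sigma,
                 amplitude_means = amplitude_means,
                 amplitude_sdlog = amplitude_sdlog,
                 group_effects = group_effects,
                 background_level = background_level,
                 noise_model = noise_model, gaussian_sd = gaussian_sd,
                 hot_pixel_rate = hot_pixel_rate,
                 hot_pixel_magnitude = hot_pixel_magnitude,
                 channels = channels),
            class = "simulation_config")
}

# deterministic cell type counts: largest-remainder apportionment so the
# per-type count is an exact function of n_cells and the proportions
apportion_types <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  setNames(as.integer(base), names(props))
}

#' Generate one synthetic ROI with ground truth
#'
#' Places cells by rejection sampling under the minimum-separation
#' constraint, renders each as an isotropic Gaussian blob (truncated at
#' 3 sigma) on its type's channels with lognormal per-cell amplitudes times
#' the group effect, adds background and per-pixel noise, and injects hot
#' pixels at recorded coordinates. Fully reproducible from `seed` (one
#' generator per ROI).
#'
#' @param cfg A [simulation_config()].
#' @param group Group label, e.g. `"HC-LN"` or `"CLL-LN"`.
#' @param roi_id,sample_id Identifiers.
#' @param seed Integer seed for this ROI.
#' @return List with `roi` (a [roi_image()]) and `truth` (list with `cells`
#'   data.frame: cell, type, center_row/col 0-based, `amp_<channel>` true
#'   amplitudes; `masks`: per-marker true label maps, label = cell index,
#'   pixels within 2 sigma of the center; `hot_pixels`: per-channel 0-based
#'   spiked coordinates; and the `config`).
#' @export
generate_roi <- function(cfg, group = "HC-LN", roi_id = "roi1",
                         sample_id = roi_id, seed = 1) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(as.integer(seed))
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  margin <- ceiling(3 * cfg$cell_radius_sigma)
  n <- cfg$n_cells

  # rejection-sample centers (0-based, kept `margin` off the border)
  centers <- matrix(numeric(0), 0, 2)
  attempts <- 0L
  max_attempts <- max(200L * n, 1000L)
  while (nrow(centers) < n) {
    if (attempts >= max_attempts)
      stop("rejection sampling failed: cell density too high for min_separation")
    attempts <- attempts + 1L
    cand <- c(runif(1, margin, H - 1 - margin), runif(1, margin, W - 1 - margin))
    if (nrow(centers) == 0 ||
        min(sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)) >=
          cfg$min_separation)
      centers <- rbind(centers, cand)
  }

  counts <- apportion_types(n, cfg$type_proportions)
  types <- if (n > 0) sample(rep(names(counts), counts)) else character(0)

  # per-cell amplitudes (lognormal around the type mean, times group effect)
  amp <- matrix(0, n, length(cfg$channels),
                dimnames = list(NULL, cfg$channels))
  for (i in seq_len(n)) {
    mus <- cfg$amplitude_means[[types[i]]]
    for (ch in names(mus)) {
      eff <- 1
      ge <- cfg$group_effects[[group]]
      gv <- if (is.null(ge)) NULL else ge[[types[i]]]
      if (!is.null(gv) && ch %in% names(gv)) eff <- as.numeric(gv[[ch]])
      amp[i, ch] <- rlnorm(1, meanlog = log(mus[ch] * eff),
                           sdlog = cfg$amplitude_sdlog)
    }
  }

  # render signal per channel
  sig <- lapply(cfg$channels, function(ch) matrix(0, H, W))
  names(sig) <- cfg$channels
  trunc_r <- ceiling(3 * cfg$cell_radius_sigma)
  s2 <- 2 * cfg$cell_radius_sigma^2
  for (i in seq_len(n)) {
    r0 <- max(floor(centers[i, 1]) - trunc_r, 0)
    r1 <- min(floor(centers[i, 1]) + trunc_r + 1, H - 1)
    c0 <- max(floor(centers[i, 2]) - trunc_r, 0)
    c1 <- min(floor(centers[i, 2]) + trunc_r + 1, W - 1)
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - centers[i, 1])^2, (cc - centers[i, 2])^2, `+`)
    blob <- exp(-d2 / s2)
    blob[d2 > trunc_r^2] <- 0
    for (ch in names(cfg$amplitude_means[[types[i]]])) {
      sig[[ch]][rr + 1, cc + 1] <- sig[[ch]][rr + 1, cc + 1] +
        amp[i, ch] * blob
    }
  }

  # background, noise, hot pixels
  hot <- list()
  for (ch in cfg$channels) {
    lam <- sig[[ch]] + cfg$background_level
    img <- switch(cfg$noise_model,
      poisson = matrix(rpois(H * W, lam), H, W),
      gaussian = pmax(lam + matrix(rnorm(H * W, 0, cfg$gaussian_sd), H, W), 0),
      none = lam)
    nhot <- rpois(1, cfg$hot_pixel_rate * H * W)
    if (nhot > 0) {
      idx <- sample.int(H * W, nhot)
      img[idx] <- img[idx] + cfg$hot_pixel_magnitude
      hot[[ch]] <- cbind(row = (idx - 1L) %% H, col = (idx - 1L) %/% H)
    } else {
      hot[[ch]] <- cbind(row = integer(0), col = integer(0))
    }
    sig[[ch]] <- img
  }

  # truth label masks: disk of radius 2 sigma per cell, label = cell index
  mask_r <- 2 * cfg$cell_radius_sigma
  lineage <- c(fibroblast = "Vimentin", endothelial = "CD31", other = "CD68")
  masks <- lapply(unique(lineage), function(ch) matrix(0L, H, W))
  names(masks) <- unique(lineage)
  for (i in seq_len(n)) {
    ch <- lineage[[types[i]]]
    r0 <- max(floor(centers[i, 1] - mask_r), 0)
    r1 <- min(ceiling(centers[i, 1] + mask_r), H - 1)
    c0 <- max(floor(centers[i, 2] - mask_r), 0)
    c1 <- min(ceiling(centers[i, 2] + mask_r), W - 1)
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - centers[i, 1])^2, (cc - centers[i, 2])^2, `+`)
    sub <- masks[[ch]][rr + 1, cc + 1]
    sub[d2 <= mask_r^2] <- i
    masks[[ch]][rr + 1, cc + 1] <- sub
  }

  cells <- data.frame(cell = seq_len(n),
                      type = types,
                      center_row = if (n > 0) centers[, 1] else numeric(0),
                      center_col = if (n > 0) centers[, 2] else numeric(0),
                      stringsAsFactors = FALSE)
  for (ch in cfg$channels) cells[[paste0("amp_", ch)]] <- amp[, ch]

  roi <- roi_image(roi_id, sample_id, group,
                   lapply(cfg$channels, function(ch)
                     channel_image(ch, sig[[ch]])))
  list(roi = roi,
       truth = list(cells = cells, masks = masks, hot_pixels = hot,
                    config = cfg, seed = as.integer(seed)))
}

#' Generate a two-group cohort of synthetic ROIs
#'
#' Independent ROIs with per-ROI seeds derived as `base_seed + index`, so a
#' cohort is reproducible without inter-ROI correlation. Group effects from
#' the configuration are applied by group label.
#'
#' @param cfg A [simulation_config()].
#' @param groups Named integer vector: label -> number of ROIs.
#' @param base_seed Integer; ROI i uses seed `base_seed + i`.
#' @return List of `generate_roi()` results, one per ROI; names are roi ids
#'   `<group>_roi<j>`.
#' @export
generate_cohort <- function(cfg, groups = c("HC-LN" = 9, "CLL-LN" = 12),
                            base_seed = 1) {
  stopifnot(length(groups) >= 1, all(groups >= 1))
  out <- list()
  i <- 0L
  for (g in names(groups)) {
    for (j in seq_len(groups[[g]])) {
      i <- i + 1L
      id <- sprintf("%s_roi%d", g, j)
      out[[id]] <- generate_roi(cfg, group = g, roi_id = id, sample_id = id,
                                seed = base_seed + i)
    }
  }
  out
}

#' Evaluate segmentation against simulated ground truth
#'
#' Greedy one-to-one matching of predicted cell centroids to true centers by
#' ascending Euclidean distance; a pair matches iff the distance is at most
#' `match_radius` and the cell types agree. Precision, recall and F1 follow
#' from the matching; `intensity_recovery_correlation` is the Pearson
#' correlation, over matched cells, between the measured raw mean intensity
#' of `recovery_channel` and the true per-cell amplitude.
#'
#' @param predicted Cell-table rows ([build_cell_table()]) for the ROI(s)
#'   being scored; must carry `centroid_row`/`centroid_col` and `cell_type`.
#' @param truth Truth object from [generate_roi()] (or a list of them for a
#'   cohort, in the same order as the predicted `roi_id`s).
#' @param match_radius Maximum matching distance in px (default 5).
#' @param cell_types Types entering the evaluation (default fibroblast and
#'   endothelial; "other" cells are untyped by the pipeline).
#' @param recovery_channel Channel for intensity recovery (default `"LYN"`).
#' @return List with `precision`, `recall`, `f1`, `n_matched`,
#'   `intensity_recovery_correlation`.
#' @export
evaluate_segmentation <- function(predicted, truth, match_radius = 5,
                                  cell_types = c("fibroblast", "endothelial"),
                                  recovery_channel = "LYN") {
  stopifnot(match_radius > 0)
  truths <- if (!is.null(truth$cells)) list(truth) else truth
  roi_ids <- unique(predicted$roi_id)
  if (length(truths) > 1 && length(roi_ids) != length(truths))
    stop("number of truth objects must match number of predicted ROIs")

  tp <- 0L; npred <- 0L; ntrue <- 0L
  meas <- numeric(0); tru <- numeric(0)
  for (k in seq_along(truths)) {
    tc <- truths[[k]]$cells
    tc <- tc[tc$type %in% cell_types, , drop = FALSE]
    pc <- if (length(truths) > 1) {
      predicted[predicted$roi_id == roi_ids[k], , drop = FALSE]
    } else predicted
    pc <- pc[pc$cell_type %in% cell_types, , drop = FALSE]
    npred <- npred + nrow(pc); ntrue <- ntrue + nrow(tc)
    if (!nrow(tc) || !nrow(pc)) next
    d <- sqrt(outer(pc$centroid_row, tc$center_row, `-`)^2 +
              outer(pc$centroid_col, tc$center_col, `-`)^2)
    type_ok <- outer(pc$cell_type, tc$type, `==`)
    d[!type_ok | d > match_radius] <- Inf
    # greedy ascending-distance one-to-one matching
    while (any(is.finite(d))) {
      ij <- arrayInd(which.min(d), dim(d))
      tp <- tp + 1L
      meas <- c(meas, pc[[paste0("mean_", recovery_channel)]][ij[1]])
      tru <- c(tru, tc[[paste0("amp_", recovery_channel)]][ij[2]])
      d[ij[1], ] <- Inf
      d[, ij[2]] <- Inf
    }
  }
  if (ntrue == 0L) stop("no ground-truth cells: recall is undefined")
  precision <- if (npred > 0) tp / npred else NA_real_
  recall <- tp / ntrue
  f1 <- if (is.na(precision) || precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  rho <- if (tp >= 3) cor(meas, tru) else NA_real_
  list(precision = precision, recall = recall, f1 = f1, n_matched = tp,
       intensity_recovery_correlation = rho)
}
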