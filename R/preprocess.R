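#' Remove hot pixels from a channel image
#'
#' A hot pixel is an isolated detector artifact whose count exceeds the
#' maximum of its 8 neighbors by more than `threshold`; it is replaced by
#' that neighbor maximum. The rule is applied in a single pass over the
#' original image (no cascading), so it is idempotent and never increases
#' any pixel value. At image borders only existing neighbors are considered.
#'
#' @param img Numeric matrix or [channel_image()].
#' @param threshold Nonnegative count difference (default 50).
#' @return Same type as `img`, cleaned.
#' @export
remove_hot_pixels <- function(img, threshold = 50) {
  is_ch <- inherits(img, "channel_image")
  m <- if (is_ch) img$data else img
  if (!is.matrix(m)) stop("hot-pixel removal expects a 2-D image")
  stopifnot(threshold >= 0)
  nmax <- neighbor_max8(m)
  hot <- (m - nmax) > threshold
  m[hot] <- nmax[hot]
  if (is_ch) channel_image(img$name, m) else m
}

# max over the 8-neighborhood, excluding the pixel itself; borders use
# existing neighbors only
neighbor_max8 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  p <- matrix(-Inf, H + 2L, W + 2L)
  p[2:(H + 1L), 2:(W + 1L)] <- m
  out <- matrix(-Inf, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    out <- pmax(out, p[(2:(H + 1L)) + dr, (2:(W + 1L)) + dc, drop = FALSE])
  }
  out
}

#' Subtract a Gaussian-blur background estimate
#'
#' Smooths uneven staining/ablation intensity by subtracting a heavy Gaussian
#' blur of the channel from the channel itself, clamping negative residuals
#' to zero. The blur uses a separable kernel truncated at 4 sigma and
#' symmetric-reflect boundary handling, so results are bit-reproducible.
#'
#' @param img Numeric matrix or [channel_image()].
#' @param sigma Blur scale in pixels (default 40).
#' @return Background-corrected nonnegative image, same type as `img`.
#' @export
subtract_background <- function(img, sigma = 40) {
  is_ch <- inherits(img, "channel_image")
  m <- if (is_ch) img$data else img
  if (!is.matrix(m)) stop("background subtraction expects a 2-D image")
  stopifnot(sigma > 0)
  out <- pmax(m - .gaussian_blur_cpp(m, sigma), 0)
  if (is_ch) channel_image(img$name, out) else out
}

#' Transform a background-corrected channel into DBSCAN pixel weights
#'
#' Pixels strictly below the `low_percentile` of the pixel population are set
#' to 0, values are clipped at the `high_percentile`, and the map is divided
#' by its new maximum so the largest weight is exactly 1. An all-zero image
#' yields an all-zero weight map (the division is guarded). Percentiles use
#' linear interpolation.
#'
#' @param img_bc Background-corrected nonnegative matrix or [channel_image()].
#' @param low_percentile,high_percentile Percentiles in 0-100
#'   (defaults 30 and 99.5).
#' @param population `"all"` (default) ranks every pixel including zeros;
#'   `"nonzero"` ranks only positive pixels.
#' @return Numeric matrix of weights in \[0, 1\].
#' @export
compute_weights <- function(img_bc, low_percentile = 30,
                            high_percentile = 99.5,
                            population = c("all", "nonzero")) {
  population <- match.arg(population)
  m <- if (inherits(img_bc, "channel_image")) img_bc$data else img_bc
  if (!is.matrix(m)) stop("weight transform expects a 2-D image")
  stopifnot(low_percentile >= 0, high_percentile <= 100,
            low_percentile < high_percentile)
  pop <- if (population == "all") as.vector(m) else m[m > 0]
  if (!length(pop)) return(matrix(0, nrow(m), ncol(m)))
  pl <- unname(quantile(pop, low_percentile / 100, type = 7))
  ph <- unname(quantile(pop, high_percentile / 100, type = 7))
  v <- pmin(m, ph)
  v[m < pl] <- 0
  mx <- max(v)
  if (mx > 0) v / mx else v * 0
}
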