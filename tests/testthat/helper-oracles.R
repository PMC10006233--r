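# Independent brute-force oracles. These deliberately share no code with the
# package: dense loops, explicit formulas, naive O(n^2) searches.

# dense 2-D convolution with the truncated Gaussian kernel and symmetric
# reflection (d c b a | a b c d) at the borders
oracle_gaussian_blur <- function(m, sigma) {
  r <- ceiling(4 * sigma)
  k1 <- exp(-((-r:r)^2) / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  H <- nrow(m); W <- ncol(m)
  fold <- function(i, n) { # 0-based symmetric reflection
    p <- 2 * n
    i <- i %% p
    i[i < 0] <- i[i < 0] + p
    ifelse(i < n, i, p - 1 - i)
  }
  out <- matrix(0, H, W)
  for (a in seq_len(H)) for (b in seq_len(W)) {
    rr <- fold((a - 1) + (-r:r), H) + 1
    cc <- fold((b - 1) + (-r:r), W) + 1
    out[a, b] <- sum(K * m[rr, cc])
  }
  out
}

# linear-interpolation percentile computed from first principles
oracle_percentile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p / 100 + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# three-step weight transform: zero below pL (strict), clip at pH, normalize
oracle_weights <- function(m, low = 30, high = 99.5) {
  pl <- oracle_percentile(as.vector(m), low)
  ph <- oracle_percentile(as.vector(m), high)
  v <- pmin(m, ph)
  v[m < pl] <- 0
  if (max(v) > 0) v / max(v) else v * 0
}

# O(n^2) weighted DBSCAN over a point list (0-based r, c, weight w);
# returns per-point labels (0 = noise)
oracle_dbscan_points <- function(pts, eps, min_weight) {
  n <- nrow(pts)
  if (!n) return(integer(0))
  D <- abs(outer(pts$r, pts$r, `-`)) + abs(outer(pts$c, pts$c, `-`))
  core <- vapply(seq_len(n), function(i)
    sum(pts$w[D[i, ] <= eps]) >= min_weight, logical(1))
  lab <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || lab[i] != 0L) next
    k <- k + 1L
    lab[i] <- k
    frontier <- i
    while (length(frontier)) {
      j <- frontier[1]
      frontier <- frontier[-1]
      nb <- which(core & D[j, ] <= eps & lab == 0L)
      lab[nb] <- k
      frontier <- c(frontier, nb)
    }
  }
  for (i in which(!core)) {
    cand <- which(core & D[i, ] <= eps)
    if (length(cand)) {
      dmin <- min(D[i, cand])
      lab[i] <- min(lab[cand[D[i, cand] == dmin]])
    }
  }
  lab
}

# run the point oracle on a weight matrix, returning a label matrix; points
# are scanned in row-major order so cluster ids (which the border tie rule
# consults) follow the first core pixel in row-major order, as the contract
# states
oracle_dbscan_map <- function(w, eps, min_weight) {
  idx <- which(w > 0)
  H <- nrow(w)
  pts <- data.frame(r = (idx - 1) %% H, c = (idx - 1) %/% H, w = w[idx])
  ord <- order(pts$r, pts$c)
  pts <- pts[ord, ]
  lab <- matrix(0L, H, ncol(w))
  lab[idx[ord]] <- oracle_dbscan_points(pts, eps, min_weight)
  lab
}

# TRUE iff two label maps agree up to a bijective relabeling (0 fixed)
labels_equivalent <- function(a, b) {
  if (!identical(dim(a), dim(b))) return(FALSE)
  if (!identical(a > 0, b > 0)) return(FALSE)
  idx <- which(a > 0)
  key <- paste(a[idx], b[idx])
  map <- unique(cbind(a[idx], b[idx])[!duplicated(key), , drop = FALSE])
  !anyDuplicated(map[, 1]) && !anyDuplicated(map[, 2])
}

# brute-force binary erosion of a full-image mask
oracle_erode <- function(mask, iterations, offsets) {
  H <- nrow(mask); W <- ncol(mask)
  for (it in seq_len(iterations)) {
    out <- mask
    for (a in seq_len(H)) for (b in seq_len(W)) {
      if (!mask[a, b]) next
      for (o in offsets) {
        aa <- a + o[1]; bb <- b + o[2]
        if (aa < 1 || aa > H || bb < 1 || bb > W || !mask[aa, bb]) {
          out[a, b] <- FALSE
          break
        }
      }
    }
    mask <- out
  }
  mask
}
cross_offsets <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))

# average-rank Spearman computed as rank-then-Pearson from first principles
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v) == v[i]))
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# connected-component count by flood fill (8-connectivity)
oracle_n_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  n <- 0L
  for (a in seq_len(H)) for (b in seq_len(W)) {
    if (!mask[a, b] || seen[a, b]) next
    n <- n + 1L
    frontier <- list(c(a, b))
    seen[a, b] <- TRUE
    while (length(frontier)) {
      p <- frontier[[1]]
      frontier <- frontier[-1]
      for (da in -1:1) for (db in -1:1) {
        aa <- p[1] + da; bb <- p[2] + db
        if (aa < 1 || aa > H || bb < 1 || bb > W) next
        if (mask[aa, bb] && !seen[aa, bb]) {
          seen[aa, bb] <- TRUE
          frontier <- c(frontier, list(c(aa, bb)))
        }
      }
    }
  }
  n
}

# render an isotropic Gaussian blob (truncated at 3 sigma) on a zero image
render_blob <- function(H, W, center_row, center_col, amplitude, sigma) {
  rr <- matrix(0:(H - 1), H, W)
  cc <- matrix(rep(0:(W - 1), each = H), H, W)
  d2 <- (rr - center_row)^2 + (cc - center_col)^2
  blob <- amplitude * exp(-d2 / (2 * sigma^2))
  blob[d2 > (3 * sigma)^2] <- 0
  blob
}

# small typed-region fixture: a rectangular region on an empty image
make_region <- function(rows, cols, shape, marker = "Vimentin", id = 1L) {
  px <- as.matrix(expand.grid(row = rows, col = cols))
  structure(list(region_id = id, marker = marker,
                 pixels = cbind(row = px[, 1], col = px[, 2]),
                 area = nrow(px), shape = shape),
            class = "imc_region")
}
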