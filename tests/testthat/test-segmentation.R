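test_that("weighted DBSCAN handles empty, isolated and plus-shaped inputs", {
  expect_equal(weighted_dbscan(matrix(0, 5, 5)), matrix(0L, 5, 5))

  lone <- matrix(0, 7, 7)
  lone[4, 4] <- 1
  expect_equal(weighted_dbscan(lone, eps = 2, min_weight = 4),
               matrix(0L, 7, 7))

  plus <- matrix(0, 7, 7)
  plus[4, 4] <- plus[3, 4] <- plus[5, 4] <- plus[4, 3] <- plus[4, 5] <- 1
  lab <- weighted_dbscan(plus, eps = 2, min_weight = 4)
  expect_equal(sort(unique(as.vector(lab))), c(0L, 1L))
  expect_identical(lab > 0, plus > 0)
  expect_true(labels_equivalent(lab, oracle_dbscan_map(plus, 2, 4)))
})

test_that("weighted DBSCAN agrees with the brute-force oracle on random weight maps", {
  set.seed(61)
  for (i in 1:50) {
    w <- matrix(0, 16, 16)
    n_on <- sample(10:60, 1)
    w[sample(256, n_on)] <- runif(n_on, 0.1, 1)
    eps <- sample(c(1, 2, 3), 1)
    mw <- sample(c(2, 4, 6) / 2, 1) * 2
    expect_true(labels_equivalent(weighted_dbscan(w, eps, mw),
                                  oracle_dbscan_map(w, eps, mw)))
  }
})

test_that("all-ones weights reduce to classical unweighted DBSCAN", {
  set.seed(71)
  for (i in 1:20) {
    w <- matrix(0, 14, 14)
    w[sample(196, 50)] <- 1
    expect_true(labels_equivalent(weighted_dbscan(w, 2, 4),
                                  oracle_dbscan_map(w, 2, 4)))
  }
})

test_that("adding a positive-weight point never unlabels an existing labeled pixel", {
  set.seed(81)
  for (i in 1:20) {
    w <- matrix(0, 12, 12)
    w[sample(144, 30)] <- runif(30, 0.2, 1)
    before <- weighted_dbscan(w, 2, 4)
    free <- which(w == 0)
    w[sample(free, 1)] <- runif(1, 0.2, 1)
    after <- weighted_dbscan(w, 2, 4)
    expect_true(all(after[before > 0] > 0))
  }
})

test_that("local maxima are found on blobs and plateaus are merged", {
  expect_equal(nrow(detect_local_maxima(matrix(0, 10, 10))), 0L)

  one <- render_blob(41, 41, 20, 20, 30, 4)
  mx <- detect_local_maxima(one)
  expect_equal(unname(mx), cbind(20L, 20L), ignore_attr = TRUE)

  two <- render_blob(60, 60, 15, 15, 30, 4) + render_blob(60, 60, 15, 45, 25, 4)
  mx2 <- detect_local_maxima(two)
  expect_equal(nrow(mx2), 2L)
  expect_equal(unname(mx2[, 2]), c(15, 45))

  # a flat positive plateau is one maximum, reported at its smallest corner
  plat <- matrix(0, 9, 9)
  plat[4:6, 4:6] <- 2
  mp <- detect_local_maxima(plat)
  expect_equal(unname(mp), cbind(3L, 3L), ignore_attr = TRUE)
})

test_that("a wider footprint suppresses shot-noise maxima inside one blob", {
  set.seed(91)
  noisy <- matrix(rpois(61 * 61, render_blob(61, 61, 30, 30, 25, 4) + 0.2),
                  61, 61)
  wide <- detect_local_maxima(noisy, footprint_radius = 4)
  narrow <- detect_local_maxima(noisy, footprint_radius = 1)
  expect_lt(nrow(wide), nrow(narrow))
})

test_that("cluster splitting assigns pixels to the nearest maximum with the tie rule", {
  # single maximum: partition unchanged
  lab <- matrix(0L, 5, 9)
  lab[3, ] <- 1L
  same <- split_clusters(lab, cbind(row = 2L, col = 4L))
  expect_equal(same, lab)

  # 1 x 9 line, maxima at columns 1 and 7; the tie at column 4 goes to the
  # lexicographically smaller maximum
  line <- matrix(1L, 1, 9)
  out <- split_clusters(line, cbind(row = c(0L, 0L), col = c(1L, 7L)))
  expect_equal(as.vector(out), c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L))

  # dumbbell from two touching blobs: boundary equals the brute-force
  # nearest-maximum assignment
  img <- render_blob(40, 60, 20, 20, 30, 4) + render_blob(40, 60, 20, 38, 30, 4)
  mask <- img > 1
  lab2 <- matrix(0L, 40, 60)
  lab2[mask] <- 1L
  mx <- cbind(row = c(20L, 20L), col = c(20L, 38L))
  got <- split_clusters(lab2, mx)
  idx <- which(mask)
  pr <- (idx - 1) %% 40
  pc <- (idx - 1) %/% 40
  d1 <- (pr - 20)^2 + (pc - 20)^2
  d2 <- (pr - 20)^2 + (pc - 38)^2
  want <- ifelse(d1 < d2 | (d1 == d2), 1L, 2L)
  expect_equal(got[idx], want)
})

test_that("splitting conserves the labeled pixel set and never merges clusters", {
  set.seed(101)
  for (i in 1:10) {
    w <- matrix(0, 20, 20)
    w[sample(400, 120)] <- runif(120, 0.3, 1)
    lab <- weighted_dbscan(w, 2, 4)
    mx <- cbind(row = sample(0:19, 4), col = sample(0:19, 4))
    out <- split_clusters(lab, mx)
    expect_identical(out > 0, lab > 0)
    expect_gte(max(out), max(lab))
    # no two originally distinct clusters share a new id
    pairs <- unique(cbind(lab[lab > 0], out[lab > 0]))
    expect_false(any(duplicated(pairs[, 2])))
  }
})
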