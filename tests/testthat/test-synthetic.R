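small_cfg <- function(...) {
  args <- utils::modifyList(
    list(image_size = 128, n_cells = 10, min_separation = 18), list(...))
  do.call(simulation_config, args)
}

test_that("the generator is deterministic and respects its constraints", {
  cfg <- small_cfg()
  a <- generate_roi(cfg, "HC-LN", "r1", seed = 5)
  b <- generate_roi(cfg, "HC-LN", "r1", seed = 5)
  expect_identical(a$roi, b$roi)
  expect_identical(a$truth$cells, b$truth$cells)

  c2 <- generate_roi(cfg, "HC-LN", "r1", seed = 6)
  expect_false(identical(a$roi, c2$roi))

  # nonnegative finite intensities, shared shapes
  for (ch in a$roi$channels) {
    expect_true(all(is.finite(ch$data)) && all(ch$data >= 0))
    expect_equal(dim(ch$data), c(128L, 128L))
  }
  # pairwise separation
  ctr <- a$truth$cells
  d <- as.matrix(dist(cbind(ctr$center_row, ctr$center_col)))
  expect_gte(min(d[upper.tri(d)]), cfg$min_separation)
})

test_that("impossible packing densities raise an explicit error", {
  cfg <- simulation_config(image_size = 64, n_cells = 200, min_separation = 15)
  expect_error(generate_roi(cfg, "HC-LN", "r", seed = 1), "density")
})

test_that("an empty ROI flows through the pipeline to an empty cell table", {
  cfg <- small_cfg(n_cells = 0)
  g <- generate_roi(cfg, "HC-LN", "r0", seed = 2)
  res <- run_pipeline(g$roi, pipeline_config())
  expect_equal(nrow(res$cells), 0L)
})

test_that("well-separated fibroblasts give one truth component per cell", {
  cfg <- simulation_config(image_size = 750, n_cells = 150, min_separation = 25,
                           type_proportions = c(fibroblast = 1, endothelial = 0,
                                                other = 0),
                           noise_model = "none", background_level = 0,
                           hot_pixel_rate = 0)
  g <- generate_roi(cfg, "HC-LN", "r", seed = 3)
  expect_equal(length(unique(g$truth$cells$type)), 1L)
  expect_equal(oracle_n_components(g$truth$masks$Vimentin > 0), 150L)
})

test_that("type counts follow the configured proportions exactly", {
  cfg <- small_cfg(n_cells = 10)
  g <- generate_roi(cfg, "HC-LN", "r", seed = 4)
  expect_equal(sort(table(g$truth$cells$type)),
               sort(table(c(rep("fibroblast", 5), rep("endothelial", 3),
                            rep("other", 2)))))
})

test_that("cohorts derive one reproducible seed per ROI and apply group effects", {
  cfg <- small_cfg()
  coh <- generate_cohort(cfg, c("HC-LN" = 2, "CLL-LN" = 2), base_seed = 10)
  expect_length(coh, 4)
  expect_equal(vapply(coh, function(x) x$truth$seed, integer(1)),
               setNames(11:14, names(coh)))
  again <- generate_cohort(cfg, c("HC-LN" = 2, "CLL-LN" = 2), base_seed = 10)
  expect_identical(coh[[1]]$roi, again[[1]]$roi)

  # CLL-LN fibroblast LYN amplitudes are scaled up ~1.5x in expectation
  big <- simulation_config(image_size = 400, n_cells = 60, min_separation = 15)
  mean_amp <- function(groups, base_seed) {
    coh <- generate_cohort(big, groups, base_seed)
    cells <- do.call(rbind, lapply(coh, function(x) x$truth$cells))
    mean(cells$amp_LYN[cells$type == "fibroblast"])
  }
  hc <- mean_amp(c("HC-LN" = 4), 100)
  cll <- mean_amp(c("CLL-LN" = 4), 200)
  expect_gt(cll / hc, 1.25)
  expect_lt(cll / hc, 1.8)
})

test_that("segmentation evaluation scores perfect, absent and jittered predictions", {
  cfg <- small_cfg(n_cells = 8)
  g <- generate_roi(cfg, "HC-LN", "r", seed = 7)
  tc <- g$truth$cells
  tc <- tc[tc$type %in% c("fibroblast", "endothelial"), ]
  perfect <- data.frame(roi_id = "r", cell_type = tc$type,
                        centroid_row = tc$center_row,
                        centroid_col = tc$center_col,
                        mean_LYN = tc$amp_LYN)
  ev <- evaluate_segmentation(perfect, g$truth, match_radius = 5)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$f1, 1)
  expect_equal(ev$intensity_recovery_correlation, 1)

  none <- perfect[0, ]
  ev0 <- evaluate_segmentation(none, g$truth, match_radius = 5)
  expect_equal(ev0$recall, 0)

  set.seed(201)
  jit <- perfect
  ang <- runif(nrow(jit), 0, 2 * pi)
  jit$centroid_row <- jit$centroid_row + 2.4 * sin(ang)
  jit$centroid_col <- jit$centroid_col + 2.4 * cos(ang)
  evj <- evaluate_segmentation(jit, g$truth, match_radius = 5)
  expect_equal(evj$f1, 1)

  empty_truth <- g$truth
  empty_truth$cells <- empty_truth$cells[0, ]
  expect_error(evaluate_segmentation(perfect, empty_truth, 5), "undefined")
})
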