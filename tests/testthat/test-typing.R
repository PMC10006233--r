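test_that("cell typing applies the strict 30%-overlap discard rule", {
  shape <- c(40L, 40L)
  # Vimentin region of area 100 (10 x 10 at rows 0-9, cols 0-9)
  vim <- make_region(0:9, 0:9, shape, "Vimentin")

  no_overlap <- assign_cell_types(list(vim),
                                  list(make_region(20:29, 20:29, shape, "CD31")))
  types <- vapply(no_overlap, `[[`, character(1), "cell_type")
  expect_setequal(types, c("endothelial", "fibroblast"))

  # 31 of 100 pixels overlapping -> discarded
  cd31_31 <- make_region(0:9, 0:2, shape, "CD31") # 30 px
  cd31_1 <- make_region(0, 3, shape, "CD31", id = 2L) # 1 px more
  typed31 <- assign_cell_types(list(vim), list(cd31_31, cd31_1))
  expect_false("fibroblast" %in%
               vapply(typed31, `[[`, character(1), "cell_type"))

  # exactly 30 overlapping pixels -> kept (strictly more than 30% discards)
  typed30 <- assign_cell_types(list(vim), list(cd31_31))
  fib <- Filter(function(rg) rg$cell_type == "fibroblast", typed30)
  expect_length(fib, 1)
  expect_equal(fib[[1]]$cd31_overlap, 0.30)

  expect_error(
    assign_cell_types(list(vim), list(make_region(0:5, 0:5, c(50L, 50L), "CD31"))),
    "shape")
})

test_that("overlap uses the union of CD31 pixels, not a single region", {
  shape <- c(40L, 40L)
  vim <- make_region(0:9, 0:9, shape, "Vimentin")
  # two CD31 regions, 20 px each, overlapping the Vimentin region: 40% union
  a <- make_region(0:9, 0:1, shape, "CD31", 1L)
  b <- make_region(0:9, 2:3, shape, "CD31", 2L)
  typed <- assign_cell_types(list(vim), list(a, b))
  expect_false("fibroblast" %in% vapply(typed, `[[`, character(1), "cell_type"))
})

test_that("erosion matches brute-force morphology on squares, rectangles and random masks", {
  shape <- c(30L, 30L)
  single <- make_region(5, 5, shape)
  expect_equal(erode_region(single, 3)$area, 0L)

  sq7 <- make_region(10:16, 10:16, shape)
  out <- erode_region(sq7, 3)
  expect_equal(out$area, 1L)
  expect_equal(unname(out$pixels), cbind(13L, 13L), ignore_attr = TRUE)

  rect39 <- make_region(10:12, 10:18, shape)
  expect_equal(erode_region(rect39, 3)$area, 0L)

  set.seed(111)
  for (i in 1:10) {
    mask <- matrix(runif(400) < 0.6, 20, 20)
    if (!any(mask)) next
    idx <- which(mask)
    rg <- structure(list(region_id = 1L, marker = "Vimentin",
                         pixels = cbind(row = (idx - 1) %% 20,
                                        col = (idx - 1) %/% 20),
                         area = length(idx), shape = c(20L, 20L)),
                    class = "imc_region")
    want <- oracle_erode(mask, 2, cross_offsets)
    got <- erode_region(rg, 2)
    gotmask <- matrix(FALSE, 20, 20)
    gotmask[got$pixels[, 1] + 1 + 20 * got$pixels[, 2]] <- TRUE
    expect_identical(gotmask, want)
  }
})

test_that("erosion is anti-extensive and monotone in iterations", {
  set.seed(121)
  rgmask <- matrix(runif(400) < 0.7, 20, 20)
  idx <- which(rgmask)
  rg <- structure(list(region_id = 1L, marker = "Vimentin",
                       pixels = cbind(row = (idx - 1) %% 20,
                                      col = (idx - 1) %/% 20),
                       area = length(idx), shape = c(20L, 20L)),
                  class = "imc_region")
  prev <- rg
  for (it in 1:4) {
    er <- erode_region(rg, it)
    expect_lte(er$area, prev$area)
    key <- function(px) paste(px[, 1], px[, 2])
    expect_true(all(key(er$pixels) %in% key(rg$pixels)))
    prev <- er
  }
})

test_that("a region touching the image border erodes at the border", {
  shape <- c(10L, 10L)
  corner <- make_region(0:2, 0:2, shape) # 3x3 block in the image corner
  out <- erode_region(corner, 1)
  # outside the image counts as background: only the block center survives
  expect_equal(unname(out$pixels), cbind(1L, 1L), ignore_attr = TRUE)
})

test_that("area filtering keeps the inclusive [10, 800] band exactly", {
  shape <- c(5L, 950L)
  mk <- function(n) make_region(0, 0:(n - 1), shape)
  areas <- function(cells) vapply(cells, `[[`, integer(1), "area")
  got <- filter_by_area(lapply(c(9, 10, 800, 801), mk), 10, 800)
  expect_equal(areas(got), c(10L, 800L))

  # monotonicity of the kept count in both bounds
  set.seed(131)
  cells <- lapply(sample(1:900, 40), mk)
  n_kept <- function(lo, hi) length(filter_by_area(cells, lo, hi))
  expect_gte(n_kept(5, 800), n_kept(10, 800))
  expect_gte(n_kept(10, 900), n_kept(10, 800))
})
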