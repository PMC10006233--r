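test_that("the two-sample t-test matches the hand-evaluated Welch formula", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(2, 3, 4, 5, 6)
  got <- welch_ttest(a, b)
  # independent evaluation of the Welch statistic and Satterthwaite df
  se <- sqrt(var(a) / 5 + var(b) / 5)
  tt <- (mean(a) - mean(b)) / se
  df <- (var(a) / 5 + var(b) / 5)^2 /
    ((var(a) / 5)^2 / 4 + (var(b) / 5)^2 / 4)
  expect_equal(got$t, tt)
  expect_equal(got$t, -1.0)
  expect_equal(got$df, df)
  expect_equal(got$df, 8)
  expect_equal(got$p_value, 2 * pt(-1, 8), tolerance = 1e-10)
  expect_equal(got$p_value, 0.3466, tolerance = 1e-4)

  same <- welch_ttest(c(3, 3, 3), c(3, 3, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  expect_error(welch_ttest(1, c(1, 2)), "at least 2")
})

test_that("swapping groups negates t and preserves p", {
  set.seed(161)
  for (i in 1:10) {
    a <- rnorm(sample(5:30, 1))
    b <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
    f <- welch_ttest(a, b)
    r <- welch_ttest(b, a)
    expect_equal(r$t, -f$t)
    expect_equal(r$p_value, f$p_value)
  }
})

test_that("the t-test is calibrated under the null", {
  set.seed(171)
  p <- replicate(1000, welch_ttest(rnorm(200), rnorm(200))$p_value)
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
  expect_gt(ks.test(p, "punif")$p.value, 1e-3)
})

test_that("violin summaries give Tukey adjacent values", {
  one <- violin_summary(7.5)
  expect_equal(unlist(one), c(median = 7.5, q1 = 7.5, q3 = 7.5,
                              adjacent_low = 7.5, adjacent_high = 7.5))

  nine <- violin_summary(1:9)
  expect_equal(unlist(nine), c(median = 5, q1 = 3, q3 = 7,
                               adjacent_low = 1, adjacent_high = 9))

  with_outlier <- violin_summary(c(1:9, 100))
  expect_equal(with_outlier$adjacent_high, 9)

  expect_error(violin_summary(numeric(0)), "at least one")

  # order invariance and shift equivariance
  set.seed(181)
  v <- rnorm(50)
  expect_equal(violin_summary(sample(v)), violin_summary(v))
  shifted <- violin_summary(v + 2)
  expect_equal(unlist(shifted), unlist(violin_summary(v)) + 2)
})

test_that("group comparison pools cells by type and respects group order", {
  mk_tab <- function(vals_a, vals_b, type = "fibroblast") {
    data.frame(roi_id = "r", sample_id = "s",
               group = rep(c("A", "B"), c(length(vals_a), length(vals_b))),
               cell_id = seq_len(length(vals_a) + length(vals_b)),
               cell_type = type, area = 50,
               centroid_row = 0, centroid_col = 0,
               mean_LYN = sinh(c(vals_a, vals_b)) * 5,
               arcsinh_LYN = c(vals_a, vals_b))
  }
  ident <- mk_tab(c(1, 2, 3), c(1, 2, 3))
  res <- compare_groups(ident, "LYN", "fibroblast")
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$n1, 3)

  set.seed(191)
  up <- mk_tab(rnorm(60, 1), rnorm(60, 1.6))
  res_up <- compare_groups(up, "LYN", "fibroblast", groups = c("A", "B"))
  expect_lt(res_up$t_statistic, 0) # B higher -> negative mean(A) - mean(B)
  expect_equal(res_up$q1_1, unname(quantile(up$arcsinh_LYN[up$group == "A"], 0.25)))

  expect_error(compare_groups(up, "THBS1", "fibroblast"), "not quantified")
  expect_error(compare_groups(up, "LYN", "endothelial"), "fewer than 2")
})

test_that("fold-change concordance selects by threshold and matches the rank oracle", {
  ids <- paste0("g", 1:10)
  fa <- data.frame(id = ids, log2fc = c(2, -1.5, 1.2, 0.9, -2.5, 0.1, 3, -1, 1.1, 0.85))
  same <- cross_layer_concordance(fa, fa, threshold = 0.8)
  expect_equal(same$rho, 1)
  expect_equal(same$n_selected, 9)

  rev_tab <- fa
  rev_tab$log2fc <- -rank(fa$log2fc)
  expect_equal(cross_layer_concordance(fa, rev_tab, threshold = -Inf)$rho, -1)

  # ties: matches brute-force rank-then-Pearson
  fb <- data.frame(id = ids, log2fc = c(1, 1, 2, 0.9, -2, 0, 2.5, -1, 1, 0.9))
  got <- cross_layer_concordance(fa, fb, threshold = 0.8)
  keep <- abs(fa$log2fc) > 0.8 | abs(fb$log2fc) > 0.8
  expect_equal(got$rho, oracle_spearman(fa$log2fc[keep], fb$log2fc[keep]))
})

test_that("concordance is invariant under monotone transforms and errors when starved", {
  ids <- paste0("g", 1:8)
  fa <- data.frame(id = ids, log2fc = c(2, -1.5, 1.2, 0.9, -2.5, 1.4, 3, -1))
  fb <- data.frame(id = ids, log2fc = c(1.5, -1, 0.8, 1.2, -2, 1.1, 2.2, -0.5))
  base <- cross_layer_concordance(fa, fb)
  mono <- fb
  mono$log2fc <- fb$log2fc^3
  expect_equal(cross_layer_concordance(fa, mono)$rho, base$rho)

  tiny <- data.frame(id = c("g1", "g2"), log2fc = c(2, -2))
  expect_error(cross_layer_concordance(tiny, tiny), "fewer than 3")

  # "both" mode is stricter than "any"
  expect_lte(cross_layer_concordance(fa, fb, mode = "both")$n_selected,
             base$n_selected)
})
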