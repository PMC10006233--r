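#' Two-sample t-test for independent groups
#'
#' Welch's unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value (the default for unequal per-group cell
#' counts); Student's equal-variance variant is available behind a flag.
#' The degenerate case of two zero-variance samples with equal means returns
#' `t = 0`, `p = 1` with pooled df.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param var_equal Use the pooled-variance (Student) variant (default FALSE).
#' @return List with `t`, `df`, `p_value` (two-sided).
#' @export
welch_ttest <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations")
  if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b))
    return(list(t = 0, df = length(a) + length(b) - 2, p_value = 1))
  ht <- t.test(a, b, var.equal = var_equal, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Box/violin summary statistics with Tukey adjacent values
#'
#' Median and quartiles by linear interpolation; the whisker ends are the
#' adjacent values: `adjacent_low` is the smallest observation at or above
#' `q1 - 1.5 * IQR`, `adjacent_high` the largest observation at or below
#' `q3 + 1.5 * IQR`.
#'
#' @param values Non-empty numeric vector.
#' @return List with `median`, `q1`, `q3`, `adjacent_low`, `adjacent_high`.
#' @export
violin_summary <- function(values) {
  if (!length(values)) stop("violin_summary needs at least one value")
  qs <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- qs[3] - qs[1]
  list(median = qs[2], q1 = qs[1], q3 = qs[3],
       adjacent_low = min(values[values >= qs[1] - 1.5 * iqr]),
       adjacent_high = max(values[values <= qs[3] + 1.5 * iqr]))
}

#' Compare a marker between two groups of cells
#'
#' Pools all cells of the requested type across ROIs and samples within each
#' group (matching per-cell figure-legend n's; no per-patient random
#' effects) and compares the arcsinh-transformed mean intensities with an
#' independent two-sided t-test, reporting per-group violin summaries.
#'
#' @param table Cell table from [build_cell_table()].
#' @param channel Quantification channel name, e.g. `"LYN"`.
#' @param cell_type Cell type to compare, e.g. `"fibroblast"`.
#' @param groups Optional length-2 character vector fixing group order
#'   (reference first); defaults to sorted unique group labels.
#' @param var_equal Passed to [welch_ttest()].
#' @return A one-row `data.frame` with channel, cell type, per-group n,
#'   median, quartiles and adjacent values (arcsinh scale), `t_statistic`
#'   (sign follows `mean(group1) - mean(group2)`, so it is negative when the
#'   second group is higher), `degrees_of_freedom`, `p_value`.
#' @export
compare_groups <- function(table, channel, cell_type, groups = NULL,
                           var_equal = FALSE) {
  col <- paste0("arcsinh_", channel)
  if (!col %in% names(table))
    stop(sprintf("channel '%s' is not quantified in this table", channel))
  if (is.null(groups)) groups <- sort(unique(table$group))
  if (length(groups) != 2)
    stop("exactly two group labels are required")
  sel <- table$cell_type == cell_type & table$group %in% groups
  x <- table[sel, ]
  va <- x[[col]][x$group == groups[1]]
  vb <- x[[col]][x$group == groups[2]]
  if (length(va) < 2 || length(vb) < 2)
    stop(sprintf("fewer than 2 '%s' cells in one group", cell_type))
  tt <- welch_ttest(va, vb, var_equal = var_equal)
  sa <- violin_summary(va)
  sb <- violin_summary(vb)
  data.frame(channel = channel, cell_type = cell_type,
             group1 = groups[1], group2 = groups[2],
             n1 = length(va), n2 = length(vb),
             median1 = sa$median, q1_1 = sa$q1, q3_1 = sa$q3,
             adjacent_low1 = sa$adjacent_low, adjacent_high1 = sa$adjacent_high,
             median2 = sb$median, q1_2 = sb$q1, q3_2 = sb$q3,
             adjacent_low2 = sb$adjacent_low, adjacent_high2 = sb$adjacent_high,
             t_statistic = tt$t, degrees_of_freedom = tt$df,
             p_value = tt$p_value, stringsAsFactors = FALSE)
}

#' Cross-layer fold-change concordance
#'
#' Selects identifiers shared by two fold-change tables whose absolute log2
#' fold change exceeds `threshold` in at least one layer (or in both, with
#' `mode = "both"`) and returns the Spearman rank correlation (average
#' ranks for ties) over the selection.
#'
#' @param fc_a,fc_b Data frames with columns `id` and `log2fc`.
#' @param threshold Absolute log2-FC selection threshold (default 0.8).
#' @param mode `"any"` (default): the threshold must be exceeded in at least
#'   one layer; `"both"`: in both layers.
#' @return List with `rho`, `n_selected`, `selected_ids`.
#' @export
cross_layer_concordance <- function(fc_a, fc_b, threshold = 0.8,
                                    mode = c("any", "both")) {
  mode <- match.arg(mode)
  for (tb in list(fc_a, fc_b))
    if (!all(c("id", "log2fc") %in% names(tb)))
      stop("fold-change tables need columns 'id' and 'log2fc'")
  if (anyDuplicated(fc_a$id) || anyDuplicated(fc_b$id))
    stop("fold-change tables must have unique ids")
  common <- intersect(fc_a$id, fc_b$id)
  va <- fc_a$log2fc[match(common, fc_a$id)]
  vb <- fc_b$log2fc[match(common, fc_b$id)]
  keep <- if (mode == "any") {
    abs(va) > threshold | abs(vb) > threshold
  } else {
    abs(va) > threshold & abs(vb) > threshold
  }
  n <- sum(keep)
  if (n < 3)
    stop("fewer than 3 identifiers pass the fold-change filter")
  list(rho = cor(va[keep], vb[keep], method = "spearman"),
       n_selected = n,
       selected_ids = common[keep])
}
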