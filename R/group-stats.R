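#' Wilcoxon-Mann-Whitney test between two samples
#'
#' Two-sided rank-sum test. The p-value is exact (full enumeration of rank
#' arrangements) when the combined sample size is at most 12 and there are
#' no ties; otherwise the normal approximation with tie and continuity
#' correction is used.
#'
#' @param x,y Non-empty numeric samples.
#' @return Tibble with the `u` statistic (for `x`), the two-sided `p` value,
#'   and the `method` used (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    abort("Both samples must be non-empty.", class = "connectoms_invalid_input")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 12 && !ties
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)
  )
  tibble(u = unname(ht$statistic), p = ht$p.value,
         method = if (exact) "exact" else "normal_approx")
}

#' Compare all group pairs on all six metrics
#'
#' Runs the two-sided Mann-Whitney test for every pair of groups present in
#' the metric table and each of the six global metrics, mirroring the
#' all-pairs significance table of the analysis. No multiple-testing
#' correction is applied by default (each test at its own 5% level); set
#' `p_adjust = "holm"` to correct across the whole table.
#'
#' @param cohort_metrics Metric table from [connectome_metrics()].
#' @param alpha Per-test significance level (default 0.05).
#' @param p_adjust `"none"` (default) or any method of [stats::p.adjust()].
#' @return Tidy tibble: `metric`, `group1`, `group2`, `n1`, `n2`, `u`, `p`,
#'   `stars` (`*`/`**`/`***` at 0.05/0.01/0.001), `significant`.
#' @export
compare_groups <- function(cohort_metrics, alpha = 0.05, p_adjust = "none") {
  groups <- GROUP_LEVELS[GROUP_LEVELS %in% unique(as.character(cohort_metrics$group))]
  sizes <- table(factor(cohort_metrics$group, levels = groups))
  usable <- names(sizes)[sizes >= 2]
  dropped <- setdiff(groups, usable)
  if (length(dropped) > 0) {
    warn(sprintf("Group(s) with < 2 subjects skipped: %s.",
                 paste(dropped, collapse = ", ")))
  }
  if (length(usable) < 2) {
    abort("Need at least 2 groups with >= 2 subjects each.",
          class = "connectoms_invalid_input")
  }
  pairs <- utils::combn(usable, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(p_i) {
    g1 <- pairs[1, p_i]; g2 <- pairs[2, p_i]
    purrr::map_dfr(METRIC_COLS, function(met) {
      x <- cohort_metrics[[met]][cohort_metrics$group == g1]
      y <- cohort_metrics[[met]][cohort_metrics$group == g2]
      mw <- mann_whitney(x, y)
      tibble(metric = met, group1 = g1, group2 = g2,
             n1 = sum(!is.na(x)), n2 = sum(!is.na(y)),
             u = mw$u, p = mw$p)
    })
  })
  if (p_adjust != "none") out$p <- stats::p.adjust(out$p, method = p_adjust)
  out$stars <- cut(out$p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", ""))
  out$significant <- out$p < alpha
  out
}

#' Pivot a group comparison to the pair-by-metric significance layout
#'
#' Rows are group pairs, columns the six metrics; cells carry the p-value
#' when significant and `NA` (printed as a dash in the paper-style table)
#' otherwise.
#'
#' @param comparison Output of [compare_groups()].
#' @return Wide tibble: `pair`, `D`, `r`, `T`, `Eg`, `Q`, `CPL`.
#' @export
comparison_table <- function(comparison) {
  comparison |>
    dplyr::mutate(
      pair = paste(.data$group1, .data$group2, sep = "-"),
      cell = ifelse(.data$significant, .data$p, NA_real_)
    ) |>
    dplyr::select("pair", "metric", "cell") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "cell") |>
    dplyr::select(dplyr::all_of(c("pair", METRIC_COLS)))
}
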