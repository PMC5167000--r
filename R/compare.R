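#' Two-sample thickness comparison for one region
#'
#' Difference in mean regional thickness between the Early and Late groups
#' (`mean(early) - mean(late)`, so positive values mean the Late group is
#' thinner), with a two-sided p-value and a t-based CI. The Welch
#' unequal-variance statistic is the default; the pooled-variance variant
#' is available for sensitivity analysis.
#'
#' If both groups have zero variance and equal means the difference is
#' exactly 0 and p is defined as 1 (degenerate but not an error); zero
#' variance with unequal means yields p = 0 with a zero-width CI.
#'
#' @param early_values,late_values Numeric vectors (mm), >= 2 values each.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @param conf_level Confidence level of the CI on the difference.
#' @return List: `difference`, `ci_low`, `ci_high`, `p_value`.
#' @examples
#' region_ttest(c(3.4, 3.5, 3.6), c(3.1, 3.2, 3.3))
#' @export
region_ttest <- function(early_values, late_values, var_equal = FALSE,
                         conf_level = 0.95) {
  if (length(early_values) < 2L || length(late_values) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (any(!is.finite(early_values)) || any(!is.finite(late_values))) {
    stop("non-finite thickness values", call. = FALSE)
  }
  diff_means <- mean(early_values) - mean(late_values)
  if (var(early_values) == 0 && var(late_values) == 0) {
    return(list(difference = diff_means, ci_low = diff_means,
                ci_high = diff_means,
                p_value = if (diff_means == 0) 1 else 0))
  }
  ht <- t.test(early_values, late_values, var.equal = var_equal,
               conf.level = conf_level)
  list(difference = diff_means,
       ci_low = unname(ht$conf.int[1]), ci_high = unname(ht$conf.int[2]),
       p_value = unname(ht$p.value))
}

#' Per-region Early vs Late group comparison with per-hemisphere FDR
#'
#' Runs [region_ttest()] on every thickness column, then applies
#' Benjamini-Hochberg FDR control separately within each hemisphere via
#' [fdr_by_hemisphere()].
#'
#' @param cohort Cohort data.frame with a `stage` column (or `duration`,
#'   staged at `cutoff`).
#' @param thickness Thickness matrix aligned to `cohort`.
#' @param q FDR level (default 0.1).
#' @param cutoff Stage cutoff used if `stage` is absent.
#' @param var_equal Passed to [region_ttest()].
#' @param conf_level CI level for the per-region difference.
#' @return data.frame (`RegionComparison` rows): `region`, `hemisphere`,
#'   `difference`, `ci_low`, `ci_high`, `p_value`, `q_value`, `discovery`.
#' @examples
#' sim <- generate_cohort(sim_config(n_early = 30, n_late = 30,
#'                                   regions = c("G_cuneus", "G_orbital"),
#'                                   seed = 4))
#' compare_regions(sim$cohort, sim$thickness)
#' @export
compare_regions <- function(cohort, thickness, q = 0.1, cutoff = 10,
                            var_equal = FALSE, conf_level = 0.95) {
  stopifnot(is.data.frame(cohort), is.matrix(thickness),
            nrow(thickness) == nrow(cohort))
  if (!"stage" %in% names(cohort)) {
    cohort$stage <- assign_stage(cohort$duration, cutoff = cutoff)
  }
  cols <- parse_thickness_key(colnames(thickness))
  is_early <- cohort$stage == "Early"
  res <- lapply(seq_len(nrow(cols)), function(j) {
    tt <- region_ttest(thickness[is_early, cols$key[j]],
                       thickness[!is_early, cols$key[j]],
                       var_equal = var_equal, conf_level = conf_level)
    data.frame(region = cols$region[j], hemisphere = cols$hemisphere[j],
               difference = tt$difference, ci_low = tt$ci_low,
               ci_high = tt$ci_high, p_value = tt$p_value, row.names = NULL)
  })
  fdr_by_hemisphere(do.call(rbind, res), q = q)
}

#' Benjamini-Hochberg FDR control applied separately per hemisphere
#'
#' Adjusts the p-values of a region-comparison table with the BH step-up
#' procedure within the left-hemisphere rows and, independently, within the
#' right-hemisphere rows, and flags discoveries at level `q`. Decisions in
#' one hemisphere never depend on p-values in the other.
#'
#' @param comparisons data.frame with at least `hemisphere` and `p_value`.
#' @param q FDR level (default 0.1).
#' @return The input with `q_value` (BH-adjusted p) and `discovery`
#'   (logical, `q_value <= q`) filled in.
#' @examples
#' df <- data.frame(region = c("a", "b", "c"), hemisphere = "left",
#'                  p_value = c(0.001, 0.02, 0.9))
#' fdr_by_hemisphere(df, q = 0.1)
#' @export
fdr_by_hemisphere <- function(comparisons, q = 0.1) {
  stopifnot(is.data.frame(comparisons))
  if (!all(c("hemisphere", "p_value") %in% names(comparisons))) {
    stop("`comparisons` must carry `hemisphere` and `p_value` columns",
         call. = FALSE)
  }
  if (!is_number(q) || q <= 0 || q >= 1) {
    stop("`q` must lie in (0, 1)", call. = FALSE)
  }
  if (nrow(comparisons) == 0L) {
    warning("empty comparison set; nothing to adjust", call. = FALSE)
    comparisons$q_value <- numeric(0)
    comparisons$discovery <- logical(0)
    return(comparisons)
  }
  if (any(comparisons$p_value < 0 | comparisons$p_value > 1, na.rm = TRUE) ||
      any(is.na(comparisons$p_value))) {
    stop("p_value column must lie in [0, 1] with no missing values",
         call. = FALSE)
  }
  comparisons$q_value <- NA_real_
  for (h in unique(comparisons$hemisphere)) {
    rows <- comparisons$hemisphere == h
    comparisons$q_value[rows] <- p.adjust(comparisons$p_value[rows],
                                          method = "BH")
  }
  comparisons$discovery <- comparisons$q_value <= q
  comparisons
}
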