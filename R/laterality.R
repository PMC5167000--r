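#' Homologous left/right region pairs of a thickness matrix
#'
#' @param thickness Thickness matrix with `<hemi>_<region>_thickness`
#'   columns.
#' @return data.frame with one row per region present in both hemispheres:
#'   `region`, `left_key`, `right_key`. Regions present in only one
#'   hemisphere are reported in the `"unpaired"` attribute.
#' @examples
#' sim <- generate_cohort(sim_config(n_early = 4, n_late = 4,
#'                                   regions = "G_cuneus", seed = 1))
#' homologous_pairs(sim$thickness)
#' @export
homologous_pairs <- function(thickness) {
  cols <- parse_thickness_key(colnames(thickness))
  left <- cols[cols$hemisphere == "left", ]
  right <- cols[cols$hemisphere == "right", ]
  common <- intersect(left$region, right$region)
  out <- data.frame(
    region = common,
    left_key = left$key[match(common, left$region)],
    right_key = right$key[match(common, right$region)],
    row.names = NULL
  )
  attr(out, "unpaired") <- setdiff(union(left$region, right$region), common)
  out
}

resolve_subgroup <- function(cohort, subgroup) {
  if (is.null(subgroup)) {
    list(keep = rep(TRUE, nrow(cohort)), label = "all")
  } else if (is.function(subgroup)) {
    keep <- subgroup(cohort)
    stopifnot(is.logical(keep), length(keep) == nrow(cohort))
    list(keep = keep & !is.na(keep), label = "custom")
  } else if (is.logical(subgroup) && length(subgroup) == nrow(cohort)) {
    list(keep = subgroup & !is.na(subgroup), label = "custom")
  } else if (is.character(subgroup) && length(subgroup) == 1L) {
    keep <- switch(
      subgroup,
      "left-handed" = cohort$handedness == "L",
      "right-handed" = cohort$handedness == "R",
      "motor-left" = motor_laterality(cohort)$side == "left-predominant",
      "motor-right" = motor_laterality(cohort)$side == "right-predominant",
      stop("unknown subgroup label '", subgroup,
           "'; use one of left-handed, right-handed, motor-left, motor-right, ",
           "or supply a logical vector / predicate function", call. = FALSE)
    )
    list(keep = keep, label = subgroup)
  } else {
    stop("`subgroup` must be NULL, a label, a logical vector, or a predicate function",
         call. = FALSE)
  }
}

#' Duration-thickness correlation within a subgroup
#'
#' Pearson correlation between disease duration and regional thickness for
#' a patient subgroup (e.g. left-handed Early-stage patients), with the
#' two-sided p-value from the product-moment test.
#'
#' @param cohort Cohort data.frame with `duration` (and whatever columns
#'   the subgroup needs).
#' @param thickness Thickness matrix aligned to `cohort`.
#' @param region Region name.
#' @param hemisphere `"left"` or `"right"`.
#' @param subgroup `NULL` (all patients), one of the labels
#'   `"left-handed"`, `"right-handed"`, `"motor-left"`, `"motor-right"`, a
#'   logical vector over patients, or a predicate `function(cohort)`.
#' @return One-row data.frame (`CorrelationResult`): `region`,
#'   `hemisphere`, `subgroup`, `n`, `r`, `p_value`.
#' @examples
#' sim <- generate_cohort(sim_config(n_early = 50, n_late = 40,
#'                                   regions = "S_orbital_med-olfact",
#'                                   rate_early = -0.06, noise_sd = 0.05,
#'                                   seed = 8))
#' duration_correlation(sim$cohort, sim$thickness, "S_orbital_med-olfact",
#'                      "left", subgroup = sim$cohort$stage == "Early")
#' @export
duration_correlation <- function(cohort, thickness, region, hemisphere,
                                 subgroup = NULL) {
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  key <- thickness_key(hemisphere, region)
  if (!key %in% colnames(thickness)) {
    stop("thickness matrix has no column ", key, call. = FALSE)
  }
  sg <- resolve_subgroup(cohort, subgroup)
  x <- cohort$duration[sg$keep]
  y <- thickness[sg$keep, key]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) {
    stop(sprintf("subgroup '%s' has %d patient(s) with data; >= 3 required",
                 sg$label, length(x)), call. = FALSE)
  }
  if (var(x) == 0 || var(y) == 0) {
    stop("zero variance in duration or thickness; correlation undefined",
         call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson")
  data.frame(region = region, hemisphere = hemisphere, subgroup = sg$label,
             n = length(x), r = unname(ct$estimate),
             p_value = unname(ct$p.value), row.names = NULL)
}

#' Within-patient left-vs-right thickness comparison
#'
#' For a subgroup (typically the motor-lateralized patients), summarizes
#' the left- and right-hemisphere thickness of a region as mean +/- SD and
#' tests the within-patient left-minus-right differences with a two-sided
#' paired t-test (an unpaired Welch variant is available for sensitivity
#' checks). If every within-patient difference is zero, p is defined as 1.
#'
#' @inheritParams duration_correlation
#' @param paired Use the paired t-test (default) or an unpaired Welch test.
#' @return One-row data.frame (`PairedHemiResult`): `region`, `subgroup`,
#'   `n`, `left_mean`, `left_sd`, `right_mean`, `right_sd`, `left_summary`
#'   and `right_summary` ("mean +/- SD" strings), `difference` (left minus
#'   right, mm), `p_value`.
#' @examples
#' sim <- generate_cohort(sim_config(n_early = 30, n_late = 30,
#'                                   regions = "G_insular_short", seed = 9))
#' paired_hemisphere_test(sim$cohort, sim$thickness, "G_insular_short")
#' @export
paired_hemisphere_test <- function(cohort, thickness, region, subgroup = NULL,
                                   paired = TRUE) {
  lkey <- thickness_key("left", region)
  rkey <- thickness_key("right", region)
  for (k in c(lkey, rkey)) {
    if (!k %in% colnames(thickness)) {
      stop("thickness matrix has no column ", k, call. = FALSE)
    }
  }
  sg <- resolve_subgroup(cohort, subgroup)
  lv <- thickness[sg$keep, lkey]
  rv <- thickness[sg$keep, rkey]
  ok <- is.finite(lv) & is.finite(rv)
  lv <- lv[ok]
  rv <- rv[ok]
  if (length(lv) < 2L) {
    stop(sprintf("subgroup '%s' has %d patient(s) with both hemispheres; >= 2 required",
                 sg$label, length(lv)), call. = FALSE)
  }
  d <- lv - rv
  p <- if (paired) {
    if (all(d == 0)) 1 else unname(t.test(d)$p.value)
  } else {
    if (var(lv) == 0 && var(rv) == 0) {
      if (mean(d) == 0) 1 else 0
    } else {
      unname(t.test(lv, rv, var.equal = FALSE)$p.value)
    }
  }
  fmt <- function(m, s) sprintf("%.2f ± %.2f", m, s)
  data.frame(
    region = region, subgroup = sg$label, n = length(lv),
    left_mean = mean(lv), left_sd = sd(lv),
    right_mean = mean(rv), right_sd = sd(rv),
    left_summary = fmt(mean(lv), sd(lv)),
    right_summary = fmt(mean(rv), sd(rv)),
    difference = mean(d), p_value = p, row.names = NULL
  )
}

#' Classify hemispheric lateralization of a slope-difference pair
#'
#' Given the [slope_difference()] results for the left and right instance
#' of one homologous region pair (computed with matched settings),
#' classifies which hemisphere shows a significant Early-vs-Late rate
#' contrast under the CI sign rule.
#'
#' @param left_diff,right_diff One-row [slope_difference()] results for the
#'   same region in the two hemispheres.
#' @return List: `region`, `left` and `right` (the inputs), and
#'   `lateralized` in `{"left-only", "right-only", "both", "neither"}`.
#' @export
asymmetry_contrast <- function(left_diff, right_diff) {
  stopifnot(is.data.frame(left_diff), nrow(left_diff) == 1L,
            is.data.frame(right_diff), nrow(right_diff) == 1L)
  if (left_diff$region != right_diff$region) {
    stop("inputs describe different regions: ", left_diff$region, " vs ",
         right_diff$region, call. = FALSE)
  }
  if (left_diff$hemisphere != "left" || right_diff$hemisphere != "right") {
    stop("inputs must be the left and right result, in that order",
         call. = FALSE)
  }
  for (f in c("n_boot", "alpha", "seed")) {
    if (left_diff[[f]] != right_diff[[f]]) {
      stop("mismatched settings between hemispheres: ", f, call. = FALSE)
    }
  }
  lsig <- left_diff$significant_early || left_diff$significant_late
  rsig <- right_diff$significant_early || right_diff$significant_late
  lateralized <- if (lsig && rsig) "both" else if (lsig) "left-only" else
    if (rsig) "right-only" else "neither"
  list(region = left_diff$region, left = left_diff, right = right_diff,
       lateralized = lateralized)
}
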