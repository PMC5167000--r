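#' Least-squares atrophy slope
#'
#' Closed-form ordinary least squares fit of thickness on disease duration.
#' The slope is the cross-sectional atrophy-rate estimate in mm/year
#' (negative = thinning). Exact on collinear input.
#'
#' @param durations Numeric vector of disease durations (years), >= 3
#'   values with nonzero variance.
#' @param thicknesses Numeric vector of thickness values (mm), same length.
#' @return List with elements `slope` (mm/year) and `intercept` (mm).
#' @examples
#' ols_slope(c(2, 4, 6, 8), 3.0 - 0.05 * c(2, 4, 6, 8))
#' @export
ols_slope <- function(durations, thicknesses) {
  if (length(durations) != length(thicknesses)) {
    stop("`durations` and `thicknesses` must have equal length", call. = FALSE)
  }
  if (length(durations) < 3L) {
    stop("at least 3 points are required for a slope estimate", call. = FALSE)
  }
  if (any(!is.finite(durations)) || any(!is.finite(thicknesses))) {
    stop("non-finite values in regression input", call. = FALSE)
  }
  mx <- mean(durations)
  my <- mean(thicknesses)
  dx <- durations - mx
  sxx <- sum(dx * dx)
  if (sxx == 0) {
    stop("durations are constant; slope is not identified", call. = FALSE)
  }
  slope <- sum(dx * (thicknesses - my)) / sxx
  list(slope = slope, intercept = my - slope * mx)
}

# Bootstrap slopes by case resampling, vectorized over replicates.
# Degenerate resamples (near-constant durations) are redrawn column-wise up
# to `max_retry` passes; the redraw tally is returned. Uses the current RNG
# stream (caller controls seeding).
boot_slopes <- function(x, y, n_boot, max_retry = 100L) {
  n <- length(x)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  xs <- matrix(x[idx], nrow = n)
  ys <- matrix(y[idx], nrow = n)
  mx <- colMeans(xs)
  sxx <- colMeans(xs * xs) - mx * mx
  tol <- max(1e-12, 1e-10 * stats::var(x))
  redraws <- 0L
  tries <- 0L
  bad <- sxx < tol
  while (any(bad)) {
    tries <- tries + 1L
    if (tries > max_retry) {
      stop(sprintf(
        "bootstrap failed: %d resample(s) still have constant durations after %d redraw passes",
        sum(bad), max_retry), call. = FALSE)
    }
    nb <- sum(bad)
    redraws <- redraws + nb
    idx2 <- matrix(sample.int(n, n * nb, replace = TRUE), nrow = n)
    xs[, bad] <- matrix(x[idx2], nrow = n)
    ys[, bad] <- matrix(y[idx2], nrow = n)
    mx <- colMeans(xs)
    sxx <- colMeans(xs * xs) - mx * mx
    bad <- sxx < tol
  }
  my <- colMeans(ys)
  sxy <- colMeans(xs * ys) - mx * my
  list(slopes = sxy / sxx, redraws = redraws)
}

# Percentile CI, with the degenerate noise-free case collapsing to a point.
percentile_ci <- function(stat, alpha) {
  unname(quantile(stat, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7))
}

#' Per-region atrophy rates by stage with bootstrap CIs
#'
#' For each thickness column (region x hemisphere) and each requested
#' stage, fits the OLS slope of thickness on disease duration within that
#' stage's patients. The point estimate comes from the unresampled stage
#' subset; the confidence interval is a percentile bootstrap over patients
#' resampled with replacement within the stage. Each (region, hemisphere,
#' stage) bootstrap uses an independent seed derived from `seed` and a
#' stable hash of the column key, so adding or reordering regions never
#' changes existing results.
#'
#' @param cohort Cohort data.frame with `duration` and `stage` columns.
#' @param thickness Thickness matrix aligned to `cohort` rows.
#' @param stage Stages to estimate (default both).
#' @param n_boot Bootstrap replicates (>= 200; default 2000).
#' @param alpha CI level complement (default 0.05 for 95% CIs).
#' @param seed Master integer seed.
#' @param max_retry Cap on redraw passes for degenerate resamples.
#' @return data.frame (`RateEstimate` rows): `region`, `hemisphere`,
#'   `stage`, `slope`, `intercept`, `n`, `ci_low`, `ci_high`, `n_boot`,
#'   `degenerate_redraws`.
#' @seealso [slope_difference()], [atrophy_rates()]
#' @export
estimate_rates <- function(cohort, thickness, stage = c("Early", "Late"),
                           n_boot = 2000L, alpha = 0.05, seed = 1L,
                           max_retry = 100L) {
  stage <- match.arg(stage, c("Early", "Late"), several.ok = TRUE)
  check_rate_inputs(cohort, thickness, n_boot, alpha)
  cols <- parse_thickness_key(colnames(thickness))
  out <- vector("list", length(stage) * nrow(cols))
  i <- 0L
  for (st in stage) {
    in_stage <- cohort$stage == st
    if (sum(in_stage) < 3L) {
      stop(sprintf("stage %s has %d patient(s); at least 3 are required",
                   st, sum(in_stage)), call. = FALSE)
    }
    x <- cohort$duration[in_stage]
    for (j in seq_len(nrow(cols))) {
      y <- thickness[in_stage, cols$key[j]]
      fit <- ols_slope(x, y)
      bs <- with_seed(derive_seed(seed, "rates", st, cols$key[j]),
                      boot_slopes(x, y, n_boot, max_retry))
      ci <- percentile_ci(bs$slopes, alpha)
      i <- i + 1L
      out[[i]] <- data.frame(
        region = cols$region[j], hemisphere = cols$hemisphere[j], stage = st,
        slope = fit$slope, intercept = fit$intercept, n = sum(in_stage),
        ci_low = ci[1], ci_high = ci[2], n_boot = n_boot,
        degenerate_redraws = bs$redraws, row.names = NULL
      )
    }
  }
  do.call(rbind, out)
}

#' Bootstrapped Early-minus-Late slope difference for one region
#'
#' Estimates the contrast `slope_Early - slope_Late` for a single region
#' and hemisphere. Each bootstrap replicate independently resamples
#' patients with replacement within the Early stratum and within the Late
#' stratum, refits both OLS slopes, and records their difference; the CI is
#' the percentile pair of that bootstrap distribution. Significance uses
#' the CI sign rule: significantly greater Early-stage atrophy when both
#' endpoints are negative (`significant_early`), significantly greater
#' Late-stage atrophy when both are positive (`significant_late`).
#'
#' @inheritParams estimate_rates
#' @param region Region name.
#' @param hemisphere `"left"` or `"right"`.
#' @return One-row data.frame (`SlopeDifference`): `region`, `hemisphere`,
#'   `difference`, `ci_low`, `ci_high`, `significant_early`,
#'   `significant_late`, `n_early`, `n_late`, `n_boot`, `seed`,
#'   `degenerate_redraws`.
#' @examples
#' sim <- generate_cohort(sim_config(
#'   n_early = 40, n_late = 40, regions = "G_insular_short",
#'   rate_early = -0.07, rate_late = -0.01, noise_sd = 0.05, seed = 2))
#' slope_difference(sim$cohort, sim$thickness, "G_insular_short", "left",
#'                  n_boot = 500, seed = 2)
#' @export
slope_difference <- function(cohort, thickness, region, hemisphere,
                             n_boot = 2000L, alpha = 0.05, seed = 1L,
                             max_retry = 100L) {
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  check_rate_inputs(cohort, thickness, n_boot, alpha)
  key <- thickness_key(hemisphere, region)
  if (!key %in% colnames(thickness)) {
    stop("thickness matrix has no column ", key, call. = FALSE)
  }
  is_early <- cohort$stage == "Early"
  n_early <- sum(is_early)
  n_late <- sum(!is_early)
  if (n_early < 3L || n_late < 3L) {
    stop(sprintf("both stages need >= 3 patients (Early %d, Late %d)",
                 n_early, n_late), call. = FALSE)
  }
  xe <- cohort$duration[is_early]
  ye <- thickness[is_early, key]
  xl <- cohort$duration[!is_early]
  yl <- thickness[!is_early, key]
  point <- ols_slope(xe, ye)$slope - ols_slope(xl, yl)$slope
  res <- with_seed(derive_seed(seed, "slopediff", key), {
    be <- boot_slopes(xe, ye, n_boot, max_retry)
    bl <- boot_slopes(xl, yl, n_boot, max_retry)
    list(diffs = be$slopes - bl$slopes, redraws = be$redraws + bl$redraws)
  })
  ci <- percentile_ci(res$diffs, alpha)
  data.frame(
    region = region, hemisphere = hemisphere, difference = point,
    ci_low = ci[1], ci_high = ci[2],
    significant_early = ci[2] < 0, significant_late = ci[1] > 0,
    n_early = n_early, n_late = n_late, n_boot = n_boot, alpha = alpha,
    seed = seed, degenerate_redraws = res$redraws, row.names = NULL
  )
}

check_rate_inputs <- function(cohort, thickness, n_boot, alpha) {
  stopifnot(is.data.frame(cohort), is.matrix(thickness))
  if (!all(c("duration", "stage") %in% names(cohort))) {
    stop("cohort must carry `duration` and `stage` columns", call. = FALSE)
  }
  if (nrow(thickness) != nrow(cohort)) {
    stop("thickness rows must align with cohort rows", call. = FALSE)
  }
  if (!is_count(n_boot) || n_boot < 200) {
    stop("`n_boot` must be an integer >= 200", call. = FALSE)
  }
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }
  invisible(TRUE)
}
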