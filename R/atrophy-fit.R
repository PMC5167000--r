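#' Fit stage-stratified regional atrophy rates
#'
#' The package's central fitting function. Stages the cohort at `cutoff`
#' (if no `stage` column is present), then for every thickness column fits
#' the per-stage OLS atrophy rate with a percentile bootstrap CI
#' ([estimate_rates()]) and the bootstrapped Early-minus-Late slope
#' difference with the CI sign rule ([slope_difference()]). All randomness
#' derives from the single `seed`; refitting with the same inputs
#' reproduces results exactly.
#'
#' @param cohort Cohort data.frame with at least `duration` (years); a
#'   `stage` column is derived at `cutoff` when absent.
#' @param thickness Thickness matrix (subjects x `<hemi>_<region>_thickness`
#'   columns) row-aligned to `cohort`.
#' @param cutoff Stage cutoff in years.
#' @param n_boot Bootstrap replicates per estimate (default 2000).
#' @param alpha CI level complement (default 0.05: 95% CIs).
#' @param seed Master seed for all bootstraps.
#' @param regions Optional character vector restricting the analysis to
#'   these region names.
#' @return An object of class `"atrophy_fit"` with components `rates`
#'   (per region x hemisphere x stage), `differences` (per region x
#'   hemisphere), `settings`, `n` (patients per stage), `model` (the data
#'   the fit was computed from) and `call`.
#' @seealso [summary.atrophy_fit()], [plot.atrophy_fit()],
#'   [simulate.atrophy_fit()]
#' @examples
#' sim <- generate_cohort(sim_config(
#'   n_early = 40, n_late = 40,
#'   regions = c("G_insular_short", "G_occipital_sup"),
#'   rate_early = c(lh_G_insular_short_thickness = -0.07),
#'   noise_sd = 0.08, seed = 5))
#' fit <- atrophy_rates(sim$cohort, sim$thickness, n_boot = 300, seed = 5)
#' fit
#' head(coef(fit))
#' @export
atrophy_rates <- function(cohort, thickness, cutoff = 10, n_boot = 2000L,
                          alpha = 0.05, seed = 1L, regions = NULL) {
  stopifnot(is.data.frame(cohort), is.matrix(thickness))
  if (!"stage" %in% names(cohort)) {
    cohort$stage <- assign_stage(cohort$duration, cutoff = cutoff)
  }
  cols <- parse_thickness_key(colnames(thickness))
  if (!is.null(regions)) {
    missing_r <- setdiff(regions, cols$region)
    if (length(missing_r)) {
      stop("region(s) absent from thickness matrix: ",
           paste(missing_r, collapse = ", "), call. = FALSE)
    }
    keep <- cols$region %in% regions
    thickness <- thickness[, cols$key[keep], drop = FALSE]
    cols <- cols[keep, , drop = FALSE]
  }
  rates <- estimate_rates(cohort, thickness, stage = c("Early", "Late"),
                          n_boot = n_boot, alpha = alpha, seed = seed)
  diffs <- do.call(rbind, lapply(seq_len(nrow(cols)), function(j) {
    slope_difference(cohort, thickness, cols$region[j], cols$hemisphere[j],
                     n_boot = n_boot, alpha = alpha, seed = seed)
  }))
  structure(
    list(
      rates = rates,
      differences = diffs,
      settings = list(cutoff = cutoff, n_boot = n_boot, alpha = alpha,
                      seed = seed, conf_level = 1 - alpha,
                      ci_method = "percentile",
                      resampling = "patients within stage"),
      n = c(early = sum(cohort$stage == "Early"),
            late = sum(cohort$stage == "Late")),
      model = list(duration = cohort$duration, stage = cohort$stage,
                   thickness = thickness),
      call = match.call()
    ),
    class = "atrophy_fit"
  )
}

#' @export
print.atrophy_fit <- function(x, ...) {
  cat("Stage-stratified cortical atrophy-rate fit\n")
  cat(sprintf("  %d Early / %d Late patients (cutoff %g years)\n",
              x$n[["early"]], x$n[["late"]], x$settings$cutoff))
  cat(sprintf("  %d region x hemisphere columns; %d bootstrap replicates, %g%% percentile CIs\n",
              nrow(x$differences), x$settings$n_boot,
              100 * x$settings$conf_level))
  cat(sprintf("  slope differences (Early - Late): %d significant early, %d significant late\n",
              sum(x$differences$significant_early),
              sum(x$differences$significant_late)))
  invisible(x)
}

#' Coefficients of an atrophy fit
#'
#' @param object An `"atrophy_fit"`.
#' @param ... Unused.
#' @return data.frame with one row per region x hemisphere: the Early and
#'   Late slopes (mm/year) and their Early-minus-Late difference.
#' @export
coef.atrophy_fit <- function(object, ...) {
  r <- object$rates
  early <- r[r$stage == "Early", c("region", "hemisphere", "slope")]
  late <- r[r$stage == "Late", c("region", "hemisphere", "slope")]
  names(early)[3] <- "slope_early"
  names(late)[3] <- "slope_late"
  out <- merge(early, late, by = c("region", "hemisphere"), sort = FALSE)
  out$difference <- out$slope_early - out$slope_late
  out
}

#' Summarize an atrophy fit
#'
#' Tallies, per hemisphere, the regions whose Early-minus-Late slope
#' difference is significant in either direction under the CI sign rule,
#' and lists the fastest-thinning regions per stage.
#'
#' @param object An `"atrophy_fit"`.
#' @param n_top Number of fastest-thinning regions to list per stage.
#' @param ... Unused.
#' @return A `"summary.atrophy_fit"` list.
#' @export
summary.atrophy_fit <- function(object, n_top = 5L, ...) {
  d <- object$differences
  tab <- do.call(rbind, lapply(split(d, d$hemisphere), function(h) {
    data.frame(hemisphere = h$hemisphere[1], n_regions = nrow(h),
               significant_early = sum(h$significant_early),
               significant_late = sum(h$significant_late), row.names = NULL)
  }))
  r <- object$rates
  top <- lapply(split(r, r$stage), function(s) {
    s <- s[order(s$slope), , drop = FALSE]
    utils::head(s[, c("region", "hemisphere", "slope", "ci_low", "ci_high")],
                n_top)
  })
  structure(list(by_hemisphere = tab, fastest = top, n = object$n,
                 settings = object$settings),
            class = "summary.atrophy_fit")
}

#' @export
print.summary.atrophy_fit <- function(x, ...) {
  cat("Atrophy-fit summary\n")
  cat(sprintf("  %d Early / %d Late patients; %g%% percentile CIs (n_boot = %d)\n\n",
              x$n[["early"]], x$n[["late"]], 100 * x$settings$conf_level,
              x$settings$n_boot))
  cat("Slope-difference sign-rule counts by hemisphere:\n")
  print(x$by_hemisphere, row.names = FALSE)
  for (st in names(x$fastest)) {
    cat(sprintf("\nFastest-thinning regions, %s stage (mm/year):\n", st))
    print(x$fastest[[st]], row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Residuals of the stage-wise linear fits
#'
#' @param object An `"atrophy_fit"`.
#' @param ... Unused.
#' @return Numeric matrix, subjects x thickness columns: observed thickness
#'   minus the fitted value of the patient's stage segment.
#' @export
residuals.atrophy_fit <- function(object, ...) {
  m <- object$model
  r <- object$rates
  key <- thickness_key(r$hemisphere, r$region)
  fitted <- matrix(0, nrow(m$thickness), ncol(m$thickness),
                   dimnames = dimnames(m$thickness))
  for (st in c("Early", "Late")) {
    rows <- m$stage == st
    sub <- r[r$stage == st, , drop = FALSE]
    k <- key[r$stage == st]
    fitted[rows, k] <- outer(m$duration[rows], sub$slope) +
      matrix(rep(sub$intercept, each = sum(rows)), sum(rows))
  }
  m$thickness - fitted
}

#' Simulate new cohorts from a fitted atrophy model
#'
#' Draws synthetic cohorts from the fitted piecewise-linear model: the
#' per-region, per-stage intercepts and slopes become the generating
#' baselines and rates, the per-region residual SD becomes the measurement
#' noise, and stage sizes and duration ranges match the fitted data.
#'
#' @param object An `"atrophy_fit"`.
#' @param nsim Number of cohorts to simulate.
#' @param seed Integer seed for the simulated cohorts.
#' @param ... Unused.
#' @return A list of `nsim` [generate_cohort()] results.
#' @export
simulate.atrophy_fit <- function(object, nsim = 1, seed = 1L, ...) {
  m <- object$model
  r <- object$rates
  res <- residuals(object)
  cols <- parse_thickness_key(colnames(m$thickness))
  pick <- function(st, what) {
    sub <- r[r$stage == st, , drop = FALSE]
    setNames(sub[[what]], thickness_key(sub$hemisphere, sub$region))[cols$key]
  }
  rng_early <- range(m$duration[m$stage == "Early"])
  rng_late <- range(m$duration[m$stage == "Late"])
  lapply(seq_len(nsim), function(i) {
    cfg <- sim_config(
      n_early = sum(m$stage == "Early"), n_late = sum(m$stage == "Late"),
      duration_range_early = rng_early, duration_range_late = rng_late,
      cutoff = object$settings$cutoff,
      regions = unique(cols$region),
      hemispheres = unique(cols$hemisphere),
      baseline_early = pick("Early", "intercept"),
      baseline_late = pick("Late", "intercept"),
      rate_early = pick("Early", "slope"),
      rate_late = pick("Late", "slope"),
      noise_sd = setNames(apply(res, 2, sd), cols$key),
      seed = derive_seed(seed, "simulate", i)
    )
    generate_cohort(cfg)
  })
}

#' Plot Early-minus-Late slope differences
#'
#' Horizontal forest-style plot of the bootstrapped slope differences with
#' their percentile CIs, one row per region, split by hemisphere.
#' Differences left of zero indicate faster Early-stage thinning; CIs
#' entirely on one side of zero are drawn filled (the sign rule).
#'
#' @param x An `"atrophy_fit"`.
#' @param hemisphere Hemisphere(s) to draw.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.atrophy_fit <- function(x, hemisphere = c("left", "right"), ...) {
  hemisphere <- match.arg(hemisphere, c("left", "right"), several.ok = TRUE)
  d <- x$differences[x$differences$hemisphere %in% hemisphere, , drop = FALSE]
  d <- d[order(d$hemisphere, d$difference), , drop = FALSE]
  k <- nrow(d)
  sig <- d$significant_early | d$significant_late
  old <- par(mar = c(4.5, 10, 2.5, 1))
  on.exit(par(old))
  plot(d$difference, seq_len(k), xlim = range(c(d$ci_low, d$ci_high, 0)),
       ylim = c(0.5, k + 0.5), yaxt = "n", pch = ifelse(sig, 19, 21),
       bg = "white", xlab = "slope difference, Early - Late (mm/year)",
       ylab = "", main = "Bootstrapped Early - Late atrophy-rate differences",
       ...)
  segments(d$ci_low, seq_len(k), d$ci_high, seq_len(k))
  abline(v = 0, lty = 2, col = "grey40")
  axis(2, at = seq_len(k), labels = paste(substr(d$hemisphere, 1, 1),
                                          d$region), las = 1, cex.axis = 0.6)
  mtext(sprintf("%g%% percentile CIs; filled = CI excludes 0",
                100 * x$settings$conf_level), cex = 0.8)
  invisible(x)
}
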