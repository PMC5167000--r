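#' Configure a synthetic PD cohort simulation
#'
#' Defines the data-generating process the analysis assumes: disease
#' durations drawn uniformly within each stage's range, and regional
#' cortical thickness following an independent linear segment per stage
#' (`baseline + rate * duration`) with homoscedastic Gaussian measurement
#' noise. Clinical covariates (sex, ages, handedness, UPDRS-III totals and
#' per-extremity item scores) are generated with the marginal structure of a
#' DBS-referral PD cohort. Defaults emulate the reference cohort shape:
#' 109 Early patients with durations on 2.2--9.9 years and 96 Late patients
#' on 10.1--27.1 years, staged at a 10-year cutoff.
#'
#' Per-region parameters (`baseline_early`, `baseline_late`, `rate_early`,
#' `rate_late`, `noise_sd`) may be given as a single number (applied to all
#' region/hemisphere columns), a full vector (one value per column, in
#' `thickness_key(hemisphere, region)` order: all left then all right), or a
#' named vector whose names are thickness column keys, overriding the scalar
#' default for just those columns.
#'
#' The two stage segments are generated independently: no continuity is
#' imposed at the cutoff, because the analysis fits each stage separately
#' and asserts nothing about the joint trajectory.
#'
#' @param n_early,n_late Patients per stage.
#' @param duration_range_early,duration_range_late `(low, high)` disease
#'   duration ranges in years; the Early range must lie at or below
#'   `cutoff`, the Late range strictly above it.
#' @param cutoff Stage cutoff in years (duration <= cutoff is Early).
#' @param regions Character vector of region names, one entry per region
#'   (each is simulated in both hemispheres). Default [destrieux_labels()].
#' @param hemispheres Hemispheres to simulate (default both).
#' @param baseline_early,baseline_late Thickness (mm) at duration 0 for each
#'   stage segment (extrapolated intercept).
#' @param rate_early,rate_late Thinning rate in mm/year (negative =
#'   thinning).
#' @param noise_sd Gaussian measurement noise SD in mm (>= 0). The default
#'   0.15 mm is an assumption: within-region between-subject thickness
#'   spread is not identified by the summary statistics the design emulates.
#' @param handed_proportions Named proportions over `R`, `L`, `NR`
#'   (right-handed, left-handed, not recorded), summing to 1.
#' @param lateralized_proportions Named proportions of patients with marked
#'   `left`- and `right`-predominant motor symptoms; the remainder have
#'   symmetric symptoms.
#' @param laterality_effect Mean shift (UPDRS item score units) between the
#'   worse and better side's extremity items for lateralized patients; the
#'   motor laterality index (right minus left extremity item mean) of a
#'   left-predominant patient has expectation `-laterality_effect`.
#' @param seed Integer RNG seed stored in the configuration; the same
#'   configuration always regenerates identical tables.
#' @return An object of class `"sim_config"`: a validated list with the
#'   above fields plus `region_params`, a data.frame with one row per
#'   thickness column (`key`, `hemisphere`, `region`, expanded per-region
#'   parameters).
#' @seealso [generate_cohort()], [generate_null_cohort()]
#' @examples
#' cfg <- sim_config(regions = c("G_insular_short", "S_orbital_med-olfact"),
#'                   rate_early = -0.05, seed = 1)
#' cfg$region_params
#' @export
sim_config <- function(n_early = 109L,
                       n_late = 96L,
                       duration_range_early = c(2.2, 9.9),
                       duration_range_late = c(10.1, 27.1),
                       cutoff = 10,
                       regions = destrieux_labels(),
                       hemispheres = c("left", "right"),
                       baseline_early = 2.7,
                       baseline_late = 2.7,
                       rate_early = -0.01,
                       rate_late = -0.01,
                       noise_sd = 0.15,
                       handed_proportions = c(R = 0.83, L = 0.10, NR = 0.07),
                       lateralized_proportions = c(left = 0.17, right = 0.16),
                       laterality_effect = 1.0,
                       seed = 1L) {
  if (!is_count(n_early)) fail_field("n_early", "must be a nonnegative count")
  if (!is_count(n_late)) fail_field("n_late", "must be a nonnegative count")
  if (!is_number(cutoff) || cutoff <= 0) {
    fail_field("cutoff", "must be a positive number of years")
  }
  check_range <- function(r, field) {
    if (!is.numeric(r) || length(r) != 2L || any(!is.finite(r))) {
      fail_field(field, "must be a finite (low, high) pair")
    }
    if (r[1] <= 0 || r[2] < r[1]) {
      fail_field(field, "must satisfy 0 < low <= high")
    }
  }
  check_range(duration_range_early, "duration_range_early")
  check_range(duration_range_late, "duration_range_late")
  if (duration_range_early[2] > cutoff) {
    fail_field("duration_range_early",
               "high end %.3g exceeds cutoff %.3g", duration_range_early[2], cutoff)
  }
  if (duration_range_late[1] <= cutoff) {
    fail_field("duration_range_late",
               "low end %.3g is not above cutoff %.3g", duration_range_late[1], cutoff)
  }
  if (!is.character(regions) || length(regions) == 0L) {
    fail_field("regions", "must be a nonempty character vector")
  }
  if (anyDuplicated(regions)) {
    fail_field("regions", "duplicated name(s): %s",
               paste(unique(regions[duplicated(regions)]), collapse = ", "))
  }
  hemispheres <- match.arg(hemispheres, c("left", "right"), several.ok = TRUE)
  if (anyDuplicated(hemispheres)) fail_field("hemispheres", "duplicated entries")
  if (!is.numeric(handed_proportions) ||
      !setequal(names(handed_proportions), c("R", "L", "NR")) ||
      any(handed_proportions < 0) ||
      abs(sum(handed_proportions) - 1) > 1e-6) {
    fail_field("handed_proportions",
               "must be nonnegative proportions named R, L, NR summing to 1")
  }
  if (!is.numeric(lateralized_proportions) ||
      !setequal(names(lateralized_proportions), c("left", "right")) ||
      any(lateralized_proportions < 0) || sum(lateralized_proportions) > 1) {
    fail_field("lateralized_proportions",
               "must be nonnegative proportions named left, right with sum <= 1")
  }
  if (!is_number(laterality_effect) || laterality_effect < 0) {
    fail_field("laterality_effect", "must be a nonnegative number")
  }
  if (!is_count(seed) || seed >= 2147483647) {
    fail_field("seed", "must be an integer in [0, 2^31 - 2]")
  }

  grid <- expand.grid(region = regions, hemisphere = hemispheres,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # column order: all of hemisphere 1, then hemisphere 2
  grid <- grid[order(match(grid$hemisphere, hemispheres)), , drop = FALSE]
  keys <- thickness_key(grid$hemisphere, grid$region)

  expand_param <- function(value, field, lower = -Inf) {
    if (!is.numeric(value) || any(!is.finite(value))) {
      fail_field(field, "must be finite numeric")
    }
    out <- if (length(value) == 1L && is.null(names(value))) {
      rep(unname(value), length(keys))
    } else if (!is.null(names(value))) {
      unknown <- setdiff(names(value), keys)
      if (length(unknown)) {
        fail_field(field, "names not among thickness columns: %s",
                   paste(unknown, collapse = ", "))
      }
      base <- rep(if (is.null(attr(value, "default"))) {
        # named partial override: fall back to the formal's scalar default
        eval(formals(sim_config)[[field]])
      } else attr(value, "default"), length(keys))
      base[match(names(value), keys)] <- unname(value)
      base
    } else if (length(value) == length(keys)) {
      unname(value)
    } else {
      fail_field(field, "length %d does not match %d thickness columns",
                 length(value), length(keys))
    }
    if (any(out < lower)) fail_field(field, "values below %g", lower)
    out
  }

  region_params <- data.frame(
    key = keys,
    hemisphere = grid$hemisphere,
    region = grid$region,
    baseline_early = expand_param(baseline_early, "baseline_early", lower = 0),
    baseline_late = expand_param(baseline_late, "baseline_late", lower = 0),
    rate_early = expand_param(rate_early, "rate_early"),
    rate_late = expand_param(rate_late, "rate_late"),
    noise_sd = expand_param(noise_sd, "noise_sd", lower = 0),
    row.names = NULL
  )

  structure(
    list(
      n_early = as.integer(n_early), n_late = as.integer(n_late),
      duration_range_early = duration_range_early,
      duration_range_late = duration_range_late,
      cutoff = cutoff,
      regions = regions, hemispheres = hemispheres,
      region_params = region_params,
      handed_proportions = handed_proportions[c("R", "L", "NR")],
      lateralized_proportions = lateralized_proportions[c("left", "right")],
      laterality_effect = laterality_effect,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic PD cohort configuration\n")
  cat(sprintf("  patients: %d Early (%.1f-%.1f y), %d Late (%.1f-%.1f y), cutoff %g y\n",
              x$n_early, x$duration_range_early[1], x$duration_range_early[2],
              x$n_late, x$duration_range_late[1], x$duration_range_late[2],
              x$cutoff))
  cat(sprintf("  thickness columns: %d (%d regions x %d hemisphere(s))\n",
              nrow(x$region_params), length(x$regions), length(x$hemispheres)))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Read a simulation configuration from a YAML file
#'
#' Scalar and vector fields are passed to [sim_config()] unchanged; named
#' per-region overrides are expressed as YAML mappings keyed by thickness
#' column name.
#'
#' @param path Path to a YAML file whose top-level keys are [sim_config()]
#'   arguments.
#' @return A `"sim_config"` object.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(formals(sim_config)))
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (f in intersect(names(raw), c("handed_proportions",
                                    "lateralized_proportions",
                                    "baseline_early", "baseline_late",
                                    "rate_early", "rate_late", "noise_sd"))) {
    if (is.list(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  do.call(sim_config, raw)
}

n_ext_items <- 8L # extremity UPDRS items per side: 4 per limb x 2 limbs

#' Generate a synthetic clinical cohort and thickness matrix
#'
#' Draws one clinical record and one regional-thickness row per patient from
#' the process described in [sim_config()]. Thickness for patient i in
#' region column j is
#' `baseline[stage_i, j] + rate[stage_i, j] * duration_i + N(0, noise_sd_j)`,
#' with durations uniform within the stage's range. Extremity UPDRS item
#' scores are integers 0--4 (8 items per side); for patients simulated as
#' motor-lateralized, the worse side's item mean is shifted upward by
#' `laterality_effect / 2` and the better side's down by the same amount.
#' Identical configurations (including seed) reproduce identical tables.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `"sim_cohort"` with components
#'   \describe{
#'     \item{cohort}{data.frame, one row per patient: `patient_id`, `sex`,
#'       `age_assessment`, `age_onset`, `duration`, `handedness`,
#'       `updrs3_off`, `updrs3_on`, `left_ext_1..8`, `right_ext_1..8`,
#'       `stage`, plus `lateralized_side` (generator ground truth).}
#'     \item{thickness}{numeric matrix, patients x thickness columns, in mm;
#'       rownames are patient ids.}
#'     \item{truth}{data.frame of generating parameters per column:
#'       rates, baselines, noise SD, the implied Early-minus-Late mean
#'       difference at the stage duration midpoints
#'       (`group_mean_difference`), and `null_region` flags (all `FALSE`
#'       here; see [generate_null_cohort()]).}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' sim <- generate_cohort(sim_config(n_early = 20, n_late = 15,
#'                                   regions = c("G_insular_short", "G_cuneus"),
#'                                   seed = 42))
#' head(sim$cohort[, 1:7])
#' sim$thickness[1:3, 1:2]
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_early + config$n_late
  if (n == 0L) fail_field("n_early", "cohort has zero patients")
  rp <- config$region_params

  with_seed(config$seed, {
    duration <- c(
      runif(config$n_early, config$duration_range_early[1], config$duration_range_early[2]),
      runif(config$n_late, config$duration_range_late[1], config$duration_range_late[2])
    )
    stage <- assign_stage(duration, cutoff = config$cutoff)
    patient_id <- sprintf("P%04d", seq_len(n))

    sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.67, 0.33))
    # onset-age means per stage follow the emulated cohort: late-stage
    # patients started younger
    age_onset <- round(ifelse(stage == "Early",
                              rnorm(n, 54.4, 9.2), rnorm(n, 49.3, 8.5)), 1)
    age_onset <- pmin(pmax(age_onset, 26), 78)
    age_assessment <- round(age_onset + duration, 1)
    handedness <- sample(c("R", "L", "NR"), n, replace = TRUE,
                         prob = config$handed_proportions)

    p_lat <- config$lateralized_proportions
    lateralized_side <- sample(c("left", "right", "none"), n, replace = TRUE,
                               prob = c(p_lat, none = 1 - sum(p_lat)))
    base_item_mean <- 1.6 # typical per-item extremity score in the Off state
    shift <- config$laterality_effect / 2
    item_mean_left <- base_item_mean +
      ifelse(lateralized_side == "left", shift,
             ifelse(lateralized_side == "right", -shift, 0))
    item_mean_right <- base_item_mean +
      ifelse(lateralized_side == "right", shift,
             ifelse(lateralized_side == "left", -shift, 0))
    draw_items <- function(item_mean) {
      p <- pmin(pmax(item_mean / 4, 0.01), 0.99)
      m <- matrix(rbinom(n * n_ext_items, size = 4L, prob = rep(p, n_ext_items)),
                  nrow = n)
      m
    }
    left_items <- draw_items(item_mean_left)
    right_items <- draw_items(item_mean_right)
    colnames(left_items) <- paste0("left_ext_", seq_len(n_ext_items))
    colnames(right_items) <- paste0("right_ext_", seq_len(n_ext_items))

    updrs3_off <- round(pmin(pmax(rnorm(n, 41.1, 12.6), 12), 84))
    improvement <- round(pmin(pmax(
      ifelse(stage == "Early", rnorm(n, 20.1, 9.5), rnorm(n, 24.5, 10.6)), 2), 58))
    updrs3_on <- pmax(updrs3_off - improvement, 0)

    k <- nrow(rp)
    is_late <- stage == "Late"
    baseline <- matrix(rep(rp$baseline_early, each = n), n, k)
    rate <- matrix(rep(rp$rate_early, each = n), n, k)
    if (any(is_late)) {
      baseline[is_late, ] <- matrix(rep(rp$baseline_late, each = sum(is_late)),
                                    sum(is_late), k)
      rate[is_late, ] <- matrix(rep(rp$rate_late, each = sum(is_late)),
                                sum(is_late), k)
    }
    noise <- matrix(rnorm(n * k), n, k) * rep(rp$noise_sd, each = n)
    thickness <- baseline + rate * duration + noise
    dimnames(thickness) <- list(patient_id, rp$key)

    cohort <- data.frame(
      patient_id = patient_id, sex = sex,
      age_assessment = age_assessment, age_onset = age_onset,
      duration = duration, handedness = handedness,
      updrs3_off = updrs3_off, updrs3_on = updrs3_on,
      left_items, right_items,
      stage = stage, lateralized_side = lateralized_side,
      stringsAsFactors = FALSE
    )

    mid_early <- mean(config$duration_range_early)
    mid_late <- mean(config$duration_range_late)
    truth <- data.frame(
      key = rp$key, hemisphere = rp$hemisphere, region = rp$region,
      rate_early = rp$rate_early, rate_late = rp$rate_late,
      baseline_early = rp$baseline_early, baseline_late = rp$baseline_late,
      noise_sd = rp$noise_sd,
      group_mean_difference =
        (rp$baseline_early + rp$rate_early * mid_early) -
        (rp$baseline_late + rp$rate_late * mid_late),
      null_region = FALSE,
      row.names = NULL
    )

    structure(list(cohort = cohort, thickness = thickness, truth = truth,
                   config = config),
              class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic PD cohort: %d patients (%d Early / %d Late), %d thickness columns\n",
              nrow(x$cohort), sum(x$cohort$stage == "Early"),
              sum(x$cohort$stage == "Late"), ncol(x$thickness)))
  invisible(x)
}

#' Generate a null/signal mixture cohort for FDR calibration
#'
#' Builds a cohort in which a chosen number of regions per hemisphere are
#' exact nulls — identical generating distribution in both stages (common
#' baseline, zero thinning rate in both segments) — while the remaining
#' `n_signal_regions` carry a fixed Early-minus-Late mean contrast
#' (`signal_difference`, applied symmetrically as +/- half to the two stage
#' baselines). Regions beyond `n_null_regions + n_signal_regions` are
#' dropped. The `truth$null_region` flags mark the null columns, supporting
#' empirical false-discovery-rate measurement against known ground truth.
#'
#' @param config A [sim_config()] object; its per-region baselines/rates are
#'   overridden as described, its region list (per hemisphere) is truncated.
#' @param n_null_regions,n_signal_regions Counts per hemisphere.
#' @param signal_difference True Early-minus-Late mean thickness contrast
#'   (mm) in signal regions.
#' @return A `"sim_cohort"` list as in [generate_cohort()], with
#'   `truth$null_region` set and `truth$group_mean_difference` equal to 0
#'   for nulls and `signal_difference` for signal regions.
#' @examples
#' cfg <- sim_config(n_early = 30, n_late = 30,
#'                   regions = paste0("region_", 1:6), seed = 7)
#' sim <- generate_null_cohort(cfg, n_null_regions = 4, n_signal_regions = 2)
#' table(sim$truth$null_region)
#' @export
generate_null_cohort <- function(config, n_null_regions, n_signal_regions,
                                 signal_difference = 0.1) {
  stopifnot(inherits(config, "sim_config"))
  if (!is_count(n_null_regions)) fail_field("n_null_regions", "must be a count")
  if (!is_count(n_signal_regions)) fail_field("n_signal_regions", "must be a count")
  if (!is_number(signal_difference)) {
    fail_field("signal_difference", "must be a finite number")
  }
  total <- n_null_regions + n_signal_regions
  if (total > length(config$regions)) {
    stop(sprintf(
      "n_null_regions + n_signal_regions = %d exceeds the %d configured regions per hemisphere",
      total, length(config$regions)), call. = FALSE)
  }
  if (total < 1) stop("at least one region must be generated", call. = FALSE)

  regions <- config$regions[seq_len(total)]
  is_null_region <- rep(c(TRUE, FALSE), c(n_null_regions, n_signal_regions))

  cfg <- config
  cfg$regions <- regions
  rp <- cfg$region_params
  rp <- rp[rp$region %in% regions, , drop = FALSE]
  flag <- is_null_region[match(rp$region, regions)]
  rp$rate_early <- 0
  rp$rate_late <- 0
  rp$baseline_late <- ifelse(flag, rp$baseline_early,
                             rp$baseline_early - signal_difference / 2)
  rp$baseline_early <- ifelse(flag, rp$baseline_early,
                              rp$baseline_early + signal_difference / 2)
  row.names(rp) <- NULL
  cfg$region_params <- rp

  out <- generate_cohort(cfg)
  out$truth$null_region <- flag
  # zero rates: the implied mean contrast is exactly the baseline contrast
  out$truth$group_mean_difference <- ifelse(flag, 0, signal_difference)
  out
}
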