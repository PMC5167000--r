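#' Configure a full analysis run
#'
#' Collects the analysis constants (stage cutoff, FDR level, CI level,
#' bootstrap size, master seed), the input table paths and the output
#' directory into a validated configuration object. `read_pipeline_config()`
#' loads the same fields from a YAML file.
#'
#' @param clinical Path to the clinical CSV (see [read_clinical()]).
#' @param thickness Path to the thickness TSV (see [read_thickness()]).
#' @param out_dir Output directory for result CSVs and metadata; `NULL`
#'   keeps results in memory only.
#' @param cutoff Stage cutoff in years (default 10).
#' @param q FDR level for the per-hemisphere group comparison (default 0.1).
#' @param alpha CI level complement for bootstrap CIs (default 0.05).
#' @param n_boot Bootstrap replicates (default 2000, >= 200).
#' @param seed Master seed for every stochastic step.
#' @param subgroups Subgroup labels for the laterality analyses (subset of
#'   `left-handed`, `right-handed`, `motor-left`, `motor-right`).
#' @param laterality_regions Region names for the paired left/right
#'   comparison in motor-lateralized subgroups.
#' @param var_equal Use pooled-variance t-tests instead of Welch.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(clinical, thickness, out_dir = NULL,
                            cutoff = 10, q = 0.1, alpha = 0.05,
                            n_boot = 2000L, seed = 1L,
                            subgroups = c("left-handed", "right-handed",
                                          "motor-left", "motor-right"),
                            laterality_regions = c("G_insular_short",
                                                   "S_orbital_med-olfact"),
                            var_equal = FALSE) {
  if (!is_number(q) || q <= 0 || q >= 1) fail_field("q", "must lie in (0, 1)")
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1) {
    fail_field("alpha", "must lie in (0, 1)")
  }
  if (!is_count(n_boot) || n_boot < 200) {
    fail_field("n_boot", "must be an integer >= 200")
  }
  if (!is_number(cutoff) || cutoff <= 0) fail_field("cutoff", "must be positive")
  if (!is_count(seed) || seed >= 2147483647) {
    fail_field("seed", "must be an integer in [0, 2^31 - 2]")
  }
  subgroups <- match.arg(subgroups, c("left-handed", "right-handed",
                                      "motor-left", "motor-right"),
                         several.ok = TRUE)
  structure(
    list(clinical = clinical, thickness = thickness, out_dir = out_dir,
         cutoff = cutoff, q = q, alpha = alpha, n_boot = as.integer(n_boot),
         seed = as.integer(seed), subgroups = subgroups,
         laterality_regions = laterality_regions,
         var_equal = isTRUE(var_equal)),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path Path to a YAML file with `pipeline_config()` fields.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(formals(pipeline_config)))
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (f in c("subgroups", "laterality_regions")) {
    if (is.list(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  do.call(pipeline_config, raw)
}

#' Cohort characterization table
#'
#' Mean (SD) and range of the clinical covariates, overall and per stage,
#' plus sex and handedness splits — the standard cohort-description table.
#'
#' @param cohort Staged cohort data.frame.
#' @return data.frame with one row per characteristic and columns for the
#'   total group and each stage.
#' @export
cohort_summary <- function(cohort) {
  stopifnot(is.data.frame(cohort), "stage" %in% names(cohort))
  groups <- list(Total = rep(TRUE, nrow(cohort)),
                 Early = cohort$stage == "Early",
                 Late = cohort$stage == "Late")
  msd <- function(v) sprintf("%.1f (%.1f)", mean(v), sd(v))
  rng <- function(v) sprintf("%.1f-%.1f", min(v), max(v))
  improvement <- cohort$updrs3_off - cohort$updrs3_on
  rows <- list(
    c("n", lapply(groups, function(g) sprintf("%d", sum(g)))),
    c("Gender (M:F)", lapply(groups, function(g)
      sprintf("%d:%d", sum(cohort$sex[g] == "M"), sum(cohort$sex[g] == "F")))),
    c("Age at assessment (years)", lapply(groups, function(g) msd(cohort$age_assessment[g]))),
    c("Age at motor onset (years)", lapply(groups, function(g) msd(cohort$age_onset[g]))),
    c("Disease duration (years)", lapply(groups, function(g) msd(cohort$duration[g]))),
    c("Disease duration range (years)", lapply(groups, function(g) rng(cohort$duration[g]))),
    c("UPDRS III Off", lapply(groups, function(g) msd(cohort$updrs3_off[g]))),
    c("UPDRS III On", lapply(groups, function(g) msd(cohort$updrs3_on[g]))),
    c("UPDRS improvement", lapply(groups, function(g) msd(improvement[g]))),
    c("Handedness (R:L:NR)", lapply(groups, function(g)
      sprintf("%d:%d:%d", sum(cohort$handedness[g] == "R"),
              sum(cohort$handedness[g] == "L"),
              sum(cohort$handedness[g] == "NR"))))
  )
  out <- data.frame(
    characteristic = vapply(rows, function(r) r[[1]], ""),
    total = vapply(rows, function(r) r$Total, ""),
    early = vapply(rows, function(r) r$Early, ""),
    late = vapply(rows, function(r) r$Late, ""),
    row.names = NULL
  )
  out
}

#' Run the full analysis pipeline
#'
#' End-to-end orchestration: read and cross-validate the clinical and
#' thickness tables, stage patients at the cutoff, build the cohort
#' summary, run the per-region Early/Late comparison with per-hemisphere
#' FDR control, fit stage-wise atrophy rates and bootstrapped slope
#' differences, and run the laterality sub-analyses (duration-thickness
#' correlations per handedness subgroup within Early-stage patients;
#' paired left/right comparisons in motor-lateralized subgroups). Every
#' result table carries the configuration hash; all randomness derives
#' from the master seed, so reruns with the same configuration are
#' identical. When `out_dir` is set, results are written as tidy CSVs plus
#' a JSON metadata file recording the configuration and every default.
#'
#' Any stage failure aborts with a message tagged by the stage name
#' (`[read]`, `[summary]`, `[compare]`, `[rates]`, `[laterality]`,
#' `[write]`).
#'
#' @param config A [pipeline_config()] object (or path to its YAML file).
#' @return An object of class `"result_bundle"`: list with `cohort_summary`,
#'   `comparisons`, `rates`, `slope_differences`, `correlations`,
#'   `paired_tests`, and `metadata`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(unclass(config))
  stage_call <- function(tag, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", tag, conditionMessage(e)), call. = FALSE)
    })
  }

  dat <- stage_call("read", {
    clinical <- read_clinical(config$clinical, cutoff = config$cutoff)
    thickness <- read_thickness(config$thickness, clinical = clinical)
    list(clinical = clinical, thickness = thickness)
  })
  summary_tab <- stage_call("summary", cohort_summary(dat$clinical))
  comparisons <- stage_call("compare",
    compare_regions(dat$clinical, dat$thickness, q = config$q,
                    cutoff = config$cutoff, var_equal = config$var_equal,
                    conf_level = 1 - config$alpha))
  fit <- stage_call("rates",
    atrophy_rates(dat$clinical, dat$thickness, cutoff = config$cutoff,
                  n_boot = config$n_boot, alpha = config$alpha,
                  seed = config$seed))

  laterality_res <- stage_call("laterality", {
    cols <- parse_thickness_key(colnames(dat$thickness))
    hand_groups <- intersect(config$subgroups, c("left-handed", "right-handed"))
    cors <- list()
    for (sg in hand_groups) {
      keep <- resolve_subgroup(dat$clinical, sg)$keep &
        dat$clinical$stage == "Early"
      if (sum(keep) < 3L) next
      for (j in seq_len(nrow(cols))) {
        res <- tryCatch(
          duration_correlation(dat$clinical, dat$thickness, cols$region[j],
                               cols$hemisphere[j], subgroup = keep),
          error = function(e) NULL)
        if (!is.null(res)) {
          res$subgroup <- paste0(sg, "/Early")
          cors[[length(cors) + 1L]] <- res
        }
      }
    }
    motor_groups <- intersect(config$subgroups, c("motor-left", "motor-right"))
    paired <- list()
    pair_regions <- intersect(config$laterality_regions,
                              homologous_pairs(dat$thickness)$region)
    for (sg in motor_groups) {
      for (reg in pair_regions) {
        res <- tryCatch(
          paired_hemisphere_test(dat$clinical, dat$thickness, reg,
                                 subgroup = sg),
          error = function(e) NULL)
        if (!is.null(res)) paired[[length(paired) + 1L]] <- res
      }
    }
    list(correlations = if (length(cors)) do.call(rbind, cors) else NULL,
         paired = if (length(paired)) do.call(rbind, paired) else NULL)
  })

  add_hash <- function(df) {
    if (is.null(df) || !nrow(df)) return(df)
    df$config_hash <- hash
    df
  }
  bundle <- structure(
    list(
      cohort_summary = add_hash(summary_tab),
      comparisons = add_hash(comparisons),
      rates = add_hash(fit$rates),
      slope_differences = add_hash(fit$differences),
      correlations = add_hash(laterality_res$correlations),
      paired_tests = add_hash(laterality_res$paired),
      fit = fit,
      metadata = list(
        config = unclass(config), config_hash = hash,
        defaults = list(
          ci_method = "percentile bootstrap",
          resampling = "patients with replacement within stage",
          t_test = if (config$var_equal) "pooled-variance" else "Welch",
          fdr = "Benjamini-Hochberg step-up, per hemisphere",
          paired_test = "paired t on within-patient left-right differences"
        ),
        n = as.list(fit$n),
        package_version = as.character(packageVersion("cortasym")),
        timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
      )
    ),
    class = "result_bundle"
  )

  if (!is.null(config$out_dir)) {
    stage_call("write", {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      tabs <- c("cohort_summary", "comparisons", "rates",
                "slope_differences", "correlations", "paired_tests")
      for (tb in tabs) {
        if (!is.null(bundle[[tb]])) {
          write.csv(bundle[[tb]], file.path(config$out_dir,
                                            paste0(tb, ".csv")),
                    row.names = FALSE)
        }
      }
      jsonlite::write_json(bundle$metadata,
                           file.path(config$out_dir, "metadata.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    })
  }
  bundle
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("cortasym result bundle\n")
  cat(sprintf("  config hash %s, seed %d\n", x$metadata$config_hash,
              x$metadata$config$seed))
  cat(sprintf("  patients: %d Early / %d Late\n",
              x$metadata$n$early, x$metadata$n$late))
  cat(sprintf("  comparisons: %d regions, %d discoveries at q = %g\n",
              nrow(x$comparisons), sum(x$comparisons$discovery),
              x$metadata$config$q))
  cat(sprintf("  slope differences: %d significant early, %d significant late\n",
              sum(x$slope_differences$significant_early),
              sum(x$slope_differences$significant_late)))
  invisible(x)
}

#' Export one per-region metric for surface mapping
#'
#' Flattens one metric of a result bundle into a per-region CSV-ready
#' table keyed by Destrieux region name and hemisphere, suitable for
#' joining onto any parcellation lookup (e.g. for rendering on a brain
#' surface with external tools).
#'
#' @param bundle A [run_pipeline()] result.
#' @param metric One of `rate_early`, `rate_late`, `slope_difference`,
#'   `mean_difference`, `p_value`, `q_value`.
#' @param path Optional path; when given, the table is also written as CSV.
#' @return data.frame: `region`, `hemisphere`, `value`.
#' @export
export_region_values <- function(bundle, metric, path = NULL) {
  stopifnot(inherits(bundle, "result_bundle"))
  metrics <- c("rate_early", "rate_late", "slope_difference",
               "mean_difference", "p_value", "q_value")
  if (!is.character(metric) || length(metric) != 1L || !metric %in% metrics) {
    stop("unknown metric '", metric, "'; valid metrics: ",
         paste(metrics, collapse = ", "), call. = FALSE)
  }
  out <- switch(
    metric,
    rate_early = {
      r <- bundle$rates[bundle$rates$stage == "Early", ]
      data.frame(region = r$region, hemisphere = r$hemisphere, value = r$slope)
    },
    rate_late = {
      r <- bundle$rates[bundle$rates$stage == "Late", ]
      data.frame(region = r$region, hemisphere = r$hemisphere, value = r$slope)
    },
    slope_difference = with(bundle$slope_differences,
      data.frame(region = region, hemisphere = hemisphere, value = difference)),
    mean_difference = with(bundle$comparisons,
      data.frame(region = region, hemisphere = hemisphere, value = difference)),
    p_value = with(bundle$comparisons,
      data.frame(region = region, hemisphere = hemisphere, value = p_value)),
    q_value = with(bundle$comparisons,
      data.frame(region = region, hemisphere = hemisphere, value = q_value))
  )
  row.names(out) <- NULL
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}
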