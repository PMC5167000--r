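#' Assign disease stage from duration
#'
#' Patients with disease duration at or below the cutoff are Early stage;
#' those above it are Late. The boundary itself (duration exactly equal to
#' the cutoff) is Early.
#'
#' @param duration Numeric vector of disease durations in years (> 0).
#' @param cutoff Stage cutoff in years (default 10).
#' @return Character vector of `"Early"` / `"Late"`.
#' @examples
#' assign_stage(c(9.9, 10, 10.1))
#' @export
assign_stage <- function(duration, cutoff = 10) {
  if (!is.numeric(duration) || any(!is.finite(duration))) {
    stop("`duration` must be finite numeric", call. = FALSE)
  }
  if (any(duration <= 0)) {
    stop("`duration` must be positive (years since first motor symptom); got ",
         paste(utils::head(duration[duration <= 0], 3), collapse = ", "),
         call. = FALSE)
  }
  if (!is_number(cutoff) || cutoff <= 0) stop("`cutoff` must be positive", call. = FALSE)
  ifelse(duration <= cutoff, "Early", "Late")
}

clinical_required_cols <- c("patient_id", "sex", "age_assessment", "age_onset",
                            "duration", "handedness", "updrs3_off", "updrs3_on")

#' Read and validate a clinical table
#'
#' Reads the clinical CSV (one row per patient) with the header
#' `patient_id,sex,age_assessment,age_onset,duration,handedness,updrs3_off,`
#' `updrs3_on,left_ext_1..k,right_ext_1..k`, validates it, maps any
#' handedness value outside `R`/`L` to `NR` (not recorded) with a warning
#' reporting the count, and derives the `stage` column at `cutoff`.
#'
#' @param path Path to a CSV file with a header row.
#' @param cutoff Stage cutoff in years passed to [assign_stage()].
#' @return A validated data.frame (`CohortTable`): the input columns, typed,
#'   plus `stage`.
#' @examples
#' sim <- generate_cohort(sim_config(n_early = 5, n_late = 5,
#'                                   regions = "G_cuneus", seed = 1))
#' f <- tempfile(fileext = ".csv")
#' write_clinical(sim$cohort, f)
#' nrow(read_clinical(f))
#' @export
read_clinical <- function(path, cutoff = 10) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(clinical_required_cols, names(df))
  if (length(missing_cols)) {
    stop("clinical table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$patient_id)) {
    stop("duplicate patient_id(s): ",
         paste(unique(df$patient_id[duplicated(df$patient_id)]), collapse = ", "),
         call. = FALSE)
  }
  for (col in c("age_assessment", "age_onset", "duration",
                "updrs3_off", "updrs3_on")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- is.na(v) & !is.na(df[[col]]) & df[[col]] != ""
    if (any(bad)) {
      stop(sprintf("non-numeric value(s) in `%s`: %s", col,
                   paste(utils::head(df[[col]][bad], 3), collapse = ", ")),
           call. = FALSE)
    }
    df[[col]] <- v
  }
  left_cols <- grep("^left_ext_[0-9]+$", names(df), value = TRUE)
  right_cols <- grep("^right_ext_[0-9]+$", names(df), value = TRUE)
  if (length(left_cols) != length(right_cols)) {
    stop(sprintf("unbalanced extremity score columns: %d left vs %d right",
                 length(left_cols), length(right_cols)), call. = FALSE)
  }
  for (col in c(left_cols, right_cols)) df[[col]] <- as.numeric(df[[col]])

  unmapped <- !(df$handedness %in% c("R", "L", "NR")) | is.na(df$handedness)
  if (any(unmapped)) {
    warning(sprintf("%d handedness value(s) outside {R, L} mapped to NR",
                    sum(unmapped)), call. = FALSE)
    df$handedness[unmapped] <- "NR"
  }
  ok_onset <- is.na(df$age_onset) | is.na(df$age_assessment) |
    df$age_onset < df$age_assessment
  if (!all(ok_onset)) {
    stop("age_onset must be below age_assessment; offending patient_id(s): ",
         paste(utils::head(df$patient_id[!ok_onset], 3), collapse = ", "),
         call. = FALSE)
  }
  df$stage <- assign_stage(df$duration, cutoff = cutoff)
  df
}

#' @rdname read_clinical
#' @param cohort A cohort data.frame (e.g. from [generate_cohort()]).
#' @export
write_clinical <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  drop <- intersect(c("stage", "lateralized_side"), names(cohort))
  write.csv(cohort[, setdiff(names(cohort), drop), drop = FALSE],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a regional thickness table
#'
#' Reads a TSV in the FreeSurfer `aparcstats2table` dialect: first column
#' the subject id, remaining columns named `<lh|rh>_<region>_thickness`
#' holding mean regional cortical thickness in mm. Values are screened for
#' plausibility (0 < thickness < 6 mm). If a clinical table is supplied,
#' subject ids must match it exactly (mismatches are reported, not
#' dropped), and rows are reordered to the clinical table's patient order.
#'
#' @param path Path to the TSV file.
#' @param clinical Optional clinical data.frame (see [read_clinical()]) to
#'   align subjects against.
#' @return Numeric matrix (subjects x thickness columns) with subject ids as
#'   rownames (`ThicknessMatrix`).
#' @examples
#' sim <- generate_cohort(sim_config(n_early = 5, n_late = 5,
#'                                   regions = "G_cuneus", seed = 1))
#' f <- tempfile(fileext = ".tsv")
#' write_thickness(sim$thickness, f)
#' dim(read_thickness(f))
#' @export
read_thickness <- function(path, clinical = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("thickness table needs a subject column plus at least one region column",
                          call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate subject id(s) in thickness table", call. = FALSE)
  }
  keys <- names(df)[-1L]
  parse_thickness_key(keys) # errors on unparseable names
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric thickness values", call. = FALSE)
  rownames(mat) <- ids
  implausible <- !is.na(mat) & (mat <= 0 | mat >= 6)
  if (any(implausible)) {
    idx <- which(implausible, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "implausible thickness value %.3g mm (subject %s, column %s); expected 0 < mm < 6",
      mat[implausible][1L], ids[idx[1L]], keys[idx[2L]]), call. = FALSE)
  }
  if (!is.null(clinical)) {
    only_thick <- setdiff(ids, clinical$patient_id)
    only_clin <- setdiff(clinical$patient_id, ids)
    if (length(only_thick) || length(only_clin)) {
      stop("subject id mismatch between tables; only in thickness: [",
           paste(only_thick, collapse = ", "), "]; only in clinical: [",
           paste(only_clin, collapse = ", "), "]", call. = FALSE)
    }
    mat <- mat[match(clinical$patient_id, ids), , drop = FALSE]
  }
  mat
}

#' @rdname read_thickness
#' @param thickness Numeric matrix with subject rownames and
#'   `<hemi>_<region>_thickness` column names.
#' @export
write_thickness <- function(thickness, path) {
  stopifnot(is.matrix(thickness), !is.null(rownames(thickness)),
            !is.null(colnames(thickness)))
  df <- data.frame(subject = rownames(thickness), thickness,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Motor laterality index and lateralized-subgroup selection
#'
#' Computes, per patient, the signed motor laterality index: the mean of
#' the right-extremity UPDRS Off item scores minus the mean of the
#' left-extremity item scores, so a negative index indicates predominant
#' left-sided motor symptoms. Patients whose index lies more than
#' `threshold_sd` cohort standard deviations from the cohort mean form the
#' lateralized subgroups; the side is taken from the index sign (negative =
#' left-predominant). The mean and SD are computed over all patients with
#' extremity scores (the total PD population), not within any subgroup.
#'
#' @param cohort Cohort data.frame with `left_ext_*` / `right_ext_*`
#'   columns.
#' @param threshold_sd Selection threshold in cohort SD units (default 1).
#' @return data.frame with one row per patient: `patient_id`, `index`,
#'   `side` (`left-predominant`, `right-predominant` or `none`) and
#'   `selected`.
#' @examples
#' sim <- generate_cohort(sim_config(n_early = 40, n_late = 30,
#'                                   regions = "G_cuneus",
#'                                   laterality_effect = 2, seed = 3))
#' table(motor_laterality(sim$cohort)$side)
#' @export
motor_laterality <- function(cohort, threshold_sd = 1) {
  stopifnot(is.data.frame(cohort))
  if (!is_number(threshold_sd) || threshold_sd < 0) {
    stop("`threshold_sd` must be a nonnegative number", call. = FALSE)
  }
  left_cols <- grep("^left_ext_[0-9]+$", names(cohort), value = TRUE)
  right_cols <- grep("^right_ext_[0-9]+$", names(cohort), value = TRUE)
  if (!length(left_cols) || !length(right_cols)) {
    stop("cohort has no extremity score columns (left_ext_*/right_ext_*)",
         call. = FALSE)
  }
  left_mean <- rowMeans(as.matrix(cohort[, left_cols, drop = FALSE]))
  right_mean <- rowMeans(as.matrix(cohort[, right_cols, drop = FALSE]))
  index <- right_mean - left_mean
  centre <- mean(index)
  spread <- sd(index)
  if (!is.finite(spread) || spread == 0) {
    # every patient has the same index: nobody deviates from the cohort
    # mean, so the SD-based criterion selects no one
    warning("cohort SD of the laterality index is zero; no patients selected",
            call. = FALSE)
    selected <- rep(FALSE, length(index))
  } else {
    selected <- abs(index - centre) > threshold_sd * spread
  }
  side <- ifelse(!selected, "none",
                 ifelse(index < 0, "left-predominant", "right-predominant"))
  data.frame(patient_id = cohort$patient_id, index = index,
             side = side, selected = selected, row.names = NULL)
}
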