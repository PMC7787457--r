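# Longitudinal cohort data model: one row per patient per 6-month time step.
#
# A cohort is an ordinary tibble with a fixed column contract so that it
# composes with dplyr verbs; constructors attach the "hf_cohort" class after
# validation. Time is discretized into half-open 6-month age bins
# [k * 0.5, (k + 1) * 0.5); a bin with at least one HF hospitalization gets
# hf = 1. Chronic co-morbidities are absorbing (1 from onset onward), acute
# co-morbidities flag only bins containing an event, and surgery is a
# cumulative count collapsed across complexity levels.

#' Column names of the cohort table
#'
#' The canonical column order of a longitudinal cohort file: patient and step
#' identifiers, the 19 covariates (age, one-hot sex, one-hot CHD lesion type,
#' 11 co-morbidity indicators, surgery count), and the binary HF label.
#'
#' @return Character vector of column names.
#' @export
cohort_columns <- function() {
  c("patient_id", "step", covariate_columns(), "hf")
}

#' @rdname cohort_columns
#' @export
covariate_columns <- function() {
  c("age", "sex_m", "sex_f",
    "lesion_severe", "lesion_shunt", "lesion_valve", "lesion_other",
    cm_columns(), "surgery")
}

#' @rdname cohort_columns
#' @export
cm_columns <- function() {
  c("cm_acute_mi", "cm_cad", "cm_arrhythmia", "cm_vent_arrhythmia",
    "cm_pulm_htn", "cm_endocarditis", "cm_diabetes", "cm_stroke",
    "cm_liver", "cm_kidney", "cm_sepsis")
}

#' @rdname cohort_columns
#' @export
acute_cm_columns <- function() {
  c("cm_acute_mi", "cm_endocarditis", "cm_sepsis")
}

#' @rdname cohort_columns
#' @export
static_cm_columns <- function() {
  setdiff(cm_columns(), acute_cm_columns())
}

binary_columns <- function() {
  c("sex_m", "sex_f",
    "lesion_severe", "lesion_shunt", "lesion_valve", "lesion_other",
    cm_columns(), "hf")
}

#' Construct and validate a cohort
#'
#' Validates the cohort invariants (one-hot sex, at least one lesion
#' indicator, binary co-morbidity and HF columns, consecutive step indices,
#' age advancing by exactly 0.5 years per step, static co-morbidities
#' constant along each timeline, timelines of length >= 2) and returns the
#' table ordered by patient then step with class `hf_cohort`.
#'
#' @param x A data frame with the columns of [cohort_columns()] (a `split`
#'   column is allowed and preserved).
#' @return A validated `hf_cohort` tibble.
#' @export
as_cohort <- function(x) {
  x <- as_tibble(x)
  validate_cohort(x)
  x <- dplyr::arrange(x, .data$patient_id, .data$step)
  class(x) <- unique(c("hf_cohort", class(x)))
  x
}

#' @rdname as_cohort
#' @export
validate_cohort <- function(x) {
  missing_cols <- setdiff(cohort_columns(), names(x))
  if (length(missing_cols) > 0) {
    stop_hftraj(
      paste0("cohort schema error: missing column(s) ",
             paste(missing_cols, collapse = ", ")),
      "schema_error"
    )
  }
  if (nrow(x) == 0) return(invisible(x))

  for (col in binary_columns()) {
    bad <- which(!x[[col]] %in% c(0, 1))
    if (length(bad) > 0) {
      stop_hftraj(
        sprintf("validation error: non-binary value in column '%s' at row %d",
                col, bad[1]),
        "validation_error"
      )
    }
  }
  bad_sex <- which(x$sex_m + x$sex_f != 1)
  if (length(bad_sex) > 0) {
    stop_hftraj(
      sprintf("validation error: sex indicators must be one-hot (row %d)",
              bad_sex[1]),
      "validation_error"
    )
  }
  lesion_sum <- x$lesion_severe + x$lesion_shunt + x$lesion_valve + x$lesion_other
  bad_lesion <- which(!lesion_sum %in% c(1, 2))
  if (length(bad_lesion) > 0) {
    stop_hftraj(
      sprintf("validation error: lesion indicators must sum to 1 or 2 (row %d)",
              bad_lesion[1]),
      "validation_error"
    )
  }
  if (any(x$surgery < 0) || any(x$surgery != round(x$surgery))) {
    stop_hftraj("validation error: surgery must be a non-negative integer count",
                "validation_error")
  }

  by_patient <- split(seq_len(nrow(x)), x$patient_id)
  for (idx in by_patient) {
    idx <- idx[order(x$step[idx])]
    pid <- x$patient_id[idx[1]]
    steps <- x$step[idx]
    if (length(idx) < 2) {
      stop_hftraj(
        sprintf("validation error: patient '%s' has fewer than 2 time steps", pid),
        "validation_error"
      )
    }
    if (!identical(as.numeric(steps), as.numeric(seq_along(steps) - 1))) {
      stop_hftraj(
        sprintf("validation error: patient '%s' steps are not consecutive from 0", pid),
        "validation_error"
      )
    }
    ages <- x$age[idx]
    if (any(abs(diff(ages) - 0.5) > 1e-8)) {
      stop_hftraj(
        sprintf("validation error: patient '%s' age does not advance by 0.5 per step", pid),
        "validation_error"
      )
    }
    for (col in static_cm_columns()) {
      if (length(unique(x[[col]][idx])) > 1 && any(diff(x[[col]][idx]) < 0)) {
        stop_hftraj(
          sprintf("validation error: static co-morbidity '%s' regresses for patient '%s'",
                  col, pid),
          "validation_error"
        )
      }
    }
  }
  invisible(x)
}

#' Read a longitudinal cohort from CSV
#'
#' One row per (patient, time step); UTF-8, "." decimal, no index column.
#' Columns can be remapped through `schema` when the file uses different
#' headers.
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names (names) to the file's column names (values).
#' @return A validated `hf_cohort` tibble.
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    stop_hftraj(paste0("file not found: ", path), "io_error")
  }
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    missing_src <- setdiff(unname(schema), names(x))
    if (length(missing_src) > 0) {
      stop_hftraj(
        paste0("cohort schema error: mapped column(s) absent from file: ",
               paste(missing_src, collapse = ", ")),
        "schema_error"
      )
    }
    names(x)[match(unname(schema), names(x))] <- names(schema)
  }
  as_cohort(x)
}

#' Write a cohort to CSV
#'
#' Deterministic column order ([cohort_columns()], plus `split` when
#' present) and row order (patient id, then step index), so that
#' write/read round trips are byte-identical on canonical files.
#'
#' @param cohort A validated cohort.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cols <- cohort_columns()
  if ("split" %in% names(cohort)) cols <- c(cols, "split")
  out <- dplyr::arrange(as_tibble(cohort)[cols], .data$patient_id, .data$step)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Restrict timelines to an age window
#'
#' Drops all time steps before `min_age` years, re-bases the surviving step
#' indices at 0, and removes patients left with fewer than 2 steps. Most HF
#' hospitalizations in congenital heart disease occur in adulthood, so
#' modelling starts at age 40 by default.
#'
#' @param cohort A cohort.
#' @param min_age Minimum age in years (default 40).
#' @return A cohort restricted to steps with age >= `min_age`.
#' @export
restrict_to_age_window <- function(cohort, min_age = 40) {
  out <- as_tibble(cohort) |>
    dplyr::filter(.data$age >= min_age - 1e-9) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::arrange(.data$step, .by_group = TRUE) |>
    dplyr::mutate(step = dplyr::row_number() - 1L) |>
    dplyr::ungroup()
  if (nrow(out) == 0) {
    class(out) <- unique(c("hf_cohort", class(out)))
    return(out)
  }
  as_cohort(out)
}

#' Encode a patient timeline into model inputs and next-step targets
#'
#' The recurrent models consume, at each step i, a 20-dimensional input
#' vector: the 19 covariates at step i followed by the observed HF label at
#' step i. The target is the HF label at step i + 1 (teacher forcing); for
#' the co-morbidity-augmented model the target additionally carries the 3
#' acute co-morbidity indicators at step i + 1.
#'
#' @param timeline A single patient's rows of a cohort (length >= 2).
#' @param include_cm_targets If `TRUE`, targets are a 4-column matrix
#'   (`hf`, then the acute co-morbidities); otherwise a numeric vector.
#' @param age_scale Multiplier applied to the age column (models store the
#'   value they were trained with; 1 leaves ages in years).
#' @return A list with `inputs` ((T-1) x 20 matrix) and `targets`.
#' @export
encode_inputs <- function(timeline, include_cm_targets = FALSE, age_scale = 1) {
  timeline <- as_tibble(timeline)
  if (length(unique(timeline$patient_id)) > 1) {
    stop_hftraj("encode_inputs expects a single patient timeline", "contract_error")
  }
  timeline <- dplyr::arrange(timeline, .data$step)
  T_len <- nrow(timeline)
  if (T_len < 2) {
    stop_hftraj("timeline too short: need at least 2 time steps", "contract_error")
  }
  cov <- as.matrix(timeline[covariate_columns()])
  cov[, "age"] <- cov[, "age"] * age_scale
  inputs <- cbind(cov[seq_len(T_len - 1), , drop = FALSE],
                  hf = timeline$hf[seq_len(T_len - 1)])
  colnames(inputs) <- input_columns()
  if (include_cm_targets) {
    targets <- cbind(
      hf = timeline$hf[2:T_len],
      as.matrix(timeline[2:T_len, acute_cm_columns()])
    )
  } else {
    targets <- timeline$hf[2:T_len]
  }
  list(inputs = inputs, targets = targets)
}

#' @rdname cohort_columns
#' @export
input_columns <- function() c(covariate_columns(), "hf")

# split a cohort tibble into per-patient tibbles, preserving order
cohort_timelines <- function(cohort) {
  split(as_tibble(cohort), cohort$patient_id)
}
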