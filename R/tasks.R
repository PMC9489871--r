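#' Pathology label from a 4-state ground-truth code
#'
#' Radiology-report pathology codes are 1 (explicitly present), 0
#' (explicitly absent), -1 (inconclusive) or `NA` (not explored). Only
#' confirmed samples are usable: 1 and 0 are kept with that label,
#' -1 and `NA` are dropped from training and testing.
#'
#' @param value numeric vector of codes in `{1, 0, -1, NA}`.
#' @return Tibble with columns `label` (`NA` for dropped samples) and
#'   `eligible` (logical).
#' @export
label_pathology <- function(value) {
  bad <- !(is.na(value) | value %in% c(1, 0, -1))
  if (any(bad)) {
    abort(paste0("Pathology codes must be 1, 0, -1 or NA; got ",
                 paste(unique(value[bad]), collapse = ", "), "."))
  }
  eligible <- !is.na(value) & value %in% c(0, 1)
  tibble::tibble(label = ifelse(eligible, value, NA_real_),
                 eligible = eligible)
}

#' Length-of-stay label: discharged alive within 48 hours
#'
#' Label 1 iff the patient is discharged alive within the 48 hours
#' following the sampling time — strictly after `t` and at or before
#' `t + 48` (boundary inclusive). Death at any time makes the label 0.
#'
#' @param t_hours sampling times (hours since admission).
#' @param discharge_time,death_time exit times in hours since admission
#'   (`NA` if absent); vectors recycled against `t_hours`.
#' @return Integer vector of 0/1 labels.
#' @export
label_los48 <- function(t_hours, discharge_time, death_time = NA_real_) {
  n <- max(length(t_hours), length(discharge_time), length(death_time))
  t_hours <- rep_len(t_hours, n)
  discharge_time <- rep_len(discharge_time, n)
  death_time <- rep_len(death_time, n)
  if (any(!is.na(discharge_time) & discharge_time < t_hours)) {
    abort("Validation error: discharge before the sampling time.")
  }
  died <- !is.na(death_time)
  as.integer(!died & !is.na(discharge_time) &
               discharge_time > t_hours & discharge_time <= t_hours + 48)
}

#' Mortality label: death within 48 hours
#'
#' Label 1 iff death occurs strictly after the sampling time and at or
#' before `t + 48`; 0 otherwise, including stays with no recorded death.
#' The same stay sampled at successive time points can therefore flip
#' from 0 to 1 as death approaches.
#'
#' @inheritParams label_los48
#' @return Integer vector of 0/1 labels.
#' @export
label_mortality48 <- function(t_hours, death_time) {
  n <- max(length(t_hours), length(death_time))
  t_hours <- rep_len(t_hours, n)
  death_time <- rep_len(death_time, n)
  if (any(!is.na(death_time) & death_time < t_hours)) {
    abort("Validation error: death before the sampling time.")
  }
  as.integer(!is.na(death_time) &
               death_time > t_hours & death_time <= t_hours + 48)
}

#' Define a predictive task
#'
#' Operational tasks (`los48`, `mortality48`) admit all 11 sources;
#' pathology tasks exclude the radiology-note source (`radn`) because the
#' ground truth was itself derived from radiology reports.
#'
#' @param name task name (for pathology tasks, the pathology name).
#' @param kind `"pathology"`, `"los48"` or `"mortality48"`.
#' @return A `task_spec` list with fields `name`, `kind`,
#'   `excluded_sources` and `anchor`.
#' @export
task_spec <- function(name, kind = c("pathology", "los48", "mortality48")) {
  kind <- match.arg(kind)
  structure(list(
    name = name,
    kind = kind,
    excluded_sources = if (kind == "pathology") "radn" else character(0),
    anchor = "image_time"
  ), class = "task_spec")
}

#' Label the samples of a cohort for one task
#'
#' Joins a sample table against the cohort's patient files and produces
#' the task's labels and eligibility flags.
#'
#' @param samples tibble with `patient_id`, `stay_id`, `t_hours` (as
#'   produced by [extract_samples()] over a cohort).
#' @param cohort named list of `patient_file` objects keyed by stay_id.
#' @param task a [task_spec()].
#' @return `samples` with added columns `task`, `label`, `eligible`.
#' @export
label_samples <- function(samples, cohort, task) {
  pf_of <- cohort[samples$stay_id]
  if (task$kind == "pathology") {
    gt <- vapply(pf_of, function(pf) {
      v <- pf$pathology_ground_truth[[task$name]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
    lab <- label_pathology(gt)
    samples$task <- task$name
    samples$label <- lab$label
    samples$eligible <- lab$eligible
  } else {
    disc <- vapply(pf_of, function(pf) pf$discharge_time, numeric(1))
    dead <- vapply(pf_of, function(pf) pf$death_time, numeric(1))
    samples$task <- task$name
    samples$label <- if (task$kind == "los48") {
      as.numeric(label_los48(samples$t_hours, disc, dead))
    } else {
      as.numeric(label_mortality48(samples$t_hours, dead))
    }
    samples$eligible <- TRUE
  }
  samples
}
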