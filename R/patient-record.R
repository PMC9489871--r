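#' Construct a patient-file record
#'
#' A `patient_file` holds everything known about one hospital admission:
#' identifiers, admission/exit timestamps, a named list of numeric
#' demographics, per-source event tables of irregular time-series
#' observations, per-source free-text notes, a list of image studies and
#' (optionally) per-pathology ground-truth codes. All times inside the
#' record are real-valued hours since admission; `admit_time` itself is an
#' absolute timestamp kept only for provenance.
#'
#' @param patient_id,stay_id opaque identifier strings.
#' @param admit_time admission timestamp (`POSIXct` or ISO-8601 string).
#' @param discharge_time,death_time hours since admission at which the
#'   patient exited alive / died, or `NA` if absent. When present they must
#'   be non-negative.
#' @param demographics named numeric vector (or named list) of demographic
#'   values.
#' @param event_tables named list of event tables, one per time-series
#'   source; each a data frame with columns `signal_name`, `time_hours`,
#'   `value`. Times must be finite and non-negative.
#' @param notes named list (per text source) of note tibbles with columns
#'   `time_hours` and `text`.
#' @param image_studies list of image studies, each a list with elements
#'   `time_hours` (scalar) and `images` (non-empty list of numeric
#'   matrices with finite intensities). At least one study is required,
#'   mirroring the inclusion rule that every admission carries a chest
#'   X-ray.
#' @param pathology_ground_truth named numeric vector of pathology codes
#'   in `{1, 0, -1, NA}` (present / absent / inconclusive / not explored).
#' @return An object of class `patient_file`.
#' @seealso [save_patient_file()], [load_patient_file()],
#'   [window_events()], [extract_samples()]
#' @export
patient_file <- function(patient_id, stay_id, admit_time,
                         discharge_time = NA_real_, death_time = NA_real_,
                         demographics = numeric(),
                         event_tables = list(),
                         notes = list(),
                         image_studies = list(),
                         pathology_ground_truth = numeric()) {
  pf <- structure(
    list(
      patient_id = as.character(patient_id),
      stay_id = as.character(stay_id),
      admit_time = as.character(admit_time),
      discharge_time = as.numeric(discharge_time),
      death_time = as.numeric(death_time),
      # named maps are stored in sorted-key order so that constructing,
      # saving and reloading all yield the same canonical layout
      demographics = sort_by_name(as.list(demographics)),
      event_tables = sort_by_name(lapply(event_tables, as_event_table)),
      notes = sort_by_name(lapply(notes, tibble::as_tibble)),
      image_studies = image_studies,
      pathology_ground_truth = sort_by_name(as.list(pathology_ground_truth))
    ),
    class = "patient_file"
  )
  validate_patient_file(pf)
}

as_event_table <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("signal_name", "time_hours", "value")
  if (!all(need %in% names(x))) {
    abort("Event tables need columns signal_name, time_hours, value.")
  }
  x <- x[need]
  x$signal_name <- as.character(x$signal_name)
  x$time_hours <- as.double(x$time_hours)
  x$value <- as.double(x$value)
  x
}

#' Validate a patient-file record
#'
#' Checks every structural invariant: identifiers present, exit times (when
#' present) non-negative, all event/note/image times finite and at or after
#' admission (time 0), at least one image study with non-empty finite
#' images, and pathology codes in `{1, 0, -1, NA}`.
#'
#' @param pf a `patient_file`.
#' @return `pf`, invisibly unchanged, or an error naming the offending
#'   record.
#' @export
validate_patient_file <- function(pf) {
  if (!inherits(pf, "patient_file")) abort("Not a `patient_file` object.")
  id <- paste0(pf$patient_id, "/", pf$stay_id)
  if (!nzchar(pf$patient_id) || !nzchar(pf$stay_id)) {
    abort("patient_id and stay_id must be non-empty strings.")
  }
  for (tm in c("discharge_time", "death_time")) {
    v <- pf[[tm]]
    if (!is.na(v) && (!is.finite(v) || v < 0)) {
      abort(paste0("Record ", id, ": ", tm,
                   " must be >= 0 hours since admission."))
    }
  }
  for (src in names(pf$event_tables)) {
    tab <- pf$event_tables[[src]]
    if (nrow(tab) > 0) {
      if (!all(is.finite(tab$time_hours)) || any(tab$time_hours < 0)) {
        abort(paste0("Record ", id, ", source ", src,
                     ": event times must be finite and >= 0 ",
                     "(hours since admission)."))
      }
      if (!all(is.finite(tab$value))) {
        abort(paste0("Record ", id, ", source ", src,
                     ": event values must be finite."))
      }
    }
  }
  for (src in names(pf$notes)) {
    nt <- pf$notes[[src]]
    if (nrow(nt) > 0 &&
        (!all(is.finite(nt$time_hours)) || any(nt$time_hours < 0))) {
      abort(paste0("Record ", id, ", notes ", src,
                   ": note times must be finite and >= 0."))
    }
  }
  if (length(pf$image_studies) < 1) {
    abort(paste0("Record ", id, ": at least one image study is required."))
  }
  for (k in seq_along(pf$image_studies)) {
    st <- pf$image_studies[[k]]
    if (!is.finite(st$time_hours) || st$time_hours < 0) {
      abort(paste0("Record ", id, ", image study ", k,
                   ": time must be finite and >= 0."))
    }
    if (length(st$images) < 1) {
      abort(paste0("Record ", id, ", image study ", k,
                   ": study must contain at least one image."))
    }
    for (img in st$images) {
      if (!is.matrix(img) || !all(is.finite(img))) {
        abort(paste0("Record ", id, ", image study ", k,
                     ": images must be finite numeric matrices."))
      }
    }
  }
  gt <- unlist(pf$pathology_ground_truth, use.names = FALSE)
  if (length(gt) > 0 && !all(is.na(gt) | gt %in% c(1, 0, -1))) {
    abort(paste0("Record ", id,
                 ": pathology codes must be 1, 0, -1 or NA."))
  }
  invisible(pf)
}

#' @export
print.patient_file <- function(x, ...) {
  n_ev <- sum(vapply(x$event_tables, nrow, integer(1)))
  n_notes <- sum(vapply(x$notes, nrow, integer(1)))
  cat("<patient_file> ", x$patient_id, "/", x$stay_id, "\n", sep = "")
  cat("  events: ", n_ev, " rows across ",
      length(x$event_tables), " sources\n", sep = "")
  cat("  notes: ", n_notes, " | image studies: ",
      length(x$image_studies), "\n", sep = "")
  cat("  discharge: ", x$discharge_time, " h | death: ",
      x$death_time, " h\n", sep = "")
  invisible(x)
}

#' Restrict a patient file to information available at time t
#'
#' Returns a view of the record containing exactly the events, notes and
#' image studies with `time_hours <= t` (boundary inclusive: an
#' observation stamped exactly at the inference time is available, as an
#' imaging procedure carries its own report). Demographics, identifiers
#' and outcome timestamps are unchanged.
#'
#' @param pf a `patient_file`.
#' @param t_hours inference time, hours since admission (`>= 0`; `Inf`
#'   returns the record unchanged).
#' @return A `patient_file` view. Note the image-study invariant (at least
#'   one study) is intentionally *not* re-imposed on views: a window may
#'   predate the first image.
#' @export
window_events <- function(pf, t_hours) {
  # views may themselves be windowed again, and a view is allowed to have
  # zero image studies, so only the class is checked here
  if (!inherits(pf, "patient_file")) abort("Not a `patient_file` object.")
  if (!is.numeric(t_hours) || length(t_hours) != 1 || is.na(t_hours) ||
      t_hours < 0) {
    abort("`t_hours` must be a single number >= 0 (Inf allowed).")
  }
  out <- pf
  out$event_tables <- lapply(pf$event_tables, function(tab) {
    tab[tab$time_hours <= t_hours, , drop = FALSE]
  })
  out$notes <- lapply(pf$notes, function(nt) {
    nt[nt$time_hours <= t_hours, , drop = FALSE]
  })
  keep <- vapply(pf$image_studies, function(st) st$time_hours <= t_hours,
                 logical(1))
  out$image_studies <- pf$image_studies[keep]
  out
}

#' Extract prediction samples from a patient file
#'
#' A sample is one (stay, inference time) point. With the `image_time`
#' anchor there is one sample per image-study time (studies sharing an
#' identical timestamp collapse into one sample — one sample per time
#' point). With the `end_of_day` anchor each study maps to the next
#' 24-hour day boundary at or after it (a study at exactly a boundary
#' keeps that boundary), and duplicates again collapse.
#'
#' @param pf a `patient_file`.
#' @param anchor `"image_time"` or `"end_of_day"`.
#' @return A tibble with columns `patient_id`, `stay_id`, `t_hours`,
#'   sorted by `t_hours`.
#' @export
extract_samples <- function(pf, anchor = c("image_time", "end_of_day")) {
  anchor <- match.arg(anchor)
  validate_patient_file(pf)
  times <- vapply(pf$image_studies, function(st) st$time_hours, numeric(1))
  t <- switch(anchor,
    image_time = times,
    end_of_day = 24 * ceiling(times / 24)
  )
  tibble::tibble(
    patient_id = pf$patient_id,
    stay_id = pf$stay_id,
    t_hours = sort(unique(t))
  )
}
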