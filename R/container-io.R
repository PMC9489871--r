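#' Save a patient file as an open on-disk container
#'
#' Writes a directory container: `manifest.json` (identifiers, timestamps,
#' demographics, pathology codes, note/image inventories),
#' `events/<source>.csv` with header `signal_name,time_hours,value`,
#' `notes/<source>/<k>.txt` plain-text note bodies, and
#' `images/<study_k>/<j>.png` 8-bit grayscale images. Manifest keys are
#' written in a canonical fixed order so save-load-save is byte-identical.
#'
#' Absent `discharge_time` / `death_time` are omitted from the manifest.
#' Image intensities are stored on the 8-bit grid; intensities already on
#' that grid (as produced by [simulate_cohort()]) round-trip exactly.
#'
#' @param pf a valid `patient_file`.
#' @param path directory to create (overwritten if it already exists).
#' @return `path`, invisibly.
#' @export
save_patient_file <- function(pf, path) {
  validate_patient_file(pf)
  if (dir.exists(path)) unlink(path, recursive = TRUE)
  ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok) abort(paste0("Cannot create container directory: ", path))

  manifest <- list(
    schema = "ehrfusion-container/1",
    patient_id = pf$patient_id,
    stay_id = pf$stay_id,
    admit_time = pf$admit_time
  )
  if (!is.na(pf$discharge_time)) manifest$discharge_time <- pf$discharge_time
  if (!is.na(pf$death_time)) manifest$death_time <- pf$death_time
  manifest$demographics <- pf$demographics[order(names(pf$demographics))]
  manifest$pathology_ground_truth <-
    pf$pathology_ground_truth[order(names(pf$pathology_ground_truth))]
  manifest$event_sources <- sort(names(pf$event_tables))
  manifest$note_sources <- lapply(
    pf$notes[order(names(pf$notes))],
    function(nt) as.numeric(nt$time_hours)
  )
  manifest$image_studies <- lapply(pf$image_studies, function(st) {
    list(time_hours = st$time_hours, n_images = length(st$images))
  })

  if (length(pf$event_tables) > 0) {
    dir.create(file.path(path, "events"))
    for (src in names(pf$event_tables)) {
      readr::write_csv(pf$event_tables[[src]],
                       file.path(path, "events", paste0(src, ".csv")),
                       progress = FALSE)
    }
  }
  if (length(pf$notes) > 0) {
    for (src in names(pf$notes)) {
      nt <- pf$notes[[src]]
      if (nrow(nt) == 0) next
      d <- file.path(path, "notes", src)
      dir.create(d, recursive = TRUE)
      for (k in seq_len(nrow(nt))) {
        writeLines(nt$text[k], file.path(d, paste0(k, ".txt")),
                   useBytes = TRUE)
      }
    }
  }
  for (k in seq_along(pf$image_studies)) {
    st <- pf$image_studies[[k]]
    d <- file.path(path, "images", sprintf("study_%03d", k))
    dir.create(d, recursive = TRUE)
    for (j in seq_along(st$images)) {
      img <- st$images[[j]]
      rng <- range(img)
      if (rng[1] < 0 || rng[2] > 1) {
        abort("Image intensities must lie in [0, 1] for PNG storage.")
      }
      png::writePNG(img, file.path(d, sprintf("%02d.png", j)))
    }
  }
  # manifest last, after all referenced files exist
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Load a patient file from a container directory
#'
#' Inverse of [save_patient_file()]. Parses the manifest, reads the event
#' CSVs, note text files and PNG images it references, and returns a fully
#' validated [patient_file()]. A missing manifest is a format error; a
#' timestamp before admission surfaces as a validation error naming the
#' record; an unreadable image is an I/O error naming the file.
#'
#' @param path container directory written by [save_patient_file()].
#' @return A validated `patient_file`.
#' @export
load_patient_file <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!dir.exists(path)) abort(paste0("Container not found: ", path))
  if (!file.exists(mf_path)) {
    abort(paste0("Format error: no manifest.json in ", path))
  }
  mf <- jsonlite::read_json(mf_path, simplifyVector = FALSE)

  event_tables <- list()
  for (src in unlist(mf$event_sources)) {
    f <- file.path(path, "events", paste0(src, ".csv"))
    if (!file.exists(f)) abort(paste0("Format error: missing event table ", f))
    event_tables[[src]] <- readr::read_csv(
      f, col_types = readr::cols(signal_name = readr::col_character(),
                                 time_hours = readr::col_double(),
                                 value = readr::col_double()),
      progress = FALSE)
  }

  notes <- list()
  for (src in names(mf$note_sources)) {
    times <- as.numeric(unlist(mf$note_sources[[src]]))
    texts <- character(length(times))
    for (k in seq_along(times)) {
      f <- file.path(path, "notes", src, paste0(k, ".txt"))
      if (!file.exists(f)) abort(paste0("Format error: missing note file ", f))
      texts[k] <- paste(readLines(f, warn = FALSE), collapse = "\n")
    }
    notes[[src]] <- tibble::tibble(time_hours = times, text = texts)
  }

  image_studies <- list()
  for (k in seq_along(mf$image_studies)) {
    st <- mf$image_studies[[k]]
    d <- file.path(path, "images", sprintf("study_%03d", k))
    imgs <- vector("list", st$n_images)
    for (j in seq_len(st$n_images)) {
      f <- file.path(d, sprintf("%02d.png", j))
      img <- tryCatch(png::readPNG(f), error = function(e) {
        abort(paste0("I/O error reading image ", f, ": ", conditionMessage(e)))
      })
      if (length(dim(img)) == 3) img <- img[, , 1] # tolerate RGB input
      imgs[[j]] <- img
    }
    image_studies[[k]] <- list(time_hours = as.numeric(st$time_hours),
                               images = imgs)
  }

  patient_file(
    patient_id = mf$patient_id,
    stay_id = mf$stay_id,
    admit_time = mf$admit_time,
    discharge_time = if (is.null(mf$discharge_time)) NA_real_ else
      as.numeric(mf$discharge_time),
    death_time = if (is.null(mf$death_time)) NA_real_ else
      as.numeric(mf$death_time),
    demographics = lapply(mf$demographics, as.numeric),
    event_tables = event_tables,
    notes = notes,
    image_studies = image_studies,
    pathology_ground_truth = lapply(mf$pathology_ground_truth, function(v) {
      if (is.null(v)) NA_real_ else as.numeric(v)
    })
  )
}
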