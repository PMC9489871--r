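#' The default source registry
#'
#' The reference configuration spans 11 data sources across 4 modalities:
#' demographics (`de`, tabular), chart / laboratory / procedure events
#' (`ce`, `le`, `pe`, time-series), radiology / ECG / echocardiogram notes
#' (`radn`, `ecgn`, `econ`, text), and single-image / multi-image vision
#' (`vp`, `vd`, `vmp`, `vmd`, image). Per-source embedding dimensions are
#' fixed by the extractors: 6 for demographics, 11 statistics per
#' time-series signal (9 chart, 22 laboratory, 10 procedure signals), 768
#' per text source, and 18 class probabilities plus 1024 dense features
#' per vision stream. The full fusion embedding is 4845-dimensional.
#'
#' The row order of the returned tibble is the canonical source order used
#' everywhere in the package: fusion layouts, subset bitmasks and
#' attribution tables all follow it.
#'
#' @param exclude character vector of source names to drop (e.g. `"radn"`
#'   for chest-pathology tasks).
#' @return A tibble with columns `source`, `modality` and `dim`.
#' @examples
#' source_registry()
#' sum(source_registry()$dim) # 4845
#' @export
source_registry <- function(exclude = NULL) {
  reg <- tibble::tibble(
    source = c("de", "ce", "le", "pe", "radn", "ecgn", "econ",
               "vp", "vd", "vmp", "vmd"),
    modality = c("tabular", "time-series", "time-series", "time-series",
                 "text", "text", "text",
                 "image", "image", "image", "image"),
    dim = c(6L, 99L, 242L, 110L, 768L, 768L, 768L, 18L, 1024L, 18L, 1024L)
  )
  if (!is.null(exclude)) {
    bad <- setdiff(exclude, reg$source)
    if (length(bad) > 0) {
      rlang::abort(paste0("Unknown source(s) in `exclude`: ",
                          paste(bad, collapse = ", ")))
    }
    reg <- reg[!reg$source %in% exclude, ]
  }
  if (nrow(reg) == 0) rlang::abort("All sources excluded; registry is empty.")
  reg
}

#' Clinical signal lists for the time-series sources
#'
#' Fixed, ordered signal name lists defining the layout of each
#' time-series source embedding: 9 chart signals, 22 unique laboratory
#' signals, and 10 procedure signals. Each signal contributes an
#' 11-statistic block, so the source dimensions are 99, 242 and 110.
#'
#' @param source one of `"ce"`, `"le"`, `"pe"`.
#' @return Character vector of signal names in embedding order.
#' @export
timeseries_signals <- function(source = c("ce", "le", "pe")) {
  source <- match.arg(source)
  switch(source,
    ce = c("heart_rate", "nbp_systolic", "nbp_diastolic",
           "respiratory_rate", "spo2",
           "gcs_verbal", "gcs_eye", "gcs_motor", "temperature"),
    le = c("glucose", "potassium", "sodium", "chloride", "creatinine",
           "urea_nitrogen", "bicarbonate", "anion_gap", "hemoglobin",
           "hematocrit", "magnesium", "platelet_count", "phosphate",
           "white_blood_cells", "total_calcium", "mch", "red_blood_cells",
           "mchc", "mcv", "rdw", "neutrophils", "vancomycin"),
    pe = c("foley_catheter", "picc_line", "intubation",
           "peritoneal_dialysis", "bronchoscopy", "eeg", "dialysis_crrt",
           "dialysis_catheter", "chest_tube_removal", "hemodialysis")
  )
}

#' Default demographics schema
#'
#' Six named numeric demographic variables with declared min/max ranges
#' used for min-max normalisation by [embed_tabular()].
#'
#' @return A tibble with columns `name`, `min`, `max`.
#' @export
demographics_schema <- function() {
  tibble::tibble(
    name = c("age", "sex", "height_cm", "weight_kg", "bmi",
             "admission_hour"),
    min = c(18, 0, 120, 30, 10, 0),
    max = c(100, 1, 220, 250, 70, 24)
  )
}

# number of statistics per time-series signal (see embed_timeseries_signal)
TS_N_FEATURES <- 11L
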