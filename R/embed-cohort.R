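#' Extract all per-source embeddings for one patient at one time
#'
#' Windows the record to the inference time and runs every extractor:
#' min-max demographics, 11-statistic time-series blocks, chunk-averaged
#' text vectors, and single-image (most recent study) / multi-image (all
#' studies in the window) vision vectors. Sources with no data in the
#' window contribute zero blocks so the fusion dimensionality stays
#' fixed; per-source presence flags record which blocks were real.
#'
#' @param pf a `patient_file`.
#' @param t_hours inference time (hours since admission).
#' @param text_enc a [text_encoder()].
#' @param image_mod an [image_model()].
#' @param registry source registry (default the full 11-source registry).
#' @return `list(embeddings = named list of vectors,
#'   presence = named logical)`.
#' @export
embed_patient <- function(pf, t_hours,
                          text_enc = stub_text_encoder(),
                          image_mod = stub_image_model(),
                          registry = source_registry()) {
  w <- window_events(pf, t_hours)
  emb <- list()
  presence <- stats::setNames(logical(nrow(registry)), registry$source)
  reg_dim <- stats::setNames(registry$dim, registry$source)

  for (s in registry$source) {
    if (s == "de") {
      emb$de <- embed_tabular(w$demographics)
      presence["de"] <- length(w$demographics) > 0
    } else if (s %in% c("ce", "le", "pe")) {
      tab <- w$event_tables[[s]]
      if (is.null(tab)) {
        tab <- tibble::tibble(signal_name = character(),
                              time_hours = double(), value = double())
      }
      emb[[s]] <- embed_timeseries_source(tab, source = s)
      presence[s] <- nrow(tab) > 0
    } else if (s %in% c("radn", "ecgn", "econ")) {
      nt <- w$notes[[s]]
      emb[[s]] <- embed_text_source(nt, text_enc)
      presence[s] <- !is.null(nt) && nrow(nt) > 0
    } else if (s %in% c("vp", "vd")) {
      if (!is.null(emb$vp)) next
      if (length(w$image_studies) > 0) {
        last <- which.max(vapply(w$image_studies, `[[`, numeric(1),
                                 "time_hours"))
        sv <- embed_image_single(w$image_studies[[last]], image_mod)
        emb$vp <- sv$prob; emb$vd <- sv$dense
        presence[c("vp", "vd")] <- TRUE
      } else {
        emb$vp <- numeric(reg_dim[["vp"]])
        emb$vd <- numeric(reg_dim[["vd"]])
      }
    } else if (s %in% c("vmp", "vmd")) {
      if (!is.null(emb$vmp)) next
      if (length(w$image_studies) > 0) {
        mv <- embed_image_multi(w$image_studies, image_mod)
        emb$vmp <- mv$prob; emb$vmd <- mv$dense
        presence[c("vmp", "vmd")] <- TRUE
      } else {
        emb$vmp <- numeric(reg_dim[["vmp"]])
        emb$vmd <- numeric(reg_dim[["vmd"]])
      }
    }
  }
  emb <- emb[intersect(names(emb), registry$source)]
  for (s in names(emb)) {
    if (length(emb[[s]]) != reg_dim[[s]]) {
      abort(paste0("Extractor for ", s, " returned length ",
                   length(emb[[s]]), ", registry requires ",
                   reg_dim[[s]], "."))
    }
  }
  list(embeddings = emb, presence = presence)
}

#' Embed every sample of a cohort
#'
#' Runs [embed_patient()] for each row of a sample table and stacks the
#' assembled fusion embeddings into a matrix whose columns follow the
#' registry's [fusion_layout()].
#'
#' @param cohort an `ehrf_cohort` (or a named list of `patient_file`
#'   keyed by stay id).
#' @param samples tibble with `stay_id` and `t_hours` (one row per
#'   sample), e.g. from [cohort_samples()].
#' @inheritParams embed_patient
#' @return `list(x = matrix n_samples x sum(dim), layout, samples,
#'   presence = logical matrix)`.
#' @export
embed_cohort <- function(cohort, samples,
                         text_enc = stub_text_encoder(),
                         image_mod = stub_image_model(),
                         registry = source_registry()) {
  files <- if (inherits(cohort, "ehrf_cohort")) cohort$files else cohort
  layout <- fusion_layout(registry$source, registry)
  n <- nrow(samples)
  x <- matrix(0, n, sum(layout$dim))
  pres <- matrix(FALSE, n, nrow(registry),
                 dimnames = list(NULL, registry$source))
  for (i in seq_len(n)) {
    pf <- files[[samples$stay_id[i]]]
    if (is.null(pf)) abort(paste0("No patient file for stay ",
                                  samples$stay_id[i]))
    ep <- embed_patient(pf, samples$t_hours[i], text_enc, image_mod,
                        registry)
    x[i, ] <- assemble_fusion(ep$embeddings, registry$source, registry)
    pres[i, ] <- ep$presence[registry$source]
  }
  list(x = x, layout = layout, samples = samples, presence = pres)
}
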