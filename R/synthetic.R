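#' Configuration for the synthetic multimodal cohort generator
#'
#' Defines the statistical structure of a simulated cohort. Each patient
#' carries a standard-normal latent risk `z`; each data source s gets its
#' own latent `u_s = rho * z + (1 - rho) * eps_s`, so `rho` is the
#' inter-source redundancy knob: at `rho = 0` sources are independent and
#' each adds fresh signal, at `rho -> 1` they all encode the same latent
#' and additional sources are redundant. Observed data for source s drift
#' with `beta_s * u_s` (`beta_s = 0` makes the source pure noise). The
#' outcome risk score is `sum(beta_s * u_s)` (standardised); death events
#' are placed in the 48 h window after the anchor image so that the
#' mortality-48h label prevalence matches `prevalence`.
#'
#' @param n_patients number of patients (one stay each by default).
#' @param stays_per_patient stays per patient.
#' @param beta named vector of per-source signal strengths (>= 0), keyed
#'   by registry source name; unnamed scalar recycles to all sources. The
#'   four image sources share their pixel data, so the image modality is
#'   driven by a single latent (that of `vp`) and `beta` of `vp` governs
#'   the whole group.
#' @param rho inter-source redundancy in \[0, 1\].
#' @param event_rate expected events per hour per signal.
#' @param note_length mean note length in tokens.
#' @param image_size side length of the square synthetic images.
#' @param prevalence target mortality-48h label prevalence in (0, 1).
#' @param link `"logistic"` (death risk is a logistic function of the risk
#'   score; intercept solved so the realised prevalence matches) or
#'   `"threshold"` (the top `prevalence` fraction by risk score dies:
#'   a separable cohort).
#' @param pathologies character vector of pathology names to attach
#'   4-state ground truth for.
#' @param sources which registry sources to populate (default all 11).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_patients = 200, stays_per_patient = 1,
                       beta = 1, rho = 0.3,
                       event_rate = 0.05, note_length = 120,
                       image_size = 48, prevalence = 0.3,
                       link = c("logistic", "threshold"),
                       pathologies = c("consolidation", "edema"),
                       sources = source_registry()$source) {
  link <- match.arg(link)
  all_src <- source_registry()$source
  if (is.null(names(beta))) {
    beta <- stats::setNames(rep_len(beta, length(sources)), sources)
  } else {
    full <- stats::setNames(numeric(length(sources)), sources)
    full[intersect(names(beta), sources)] <-
      beta[intersect(names(beta), sources)]
    beta <- full
  }
  if (any(beta < 0)) abort("`beta` must be >= 0.")
  if (rho < 0 || rho > 1) abort("`rho` must be in [0, 1].")
  if (event_rate < 0 || note_length < 1 || image_size < 2) {
    abort("Rates and sizes must be positive.")
  }
  if (prevalence <= 0 || prevalence >= 1) {
    abort("`prevalence` must be in (0, 1).")
  }
  if (!all(sources %in% all_src)) abort("Unknown source in `sources`.")
  structure(list(
    n_patients = n_patients, stays_per_patient = stays_per_patient,
    beta = beta, rho = rho, event_rate = event_rate,
    note_length = note_length, image_size = image_size,
    prevalence = prevalence, link = link, pathologies = pathologies,
    sources = sources
  ), class = "sim_config")
}

# round to the 8-bit PNG grid so disk round-trips are exact
quant8 <- function(x) round(pmin(pmax(x, 0), 1) * 255) / 255

#' Simulate a multimodal synthetic cohort
#'
#' Generates `n_patients * stays_per_patient` in-memory patient files with
#' the full container structure: demographics, irregular time-series
#' events for the chart/laboratory/procedure sources, free-text notes for
#' the three note sources (numeric "severity" tokens carry the source
#' latent through the stub text encoder), grayscale images whose mean
#' intensity carries the image latent, 4-state pathology ground truth
#' correlated with the image latent, and death/discharge times consistent
#' with the target mortality-48h prevalence. Fully reproducible: the
#' output is a pure function of `config` and `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return A list of class `ehrf_cohort`: `files` (named list of
#'   `patient_file`, keyed by stay id), `latents` (tibble of per-stay
#'   latent risk, per-source latents and risk score) and `config`.
#' @export
simulate_cohort <- function(config, seed = 1L) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config.")
  withr::with_seed(seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cf) {
  n_stay <- cf$n_patients * cf$stays_per_patient
  src <- cf$sources
  stay_pat <- rep(seq_len(cf$n_patients), each = cf$stays_per_patient)
  z <- stats::rnorm(cf$n_patients)[stay_pat]
  u <- vapply(src, function(s) {
    cf$rho * z + (1 - cf$rho) * stats::rnorm(n_stay)
  }, numeric(n_stay))
  if (n_stay == 1) u <- matrix(u, nrow = 1, dimnames = list(NULL, src))
  # image sources share pixels: one latent drives the whole group
  img_src <- intersect(c("vp", "vd", "vmp", "vmd"), src)
  if (length(img_src) > 1) for (s in img_src[-1]) u[, s] <- u[, img_src[1]]

  raw <- as.numeric(u %*% cf$beta[src])
  sd_raw <- if (n_stay > 1) stats::sd(raw) else 0
  risk <- if (isTRUE(sd_raw > 0)) (raw - mean(raw)) / sd_raw else raw * 0

  t_img <- stats::runif(n_stay, 6, 72)
  died <- switch(cf$link,
    logistic = {
      slope <- 1.5
      f <- function(c0) mean(stats::plogis(c0 + slope * risk)) - cf$prevalence
      c0 <- stats::uniroot(f, c(-30, 30))$root
      stats::runif(n_stay) < stats::plogis(c0 + slope * risk)
    },
    threshold = risk >= stats::quantile(risk, 1 - cf$prevalence,
                                        names = FALSE)
  )
  if (cf$link == "threshold") {
    # separable cohort: push each class's latents away from the decision
    # boundary so observed features separate the classes with a margin
    u <- u + 1.5 * (2 * died - 1)
  }
  death_time <- ifelse(died, t_img + stats::runif(n_stay, 1, 47), NA_real_)
  disc_delay <- stats::rlnorm(n_stay, meanlog = log(40) + 0.4 * risk,
                              sdlog = 0.6)
  discharge_time <- ifelse(died, NA_real_, t_img + disc_delay)
  exit_time <- ifelse(died, death_time, discharge_time)

  schema <- demographics_schema()
  files <- vector("list", n_stay)
  ids <- character(n_stay)
  for (i in seq_len(n_stay)) {
    pid <- sprintf("p%04d", stay_pat[i])
    sid <- sprintf("s%04d", i)
    ids[i] <- sid

    demo <- stats::setNames(as.list(
      schema$min + stats::runif(6) * (schema$max - schema$min)), schema$name)
    if ("de" %in% src) {
      # spread the tabular latent across four of the six variables
      b <- cf$beta[["de"]]
      mix <- function(mid, spread) {
        mid + spread * (b * u[i, "de"] + 0.25 * stats::rnorm(1))
      }
      demo$age <- min(max(mix(59, 12), 18), 100)
      demo$bmi <- min(max(mix(30, 8), 10), 70)
      demo$weight_kg <- min(max(mix(90, 25), 30), 250)
      demo$height_cm <- min(max(mix(170, -10), 120), 220)
    }
    demo <- lapply(demo, function(v) round(v, 6))

    ev <- list()
    for (s in intersect(c("ce", "le", "pe"), src)) {
      sigs <- timeseries_signals(s)
      b <- cf$beta[[s]]
      n_ev <- stats::rpois(length(sigs), cf$event_rate * exit_time[i])
      tot <- sum(n_ev)
      if (tot == 0) {
        ev[[s]] <- tibble::tibble(signal_name = character(),
                                  time_hours = double(), value = double())
        next
      }
      sig_col <- rep(sigs, n_ev)
      tt <- stats::runif(tot, 0, exit_time[i])
      ord <- order(sig_col, tt)
      tt <- round(tt[ord], 6)
      vv <- round(b * u[i, s] + stats::rnorm(tot, sd = 0.7) +
                    0.2 * tt / 24, 6)
      ev[[s]] <- tibble::tibble(signal_name = sig_col[ord],
                                time_hours = tt, value = vv)
    }

    notes <- list()
    vocab <- c("patient", "stable", "followup", "reviewed", "chest",
               "cardiac", "rhythm", "study", "impression", "clinical")
    for (s in intersect(c("radn", "ecgn", "econ"), src)) {
      b <- cf$beta[[s]]
      n_tok <- max(8, stats::rpois(1, cf$note_length))
      n_num <- max(2, round(n_tok * 0.2))
      sev <- round(b * u[i, s] + stats::rnorm(n_num, sd = 0.4), 4)
      toks <- c(sample(vocab, n_tok - n_num, replace = TRUE),
                formatC(sev, format = "f", digits = 4))
      notes[[s]] <- tibble::tibble(
        time_hours = round(stats::runif(1, 0, t_img[i]), 6),
        text = paste(sample(toks), collapse = " ")
      )
    }

    studies <- list()
    if (length(img_src) > 0) {
      b <- cf$beta[[img_src[1]]]
      sz <- cf$image_size
      base <- matrix(stats::rnorm(sz * sz, sd = 0.06), sz, sz)
      grad <- outer(seq_len(sz) / sz, rep(0.05, sz))
      img <- quant8(0.5 + 0.12 * tanh(b * u[i, img_src[1]]) + grad + base)
      studies[[1]] <- list(time_hours = round(t_img[i], 6),
                           images = list(img))
    } else {
      # container invariant: at least one image study
      studies[[1]] <- list(time_hours = round(t_img[i], 6),
                           images = list(matrix(0.5, 4, 4)))
    }

    gt <- stats::setNames(lapply(cf$pathologies, function(p) {
      r <- stats::runif(1)
      if (r < 0.15) return(NA_real_)   # not explored
      if (r < 0.25) return(-1)         # inconclusive
      sig <- if (length(img_src) > 0) cf$beta[[img_src[1]]] * u[i, img_src[1]]
             else 0
      as.numeric(stats::runif(1) < stats::plogis(-0.5 + 1.5 * sig))
    }), cf$pathologies)

    files[[i]] <- patient_file(
      patient_id = pid, stay_id = sid,
      admit_time = "2019-01-01T00:00:00Z",
      discharge_time = round(discharge_time[i], 6),
      death_time = round(death_time[i], 6),
      demographics = demo,
      event_tables = ev,
      notes = notes,
      image_studies = studies,
      pathology_ground_truth = gt
    )
  }
  names(files) <- ids
  latents <- tibble::tibble(
    patient_id = sprintf("p%04d", stay_pat), stay_id = ids,
    z = z, risk = risk, t_img = t_img,
    death_time = death_time, discharge_time = discharge_time
  )
  structure(list(files = files, latents = latents, config = cf),
            class = "ehrf_cohort")
}

#' @export
print.ehrf_cohort <- function(x, ...) {
  cat("<ehrf_cohort> ", length(x$files), " stays, rho = ",
      x$config$rho, ", prevalence target = ", x$config$prevalence,
      "\n", sep = "")
  invisible(x)
}

#' Sample and label a cohort for one task
#'
#' Extracts one sample per image-study time from every file and attaches
#' the task's labels.
#'
#' @param cohort an `ehrf_cohort`.
#' @param task a [task_spec()].
#' @return A labelled sample tibble (see [label_samples()]).
#' @export
cohort_samples <- function(cohort, task = task_spec("mortality48",
                                                    "mortality48")) {
  samples <- dplyr::bind_rows(lapply(cohort$files, extract_samples,
                                     anchor = task$anchor))
  label_samples(samples, cohort$files, task)
}
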