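# Shared in-code fixtures for the suite.

# A minimal hand-built patient file: 3 HR events, one note, two image
# studies, known outcome times.
toy_patient <- function(death_time = NA_real_, discharge_time = 200) {
  patient_file(
    patient_id = "p1", stay_id = "s1",
    admit_time = "2020-01-01T00:00:00Z",
    discharge_time = discharge_time, death_time = death_time,
    demographics = list(age = 59, sex = 1, height_cm = 170,
                        weight_kg = 140, bmi = 40, admission_hour = 12),
    event_tables = list(
      ce = tibble::tibble(signal_name = "heart_rate",
                          time_hours = c(1, 5, 9),
                          value = c(80, 95, 90))
    ),
    notes = list(
      econ = tibble::tibble(time_hours = 2, text = "normal sinus rhythm")
    ),
    image_studies = list(
      list(time_hours = 3, images = list(matrix(0.5, 8, 8))),
      list(time_hours = 30, images = list(matrix(0.25, 8, 8)))
    ),
    pathology_ground_truth = list(consolidation = 1, edema = -1)
  )
}

# a registry of 3 tiny sources used where full dims would be wasteful
toy_registry <- function() {
  tibble::tibble(
    source = c("a", "b", "c"),
    modality = c("tabular", "time-series", "text"),
    dim = c(2L, 3L, 4L)
  )
}

# random transferable-utility game on k players: v[mask + 1], v[1] = 0.5
random_game <- function(k, seed) {
  withr::with_seed(seed, c(0.5, runif(2^k - 1, 0.4, 0.95)))
}

# deterministic feature matrix + labels with a separable structure
separable_xy <- function(n = 120, p = 5, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p)
    y <- as.integer(x[, 1] > 0)
    list(x = x, y = y, patient_id = sprintf("p%03d", seq_len(n)))
  })
}
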