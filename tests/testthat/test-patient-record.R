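test_that("constructor validates record invariants", {
  expect_s3_class(toy_patient(), "patient_file")
  # event before admission
  expect_error(
    patient_file("p", "s", "2020-01-01",
                 event_tables = list(ce = tibble::tibble(
                   signal_name = "heart_rate", time_hours = -1, value = 1)),
                 image_studies = list(list(time_hours = 1,
                                           images = list(matrix(0, 2, 2))))),
    "finite and >= 0")
  # no image study
  expect_error(
    patient_file("p", "s", "2020-01-01", image_studies = list()),
    "at least one image study")
  # bad pathology code
  expect_error(
    patient_file("p", "s", "2020-01-01",
                 image_studies = list(list(time_hours = 1,
                                           images = list(matrix(0, 2, 2)))),
                 pathology_ground_truth = list(edema = 2)),
    "1, 0, -1 or NA")
})

test_that("container round-trip is lossless and manifests are canonical", {
  co <- simulate_cohort(sim_config(n_patients = 2), seed = 42)
  for (pf in co$files) {
    d <- withr::local_tempdir()
    save_patient_file(pf, file.path(d, "c"))
    pf2 <- load_patient_file(file.path(d, "c"))
    expect_equal(unclass(pf2), unclass(pf), tolerance = 0)
    # save -> load -> save: byte-identical manifest (canonical key order)
    save_patient_file(pf2, file.path(d, "c2"))
    expect_identical(readLines(file.path(d, "c2", "manifest.json")),
                     readLines(file.path(d, "c", "manifest.json")))
  }
})

test_that("optional exit-time keys are omitted from the manifest", {
  pf <- toy_patient(discharge_time = NA_real_)
  d <- withr::local_tempdir()
  save_patient_file(pf, file.path(d, "c"))
  mf <- jsonlite::read_json(file.path(d, "c", "manifest.json"))
  expect_false("death_time" %in% names(mf))
  expect_false("discharge_time" %in% names(mf))
  # study count preserved as subdirectories
  expect_length(list.dirs(file.path(d, "c", "images"), recursive = FALSE), 2)
})

test_that("a missing manifest is a format error", {
  d <- withr::local_tempdir()
  dir.create(file.path(d, "empty"))
  expect_error(load_patient_file(file.path(d, "empty")), "manifest")
  expect_error(load_patient_file(file.path(d, "nonexistent")), "not found")
})

test_that("windowing keeps exactly the events at or before t", {
  pf <- toy_patient()
  w <- window_events(pf, 5) # events at 1, 5, 9 h
  expect_equal(nrow(w$event_tables$ce), 2) # boundary inclusive
  expect_equal(length(w$image_studies), 1) # studies at 3, 30 h
  # t = 0 with all events later -> empty tables
  w0 <- window_events(pf, 0)
  expect_equal(nrow(w0$event_tables$ce), 0)
  expect_length(w0$image_studies, 0)
  # t = Inf is the identity
  expect_equal(unclass(window_events(pf, Inf)), unclass(pf))
  expect_error(window_events(pf, -1), ">= 0")
})

test_that("windowing is monotone and idempotent", {
  co <- simulate_cohort(sim_config(n_patients = 3, event_rate = 0.2),
                        seed = 5)
  n_events <- function(pf) sum(vapply(pf$event_tables, nrow, integer(1)))
  for (pf in co$files) {
    ts <- c(0, 12, 24, 48, 96, Inf)
    counts <- vapply(ts, function(t) n_events(window_events(pf, t)),
                     numeric(1))
    expect_true(all(diff(counts) >= 0))
    for (t in c(12, 48)) {
      once <- window_events(pf, t)
      expect_equal(unclass(window_events(once, t)), unclass(once))
    }
  }
})

test_that("sample extraction follows the anchor rules", {
  pf <- toy_patient() # studies at 3 h and 30 h
  s <- extract_samples(pf, anchor = "image_time")
  expect_equal(s$t_hours, c(3, 30))
  # every sample time is justified by a study time
  study_times <- vapply(pf$image_studies, `[[`, numeric(1), "time_hours")
  expect_true(all(s$t_hours %in% study_times))
  # end-of-day: next 24 h boundary at or after the study
  s2 <- extract_samples(pf, anchor = "end_of_day")
  expect_equal(s2$t_hours, c(24, 48))
  # duplicate timestamps collapse to one sample per time point
  pf_dup <- patient_file("p", "s", "2020-01-01",
    image_studies = list(
      list(time_hours = 3, images = list(matrix(0, 2, 2))),
      list(time_hours = 3, images = list(matrix(1, 2, 2)))))
  expect_equal(nrow(extract_samples(pf_dup, "image_time")), 1)
})
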