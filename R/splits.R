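#' Patient-stratified repeated train/test splits
#'
#' Builds `n_rep` independent 80/20 partitions at patient-id granularity:
#' no patient ever contributes samples to both sides of a repetition,
#' which is the leakage guard for records sampled at several time points.
#' With `stratify_label = TRUE` (pathology tasks) patients are first
#' grouped by their majority label and each group is split separately, so
#' the target ratio is approximately balanced at patient granularity.
#'
#' @param samples tibble with columns `patient_id` and `label`.
#' @param n_rep number of repetitions (default 5).
#' @param test_frac test fraction (default 0.2).
#' @param stratify_label balance labels at the patient level.
#' @param seed integer seed; the plan is a pure function of it.
#' @return An object of class `ehrf_split_plan`: a list of `n_rep` lists
#'   with `train` / `test` patient-id vectors, plus the call parameters.
#' @export
make_splits <- function(samples, n_rep = 5, test_frac = 0.2,
                        stratify_label = FALSE, seed = 1L) {
  labs <- unique(samples$label[!is.na(samples$label)])
  if (length(labs) < 2) {
    abort("Task has a single class; AUROC is undefined.")
  }
  patients <- unique(samples$patient_id)
  if (stratify_label) {
    pat_lab <- tapply(samples$label, samples$patient_id,
                      function(l) as.integer(mean(l, na.rm = TRUE) >= 0.5))
    groups <- split(names(pat_lab), unname(pat_lab))
    if (any(vapply(groups, length, integer(1)) < 2)) {
      abort("Need at least 2 patients per class for stratified splits.")
    }
  } else {
    groups <- list(patients)
  }
  reps <- withr::with_seed(seed, {
    lapply(seq_len(n_rep), function(r) {
      test <- unlist(lapply(groups, function(g) {
        n_test <- max(1L, round(length(g) * test_frac))
        sample(g, n_test)
      }), use.names = FALSE)
      list(train = setdiff(patients, test), test = test)
    })
  })
  structure(list(reps = reps, n_rep = n_rep, test_frac = test_frac,
                 stratify_label = stratify_label, seed = seed),
            class = "ehrf_split_plan")
}

#' @export
print.ehrf_split_plan <- function(x, ...) {
  cat("<ehrf_split_plan> ", x$n_rep, " repetitions, test_frac = ",
      x$test_frac, ", stratified = ", x$stratify_label,
      ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}
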