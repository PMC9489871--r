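#' Train and evaluate one model on one split
#'
#' Fits the backend on the training rows (selected by patient id from the
#' split), standardises features with a normalizer fitted on the training
#' rows only, runs the cross-validated hyperparameter grid search entirely
#' inside the training split (when the backend uses a grid), refits the
#' winning cell on the full training split, and touches the test split
#' exactly once for the reported AUROC.
#'
#' Grid cells whose inner training folds are single-class are skipped with
#' a warning; if every cell degenerates, an error is raised. Ties on
#' cross-validated AUROC break to the first cell in grid order.
#'
#' @param x feature matrix (rows = samples).
#' @param y 0/1 labels.
#' @param patient_id per-row patient ids (grouping unit of the split).
#' @param split one repetition of an [make_splits()] plan:
#'   `list(train =, test =)` patient-id vectors.
#' @param grid a [hyperparameter_grid()] (ignored by grid-free backends).
#' @param backend a classifier backend ([backend_xgboost()] default).
#' @return `list(auroc, params, n_train, n_test)`.
#' @export
train_eval_model <- function(x, y, patient_id, split,
                             grid = hyperparameter_grid(),
                             backend = backend_xgboost()) {
  x <- as.matrix(x)
  tr <- patient_id %in% split$train
  te <- patient_id %in% split$test
  if (!any(tr) || !any(te)) abort("Split leaves an empty train or test set.")
  x_tr <- x[tr, , drop = FALSE]; y_tr <- y[tr]
  x_te <- x[te, , drop = FALSE]; y_te <- y[te]
  if (length(unique(y_tr)) < 2) abort("Training split is single-class.")

  norm <- fit_normalizer(x_tr)
  x_tr <- apply_normalizer(norm, x_tr)
  x_te <- apply_normalizer(norm, x_te)

  chosen <- list(max_depth = NA, n_estimators = NA, learning_rate = NA)
  if (isTRUE(backend$uses_grid) && !is.null(grid) && nrow(grid) > 1) {
    chosen <- select_hyperparameters(x_tr, y_tr, patient_id[tr], grid, backend)
  } else if (isTRUE(backend$uses_grid) && !is.null(grid)) {
    chosen <- as.list(grid[1, ])
  }

  model <- backend$fit(x_tr, y_tr, chosen)
  scores <- backend$predict_prob(model, x_te)
  list(auroc = auroc(y_te, scores), params = chosen,
       n_train = sum(tr), n_test = sum(te))
}

# Fivefold (by default) cross-validated grid search inside the training
# split. Folds are assigned at patient granularity so the inner loop
# inherits the leakage guard.
select_hyperparameters <- function(x_tr, y_tr, pid_tr, grid, backend) {
  cv_folds <- attr(grid, "cv_folds") %||% 5
  pats <- unique(pid_tr)
  fold_of_pat <- stats::setNames(rep_len(seq_len(cv_folds), length(pats)),
                                 pats)
  fold <- fold_of_pat[pid_tr]
  cv_auc <- rep(NA_real_, nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- as.list(grid[g, ])
    aucs <- numeric(0)
    degenerate <- FALSE
    for (f in seq_len(cv_folds)) {
      in_f <- fold == f
      if (!any(in_f) || length(unique(y_tr[!in_f])) < 2) {
        degenerate <- TRUE
        break
      }
      m <- backend$fit(x_tr[!in_f, , drop = FALSE], y_tr[!in_f], params)
      s <- backend$predict_prob(m, x_tr[in_f, , drop = FALSE])
      aucs <- c(aucs, auroc(y_tr[in_f], s))
    }
    if (degenerate) {
      warn(paste0("Grid cell ", g, " skipped: single-class inner fold."))
      next
    }
    cv_auc[g] <- mean(aucs, na.rm = TRUE)
  }
  if (all(is.na(cv_auc))) abort("All grid cells degenerate.")
  as.list(grid[which.max(cv_auc), ]) # which.max takes the first tie
}

#' Run the exhaustive subset-ablation experiment for one task
#'
#' For every enumerated source subset, assembles the subset's feature
#' columns from the embedding matrix, trains and evaluates one model per
#' split repetition with [train_eval_model()], and records the mean and SD
#' of the test AUROCs. This is the value table the Shapley attribution
#' consumes.
#'
#' Results are order-independent across subsets; with `checkpoint` set,
#' completed subsets are appended to a CSV as they finish and skipped on
#' restart.
#'
#' @param embeddings embedding matrix (rows = samples) whose columns
#'   follow `layout`.
#' @param layout a [fusion_layout()] for the full allowed registry,
#'   matching `ncol(embeddings)`.
#' @param samples tibble aligned with the rows of `embeddings`, holding
#'   `patient_id` and `label` (only eligible, labelled rows are used).
#' @param enumeration an [enumerate_source_subsets()] tibble.
#' @param splits an [make_splits()] plan.
#' @param grid,backend see [train_eval_model()].
#' @param task task name recorded in the result rows.
#' @param checkpoint optional CSV path for resumable execution.
#' @return An `ehrf_auroc_table`: a tibble with one row per subset
#'   (`task`, `bitmask`, `n_sources`, `n_modalities`, `auroc_mean`,
#'   `auroc_sd`, chosen hyperparameters), with the registry layout
#'   attached.
#' @export
run_experiment <- function(embeddings, layout, samples, enumeration,
                           splits, grid = hyperparameter_grid(),
                           backend = backend_xgboost(),
                           task = "task", checkpoint = NULL) {
  embeddings <- as.matrix(embeddings)
  if (ncol(embeddings) != sum(layout$dim)) {
    abort("Embedding matrix width does not match the layout.")
  }
  if (nrow(embeddings) != nrow(samples)) {
    abort("`embeddings` and `samples` disagree on the number of rows.")
  }
  keep <- !is.na(samples$label)
  if ("eligible" %in% names(samples)) keep <- keep & samples$eligible
  embeddings <- embeddings[keep, , drop = FALSE]
  samples <- samples[keep, , drop = FALSE]

  col_of <- stats::setNames(
    lapply(seq_len(nrow(layout)), function(i) {
      layout$offset[i] + seq_len(layout$dim[i])
    }), layout$source)

  done <- character(0)
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    prev <- readr::read_csv(
      checkpoint, col_types = readr::cols(bitmask = readr::col_character()),
      progress = FALSE)
    done <- as.character(prev$bitmask)
  }

  rows <- vector("list", nrow(enumeration))
  for (i in seq_len(nrow(enumeration))) {
    bm <- enumeration$bitmask[i]
    if (bm %in% done) next
    srcs <- enumeration$sources[[i]]
    miss <- setdiff(srcs, names(col_of))
    if (length(miss) > 0) {
      abort(paste0("No embedding block for source(s): ",
                   paste(miss, collapse = ", ")))
    }
    cols <- unlist(col_of[srcs], use.names = FALSE)
    x <- embeddings[, cols, drop = FALSE]
    fits <- lapply(splits$reps, function(rep) {
      train_eval_model(x, samples$label, samples$patient_id, rep,
                       grid = grid, backend = backend)
    })
    aucs <- vapply(fits, function(f) f$auroc, numeric(1))
    params <- majority_params(lapply(fits, `[[`, "params"))
    row <- tibble::tibble(
      task = task, bitmask = bm,
      n_sources = enumeration$n_sources[i],
      n_modalities = enumeration$n_modalities[i],
      auroc_mean = mean(aucs, na.rm = TRUE),
      auroc_sd = stats::sd(aucs, na.rm = TRUE),
      chosen_depth = params$max_depth,
      chosen_estimators = params$n_estimators,
      chosen_lr = params$learning_rate
    )
    rows[[i]] <- row
    if (!is.null(checkpoint)) {
      readr::write_csv(row, checkpoint, append = file.exists(checkpoint),
                       progress = FALSE)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (length(done) > 0) out <- dplyr::bind_rows(prev, out)
  out <- out[match(enumeration$bitmask, out$bitmask), ]
  structure(out, layout = layout, class = c("ehrf_auroc_table", class(out)))
}

# most frequent hyperparameter combination across repetitions (first on tie)
majority_params <- function(params_list) {
  keys <- vapply(params_list, function(p) paste(unlist(p), collapse = "/"),
                 character(1))
  counts <- tabulate(match(keys, unique(keys)))
  params_list[[match(unique(keys)[which.max(counts)], keys)]]
}

#' Summarise an AUROC table by modality and source counts
#'
#' Produces the mean/SD AUROC in every (n_modalities, n_sources) cell and
#' the average percent AUROC change of every multi-source subset relative
#' to the single-source baseline:
#' `delta = 100 * (auroc_subset - baseline) / baseline`, with the baseline
#' the mean AUROC over all single-source models (`baseline = "mean"`), or
#' the best single-source model (`baseline = "best"`).
#'
#' @param table an `ehrf_auroc_table` from [run_experiment()].
#' @param baseline `"mean"` (default) or `"best"`.
#' @return A list of class `ehrf_auroc_summary`: `by_cell` (tibble of
#'   modality x source cells), `delta` (per-subset percent change),
#'   `baseline_auroc`, `baseline`.
#' @export
summarize_auroc <- function(table, baseline = c("mean", "best")) {
  baseline <- match.arg(baseline)
  singles <- table$auroc_mean[table$n_sources == 1]
  if (length(singles) == 0) abort("Table has no single-source rows.")
  base <- if (baseline == "mean") mean(singles) else max(singles)
  by_cell <- table %>%
    dplyr::group_by(.data$n_modalities, .data$n_sources) %>%
    dplyr::summarise(auroc_sd = stats::sd(.data$auroc_mean),
                     auroc_mean = mean(.data$auroc_mean),
                     n_subsets = dplyr::n(), .groups = "drop") %>%
    dplyr::select("n_modalities", "n_sources", "auroc_mean", "auroc_sd",
                  "n_subsets")
  delta <- table %>%
    dplyr::filter(.data$n_sources > 1) %>%
    dplyr::mutate(delta_auroc_pct =
                    100 * (.data$auroc_mean - base) / base) %>%
    dplyr::select("task", "bitmask", "n_sources", "n_modalities",
                  "delta_auroc_pct")
  structure(list(by_cell = by_cell, delta = delta,
                 baseline_auroc = base, baseline = baseline),
            class = "ehrf_auroc_summary")
}

#' @export
print.ehrf_auroc_summary <- function(x, ...) {
  cat("<ehrf_auroc_summary> baseline (", x$baseline, " single-source) = ",
      round(x$baseline_auroc, 4), "\n", sep = "")
  print(x$by_cell)
  invisible(x)
}
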