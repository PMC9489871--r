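test_that("subset enumeration counts and modality groups are exact", {
  enum11 <- enumerate_source_subsets()
  expect_equal(nrow(enum11), 2047)
  enum10 <- enumerate_source_subsets(exclude = "radn")
  expect_equal(nrow(enum10), 1023)
  grp <- table(enum10$n_modalities)
  expect_equal(as.integer(grp), c(26, 196, 486, 315))
  # brute-force scan over modality sizes (1, 3, 2, 4) after exclusion
  sizes <- c(tabular = 1, `time-series` = 3, text = 2, image = 4)
  brute <- sapply(1:4, function(m) {
    sum(vapply(utils::combn(names(sizes), m, simplify = FALSE),
               function(mods) prod(2^sizes[mods] - 1), numeric(1)))
  })
  expect_equal(as.integer(grp), as.integer(brute))
  # groups partition the enumeration for every k
  for (reg in list(toy_registry(), source_registry())) {
    e <- enumerate_source_subsets(reg)
    expect_equal(nrow(e), 2^nrow(reg) - 1)
    expect_equal(sum(table(e$n_modalities)), nrow(e))
  }
  expect_error(enumerate_source_subsets(exclude = source_registry()$source),
               "excluded")
})

test_that("bitmasks encode subsets over the canonical order", {
  reg <- source_registry()
  bm <- subset_bitmask(c("de", "vmd"), reg)
  expect_equal(bm, "10000000001")
  expect_equal(bitmask_sources(bm, reg), c("de", "vmd"))
  enum <- enumerate_source_subsets(reg)
  i <- sample(nrow(enum), 20)
  expect_equal(vapply(enum$sources[i], subset_bitmask, character(1), reg),
               enum$bitmask[i])
})

test_that("splits never leak patients and are reproducible", {
  s <- tibble::tibble(patient_id = rep(sprintf("p%02d", 1:10), each = 3),
                      label = rep(c(0, 1), 15))
  plan <- make_splits(s, n_rep = 5, test_frac = 0.2, seed = 4)
  for (rep in plan$reps) {
    expect_length(intersect(rep$train, rep$test), 0)
    expect_length(rep$test, 2) # 10 patients * 0.2
    expect_setequal(c(rep$train, rep$test), unique(s$patient_id))
  }
  expect_identical(make_splits(s, n_rep = 5, seed = 4)$reps, plan$reps)
  expect_false(identical(make_splits(s, n_rep = 5, seed = 5)$reps,
                         plan$reps))
  expect_error(make_splits(tibble::tibble(patient_id = "a", label = 1)),
               "single class")
})

test_that("stratified splits balance labels at patient granularity", {
  withr::with_seed(11, {
    s <- tibble::tibble(patient_id = sprintf("p%03d", 1:60),
                        label = rep(c(0, 0, 0, 1), 15))
    plan <- make_splits(s, n_rep = 5, stratify_label = TRUE, seed = 9)
    lab_of <- stats::setNames(s$label, s$patient_id)
    for (rep in plan$reps) {
      # 25% positives overall -> exactly 3 of 12 test patients positive
      expect_equal(sum(lab_of[rep$test]), 3)
    }
  })
})

test_that("training is deterministic and separable data reaches AUROC 1", {
  d <- separable_xy(n = 120)
  split <- list(train = d$patient_id[1:90], test = d$patient_id[91:120])
  r1 <- train_eval_model(d$x, d$y, d$patient_id, split,
                         backend = backend_logistic())
  expect_equal(r1$auroc, 1.0)
  r2 <- train_eval_model(d$x, d$y, d$patient_id, split,
                         backend = backend_logistic())
  expect_identical(r1$auroc, r2$auroc)
  # gradient-boosted backend with a tiny grid is also deterministic
  g <- hyperparameter_grid(max_depth = c(2, 3), n_estimators = 20,
                           learning_rate = 0.3, cv_folds = 3)
  rb1 <- train_eval_model(d$x, d$y, d$patient_id, split, grid = g,
                          backend = backend_xgboost())
  rb2 <- train_eval_model(d$x, d$y, d$patient_id, split, grid = g,
                          backend = backend_xgboost())
  expect_identical(rb1$auroc, rb2$auroc)
  expect_true(rb1$auroc > 0.9)
  expect_true(rb1$params$max_depth %in% c(2, 3))
})

test_that("labels independent of features give chance AUROC", {
  withr::with_seed(33, {
    n <- 2000
    x <- matrix(rnorm(n * 8), n, 8)
    y <- rbinom(n, 1, 0.4) # no relation to x
    pid <- sprintf("p%04d", seq_len(n))
    plan <- make_splits(tibble::tibble(patient_id = pid, label = y),
                        n_rep = 2, seed = 6)
    aucs <- vapply(plan$reps, function(rep) {
      train_eval_model(x, y, pid, rep, backend = backend_logistic())$auroc
    }, numeric(1))
    expect_true(all(abs(aucs - 0.5) < 0.05))
  })
})

test_that("the experiment engine covers the enumeration and is resumable", {
  withr::with_seed(13, {
    reg <- toy_registry()
    n <- 80
    x <- matrix(rnorm(n * sum(reg$dim)), n)
    y <- as.integer(x[, 1] + x[, 3] > 0) # sources a and b informative
    samples <- tibble::tibble(patient_id = sprintf("p%03d", 1:n), label = y)
    layout <- fusion_layout(reg$source, reg)
    enum <- enumerate_source_subsets(reg)
    splits <- make_splits(samples, n_rep = 2, seed = 1)
    tab <- run_experiment(x, layout, samples, enum, splits,
                          backend = backend_logistic(), task = "toy")
    expect_equal(nrow(tab), 7)
    expect_setequal(tab$bitmask, enum$bitmask)
    expect_true(all(tab$auroc_mean >= 0 & tab$auroc_mean <= 1))
    expect_true(all(tab$auroc_sd >= 0))
    # identical seeds -> identical table
    tab2 <- run_experiment(x, layout, samples, enum, splits,
                           backend = backend_logistic(), task = "toy")
    expect_equal(tab$auroc_mean, tab2$auroc_mean)
    # resumable: first 4 rows in a checkpoint are reused verbatim
    ck <- withr::local_tempfile(fileext = ".csv")
    readr::write_csv(tab[1:4, ], ck)
    tab3 <- run_experiment(x, layout, samples, enum, splits,
                           backend = backend_logistic(), task = "toy",
                           checkpoint = ck)
    expect_equal(tab3$auroc_mean, tab$auroc_mean)
  })
})

test_that("summaries compute the percent change against the baseline", {
  # hand-built table: singles at 0.6 and 0.8, pair at 0.77
  reg <- toy_registry()[1:2, ]
  tab <- tibble::tibble(
    task = "toy", bitmask = c("10", "01", "11"),
    n_sources = c(1, 1, 2), n_modalities = c(1, 1, 2),
    auroc_mean = c(0.6, 0.8, 0.77), auroc_sd = 0)
  tab <- structure(tab, layout = fusion_layout(reg$source, reg),
                   class = c("ehrf_auroc_table", class(tab)))
  sm <- summarize_auroc(tab)
  expect_equal(sm$baseline_auroc, 0.7)
  expect_equal(sm$delta$delta_auroc_pct, 10) # (0.77 - 0.7) / 0.7 * 100
  expect_equal(sm$by_cell$auroc_mean[sm$by_cell$n_sources == 1], 0.7)
  sm_best <- summarize_auroc(tab, baseline = "best")
  expect_equal(sm_best$baseline_auroc, 0.8)
  # constant table -> all deltas zero
  tabc <- tab; tabc$auroc_mean <- rep(0.7, 3)
  expect_equal(summarize_auroc(tabc)$delta$delta_auroc_pct, 0)
})
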