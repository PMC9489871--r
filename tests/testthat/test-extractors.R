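# independent brute-force statistics oracle for a single series
oracle_ts_features <- function(time, value) {
  n <- length(value)
  if (n == 0) return(numeric(11))
  if (n == 1) return(c(1, value, value, value, value, 0, 0, 0, 0, 0, 0))
  peaks <- 0
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      if (value[i] > value[i - 1] && value[i] > value[i + 1]) peaks <- peaks + 1
    }
  }
  slopes <- c(); achg <- c()
  for (i in 2:n) {
    dt <- time[i] - time[i - 1]
    if (dt > 0) {
      slopes <- c(slopes, (value[i] - value[i - 1]) / dt)
      achg <- c(achg, abs(value[i] - value[i - 1]) / dt)
    }
  }
  span <- time[n] - time[1]
  c(n, max(value), min(value), sum(value) / n, median(value),
    sqrt(sum((value - mean(value))^2) / n), sum((value - mean(value))^2) / n,
    peaks,
    if (length(slopes)) mean(slopes) else 0,
    if (length(achg)) mean(achg) else 0,
    if (span > 0) (value[n] - value[1]) / span else 0)
}

test_that("time-series statistics match the worked example and edge cases", {
  f <- embed_timeseries_signal(c(0, 1, 2), c(1, 3, 2))
  expect_equal(unname(f),
               c(3, 3, 1, 2, 2, sqrt(2 / 3), 2 / 3, 1, 0.5, 1.5, 0.5),
               tolerance = 1e-12)
  # constant series: no spread, no peaks, no slopes
  g <- embed_timeseries_signal(0:4, rep(7, 5))
  expect_equal(unname(g), c(5, 7, 7, 7, 7, 0, 0, 0, 0, 0, 0))
  expect_equal(unname(embed_timeseries_signal(numeric(0), numeric(0))),
               numeric(11))
  expect_equal(unname(embed_timeseries_signal(2, 9))[1:5], c(1, 9, 9, 9, 9))
  expect_error(embed_timeseries_signal(c(2, 1), c(0, 0)), "sorted")
  expect_error(embed_timeseries_signal(c(1, 2), c(0, NaN)), "finite")
})

test_that("time-series statistics agree with the brute-force oracle", {
  withr::with_seed(99, {
    for (rep in 1:300) {
      n <- sample(0:50, 1)
      time <- sort(round(runif(n, 0, 100), 2))
      value <- rnorm(n)
      expect_equal(unname(embed_timeseries_signal(time, value)),
                   oracle_ts_features(time, value), tolerance = 1e-9)
    }
  })
})

test_that("source embeddings have the registry dimensions and are local", {
  empty <- tibble::tibble(signal_name = character(), time_hours = double(),
                          value = double())
  expect_length(embed_timeseries_source(empty, "ce"), 99)
  expect_length(embed_timeseries_source(empty, "le"), 242)
  expect_length(embed_timeseries_source(empty, "pe"), 110)
  expect_length(timeseries_signals("le"), 22)
  # rows for one signal only touch that signal's block
  hr <- tibble::tibble(signal_name = "heart_rate",
                       time_hours = c(0, 2), value = c(60, 80))
  v <- embed_timeseries_source(hr, "ce")
  expect_true(all(v[12:99] == 0)) # all other signal blocks untouched
  expect_equal(unname(v[1]), 2)   # count slot of heart_rate
  expect_equal(unname(v[2]), 80)  # max slot
})

test_that("tabular embedding min-max normalises with clipping", {
  sch <- demographics_schema()
  at_min <- stats::setNames(as.list(sch$min), sch$name)
  expect_equal(unname(embed_tabular(at_min)), rep(0, 6))
  mid <- stats::setNames(as.list((sch$min + sch$max) / 2), sch$name)
  expect_equal(unname(embed_tabular(mid)), rep(0.5, 6))
  # missing entries are zero; out-of-range values clip with a warning
  expect_equal(unname(embed_tabular(list(age = 59))),
               c((59 - 18) / 82, 0, 0, 0, 0, 0))
  expect_warning(v <- embed_tabular(list(age = 300)), "clipped")
  expect_equal(unname(v[1]), 1)
})

test_that("text chunking is minimal and concatenation-preserving", {
  for (n in c(0, 1, 511, 512, 513, 1024, 1100, 2049)) {
    toks <- as.character(seq_len(n))
    ch <- chunk_text(toks)
    expect_length(ch, ceiling(n / 512))
    expect_identical(unlist(ch), if (n == 0) NULL else toks)
    expect_true(all(lengths(ch) <= 512))
  }
  expect_equal(lengths(chunk_text(as.character(1:1100))), c(512, 512, 76))
})

test_that("text source embedding averages chunk vectors", {
  # constant stub: output equals the constant regardless of chunking
  const_enc <- text_encoder(function(tokens) rep(0.25, 768))
  short <- tibble::tibble(time_hours = 0, text = "a b c")
  long <- tibble::tibble(time_hours = 0,
                         text = paste(rep("tok", 1300), collapse = " "))
  expect_equal(embed_text_source(short, const_enc), rep(0.25, 768))
  expect_equal(embed_text_source(long, const_enc), rep(0.25, 768))
  # antisymmetric encoder on two chunks averages to zero
  flip <- local({
    count <- 0
    text_encoder(function(tokens) {
      count <<- count + 1
      if (count %% 2) rep(1, 768) else rep(-1, 768)
    })
  })
  two_chunks <- tibble::tibble(time_hours = 0,
                               text = paste(rep("x", 1024), collapse = " "))
  expect_equal(embed_text_source(two_chunks, flip), rep(0, 768))
  # no notes and empty text give zero vectors
  none <- tibble::tibble(time_hours = double(), text = character())
  expect_equal(embed_text_source(none, const_enc), numeric(768))
  blank <- tibble::tibble(time_hours = 0, text = "   ")
  expect_equal(embed_text_source(blank, const_enc), numeric(768))
  # contract enforcement
  bad <- text_encoder(function(tokens) numeric(10))
  expect_error(embed_text_source(short, bad), "contract")
})

test_that("area resampling preserves range, constants and the global mean", {
  expect_equal(preprocess_image(matrix(0.3, 224, 224)),
               matrix(0.3, 224, 224))
  expect_equal(preprocess_image(matrix(0.7, 448, 448)),
               matrix(0.7, 224, 224))
  # 2x2-block checkerboard: mean conserved, range respected
  blk <- matrix(rep(c(0, 1), length.out = 448), 448, 448)
  out <- preprocess_image(blk)
  expect_true(all(out >= 0 & out <= 1))
  expect_equal(mean(out), mean(blk), tolerance = 1e-6)
  # non-integer ratio upsampling also conserves the mean
  odd <- matrix(runif(90 * 130), 90, 130)
  expect_equal(mean(preprocess_image(odd)), mean(odd), tolerance = 1e-6)
  expect_error(preprocess_image(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("image embeddings honour the model contract", {
  fixed <- image_model(function(img) list(prob = rep(0.5, 18),
                                          dense = rep(2, 1024)))
  study <- list(time_hours = 1, images = list(matrix(0.4, 10, 10)))
  out <- embed_image_single(study, fixed)
  expect_equal(out$prob, rep(0.5, 18))
  expect_equal(out$dense, rep(2, 1024))
  # faulty plug-in: probability outside [0,1]
  faulty <- image_model(function(img) list(prob = c(1.5, rep(0, 17)),
                                           dense = numeric(1024)))
  expect_error(embed_image_single(study, faulty), "contract")
  # multi-image averaging
  p_of_mean <- image_model(function(img) list(
    prob = c(rep(mean(img), 2), rep(0, 16)), dense = numeric(1024)))
  s1 <- list(time_hours = 1, images = list(matrix(0.2, 6, 6)))
  s2 <- list(time_hours = 2, images = list(matrix(0.6, 6, 6)))
  mv <- embed_image_multi(list(s1, s2), p_of_mean)
  expect_equal(mv$prob[1], 0.4, tolerance = 1e-12)
  # mean of one study equals the single-image output
  sv <- embed_image_single(s1, p_of_mean)
  mv1 <- embed_image_multi(list(s1), p_of_mean)
  expect_equal(mv1$prob, sv$prob)
  # permutation invariance of the study list
  expect_equal(embed_image_multi(list(s2, s1), p_of_mean)$prob, mv$prob)
})

test_that("stub encoders are deterministic, in-contract and injective", {
  enc <- stub_text_encoder(7)
  t1 <- enc$encode(c("alpha", "beta"))
  expect_identical(enc$encode(c("alpha", "beta")), t1)
  expect_length(t1, 768)
  mod <- stub_image_model(7)
  img <- matrix(runif(224 * 224), 224, 224)
  o1 <- mod$forward(img)
  expect_identical(mod$forward(img), o1)
  expect_true(all(o1$prob >= 0 & o1$prob <= 1))
  expect_length(o1$dense, 1024)
  # collision scan over distinct random inputs
  withr::with_seed(3, {
    outs <- vapply(1:200, function(i) {
      enc$encode(as.character(sample(1e6, 5)))[1:4]
    }, numeric(4))
    expect_equal(nrow(unique(t(outs))), 200)
  })
  # two different images give different dense vectors
  img2 <- img; img2[1, 1] <- img2[1, 1] / 2 + 0.25
  expect_false(identical(mod$forward(img2)$dense, o1$dense))
})
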