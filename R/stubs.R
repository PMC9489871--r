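#' Deterministic stub text encoder
#'
#' A drop-in [text_encoder()] for tests and synthetic cohorts, standing in
#' for a pretrained clinical-language transformer. Each chunk is mapped to
#' a 768-vector built from two parts: a *smooth* component driven by
#' summary statistics of the chunk (token count, mean token length,
#' digit-token fraction, and the mean value of numeric tokens — the
#' channel through which synthetic notes carry their latent signal), and a
#' *hash* component, a content-keyed pseudo-random vector that makes
#' distinct chunks produce distinct outputs with overwhelming
#' probability. Fully deterministic for fixed input and seed; never
#' touches R's global RNG.
#'
#' @param seed integer seed fixing the projection.
#' @return A [text_encoder()].
#' @export
stub_text_encoder <- function(seed = 1L) {
  d <- 768L
  proj <- matrix(lehmer_stream(seed + 97, 4 * d) - 0.5, nrow = d)
  encode <- function(tokens) {
    n <- length(tokens)
    nums <- suppressWarnings(as.numeric(tokens))
    num_frac <- mean(!is.na(nums))
    num_mean <- if (any(!is.na(nums))) mean(nums, na.rm = TRUE) else 0
    stats_vec <- c(log1p(n), mean(nchar(tokens)) / 10, num_frac, num_mean)
    smooth <- tanh(proj %*% stats_vec)
    h <- string_hash(tokens, seed)
    hashed <- lehmer_stream(h, d) - 0.5
    as.numeric(smooth + 0.1 * hashed)
  }
  text_encoder(encode)
}

#' Deterministic stub image model
#'
#' A drop-in [image_model()] standing in for a pretrained chest X-ray
#' classifier. The forward pass pools the preprocessed image into a small
#' statistics vector (mean, SD, quartiles, row/column-gradient energy,
#' quadrant means) and projects it through fixed seed-keyed random
#' matrices: a sigmoid-squashed 18-vector of "class probabilities" (always
#' in \[0, 1\]) and a tanh 1024-vector of "dense features". Smooth in the
#' pixel data, so synthetic images whose mean intensity encodes a latent
#' risk pass that signal through; a small content-keyed hash component
#' separates near-identical inputs.
#'
#' @param seed integer seed fixing the projections.
#' @return An [image_model()].
#' @export
stub_image_model <- function(seed = 1L) {
  p_dim <- 18L
  d_dim <- 1024L
  n_stats <- 11L
  wp <- matrix(lehmer_stream(seed + 11, p_dim * n_stats) - 0.5, nrow = p_dim)
  wd <- matrix(lehmer_stream(seed + 23, d_dim * n_stats) - 0.5, nrow = d_dim)
  forward <- function(img) {
    q <- stats::quantile(img, c(0.25, 0.5, 0.75), names = FALSE)
    h <- nrow(img); w <- ncol(img)
    s <- c(mean(img), stats::sd(img), q,
           mean(abs(diff(img))), mean(abs(t(diff(t(img))))),
           mean(img[1:(h %/% 2), 1:(w %/% 2)]),
           mean(img[1:(h %/% 2), (w %/% 2 + 1):w]),
           mean(img[(h %/% 2 + 1):h, 1:(w %/% 2)]),
           mean(img[(h %/% 2 + 1):h, (w %/% 2 + 1):w]))
    key <- string_hash(sprintf("%.6f", s), seed)
    jitter_p <- lehmer_stream(key, p_dim) - 0.5
    jitter_d <- lehmer_stream(key + 1, d_dim) - 0.5
    list(
      prob = stats::plogis(as.numeric(wp %*% (4 * s)) + 0.05 * jitter_p),
      dense = tanh(as.numeric(wd %*% s) + 0.05 * jitter_d)
    )
  }
  image_model(forward)
}
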