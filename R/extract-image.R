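#' Resample an image to 224 x 224 by pixel-area relations
#'
#' Area interpolation: each output pixel is the average of the input
#' pixels it covers, weighted by geometric overlap. This is exact for both
#' down- and up-sampling, preserves the global mean intensity, and keeps
#' every output value inside the input's intensity range. Implemented as
#' two dense weight-matrix multiplications, so a single call is a few
#' milliseconds even for large inputs.
#'
#' @param img numeric matrix (grayscale intensities, at least 1 pixel).
#' @param size output side lengths, default `c(224, 224)`.
#' @return `size[1] x size[2]` numeric matrix.
#' @export
preprocess_image <- function(img, size = c(224, 224)) {
  if (!is.matrix(img) || length(img) == 0) {
    abort("`img` must be a non-empty numeric matrix.")
  }
  if (!all(is.finite(img))) abort("Image intensities must be finite.")
  wr <- area_weights(nrow(img), size[1])
  wc <- area_weights(ncol(img), size[2])
  wr %*% img %*% t(wc)
}

# out_n x in_n row-stochastic overlap-weight matrix: entry [j, i] is the
# fraction of output cell j covered by input cell i.
area_weights <- function(in_n, out_n) {
  scale <- in_n / out_n
  w <- matrix(0, out_n, in_n)
  for (j in seq_len(out_n)) {
    lo <- (j - 1) * scale
    hi <- j * scale
    i0 <- floor(lo) + 1
    i1 <- min(ceiling(hi), in_n)
    for (i in i0:i1) {
      overlap <- min(hi, i) - max(lo, i - 1)
      if (overlap > 0) w[j, i] <- overlap / scale
    }
  }
  w
}

#' Construct an image-model contract
#'
#' An image model maps one preprocessed `224 x 224` grayscale array to a
#' pair of embeddings: an 18-dimensional class-probability vector (all
#' entries in \[0, 1\]) and a 1024-dimensional dense-feature vector (the
#' penultimate-layer activations of a chest X-ray classifier in the
#' reference configuration). Both dimensions are enforced on every call.
#'
#' @param forward `function(img224) -> list(prob = numeric(18),
#'   dense = numeric(1024))`.
#' @param prob_dim,dense_dim output dimensions (defaults 18 and 1024).
#' @param input_size expected input side length (default 224).
#' @return An object of class `image_model`.
#' @export
image_model <- function(forward, prob_dim = 18, dense_dim = 1024,
                        input_size = 224) {
  structure(list(forward = forward, prob_dim = prob_dim,
                 dense_dim = dense_dim, input_size = input_size),
            class = "image_model")
}

forward_checked <- function(model, img) {
  out <- model$forward(img)
  p <- out$prob; d <- out$dense
  if (length(p) != model$prob_dim || !all(is.finite(p)) ||
      any(p < 0) || any(p > 1)) {
    abort(paste0("Image model contract violated: probabilities must be ",
                 model$prob_dim, " finite values in [0, 1]."))
  }
  if (length(d) != model$dense_dim || !all(is.finite(d))) {
    abort(paste0("Image model contract violated: dense features must be ",
                 model$dense_dim, " finite values."))
  }
  list(prob = as.numeric(p), dense = as.numeric(d))
}

#' Single-image embeddings (most recent image)
#'
#' Preprocesses the most recent image of a study (its last image) to
#' `224 x 224` and runs it through the image model, returning the
#' probability (`vp`) and dense-feature (`vd`) vectors.
#'
#' @param study an image study (`list(time_hours, images)`).
#' @param model an [image_model()].
#' @return `list(prob = numeric(18), dense = numeric(1024))`.
#' @export
embed_image_single <- function(study, model) {
  if (length(study$images) < 1) abort("Study has no images.")
  img <- study$images[[length(study$images)]]
  sz <- model$input_size
  forward_checked(model, preprocess_image(img, c(sz, sz)))
}

#' Multi-image embeddings (all available images)
#'
#' Runs every image of every study (all planes and all past studies in the
#' window) through the model and averages the probability and dense
#' vectors element-wise, giving the aggregated `vmp` / `vmd` embeddings.
#'
#' @param studies non-empty list of image studies.
#' @param model an [image_model()].
#' @return `list(prob, dense)` of element-wise means.
#' @export
embed_image_multi <- function(studies, model) {
  if (length(studies) < 1) abort("`studies` must contain at least one study.")
  sz <- model$input_size
  outs <- list()
  for (st in studies) {
    for (img in st$images) {
      outs[[length(outs) + 1]] <-
        forward_checked(model, preprocess_image(img, c(sz, sz)))
    }
  }
  list(
    prob = rowMeans(vapply(outs, `[[`, numeric(model$prob_dim), "prob")),
    dense = rowMeans(vapply(outs, `[[`, numeric(model$dense_dim), "dense"))
  )
}
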