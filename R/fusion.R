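#' Fusion layout for a source subset
#'
#' Computes the contiguous (offset, length) block layout of a fusion
#' embedding restricted to a subset of sources, in canonical registry
#' order.
#'
#' @param subset character vector of source names (order irrelevant; the
#'   registry order is always used).
#' @param registry a source registry tibble (default [source_registry()]).
#' @return Tibble with columns `source`, `modality`, `offset` (0-based),
#'   `dim`.
#' @export
fusion_layout <- function(subset = NULL, registry = source_registry()) {
  if (is.null(subset)) subset <- registry$source
  bad <- setdiff(subset, registry$source)
  if (length(bad) > 0) {
    abort(paste0("Unknown source(s): ", paste(bad, collapse = ", ")))
  }
  if (length(subset) == 0) abort("Subset must be non-empty.")
  lay <- registry[registry$source %in% subset, ]
  lay$offset <- cumsum(c(0L, lay$dim[-nrow(lay)]))
  lay[c("source", "modality", "offset", "dim")]
}

#' Assemble a fusion embedding from per-source embeddings
#'
#' Concatenates per-source embedding vectors in canonical registry order,
#' restricted to `subset`. Every member's vector must have exactly its
#' registry dimension. The full default registry gives a 4845-dimensional
#' vector.
#'
#' @param embeddings named list of numeric vectors, keyed by source name.
#' @param subset character vector of sources to include (default: all
#'   registry sources).
#' @param registry source registry tibble.
#' @return Numeric vector with a `layout` attribute (see
#'   [fusion_layout()]).
#' @export
assemble_fusion <- function(embeddings, subset = NULL,
                            registry = source_registry()) {
  lay <- fusion_layout(subset, registry)
  parts <- lapply(seq_len(nrow(lay)), function(i) {
    src <- lay$source[i]
    v <- embeddings[[src]]
    if (is.null(v)) abort(paste0("No embedding supplied for source ", src, "."))
    v <- as.numeric(v)
    if (length(v) != lay$dim[i]) {
      abort(paste0("Embedding for ", src, " has length ", length(v),
                   "; registry requires ", lay$dim[i], "."))
    }
    v
  })
  structure(unlist(parts, use.names = FALSE), layout = lay)
}

#' Fit a per-feature normalizer on a training matrix
#'
#' Standardisation parameters (per-feature center and scale) estimated on
#' the training rows only. The scale is the population standard deviation;
#' zero-variance features get center = their constant value and scale = 1,
#' so they pass through as zeros. Apply never refits, which is the leakage
#' guard: test rows can never influence the transform.
#'
#' @param x numeric matrix (rows = samples).
#' @return An object of class `ehrf_normalizer`.
#' @export
fit_normalizer <- function(x) {
  x <- as.matrix(x)
  center <- colMeans(x)
  scale <- sqrt(colMeans(sweep(x, 2, center)^2))
  scale[scale <= 0 | !is.finite(scale)] <- 1
  structure(list(center = center, scale = scale, n_features = ncol(x)),
            class = "ehrf_normalizer")
}

#' Apply a fitted normalizer
#'
#' @param norm an `ehrf_normalizer` from [fit_normalizer()].
#' @param x matrix with the same number of features the normalizer was
#'   fitted on.
#' @return Standardised matrix.
#' @export
apply_normalizer <- function(norm, x) {
  if (!inherits(norm, "ehrf_normalizer")) abort("Not an ehrf_normalizer.")
  x <- as.matrix(x)
  if (ncol(x) != norm$n_features) {
    abort(paste0("Feature-count mismatch: normalizer fitted on ",
                 norm$n_features, " features, matrix has ", ncol(x), "."))
  }
  sweep(sweep(x, 2, norm$center), 2, norm$scale, "/")
}
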