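#' Enumerate every non-empty source subset
#'
#' Generates all `2^k - 1` non-empty subsets of the allowed sources and
#' annotates each with its size and the number of distinct modalities it
#' covers. With the 11-source registry this is 2047 subsets; excluding the
#' radiology-note source (pathology tasks) gives 1023, whose
#' modality-count groups have sizes 26 / 196 / 486 / 315.
#'
#' @param registry source registry tibble.
#' @param exclude sources to drop before enumeration.
#' @return Tibble with columns `bitmask` (character over the canonical
#'   order of `registry`), `sources` (list-column of name vectors),
#'   `n_sources`, `n_modalities`.
#' @export
enumerate_source_subsets <- function(registry = source_registry(),
                                     exclude = NULL) {
  if (!is.null(exclude)) registry <- registry[!registry$source %in% exclude, ]
  k <- nrow(registry)
  if (k == 0) abort("All sources excluded; nothing to enumerate.")
  if (k > 20) abort("Exhaustive enumeration capped at 20 sources.")
  masks <- seq_len(2^k - 1)
  member <- outer(masks, seq_len(k) - 1,
                  function(m, b) bitwAnd(m, bitwShiftL(1L, b)) > 0)
  sources <- apply(member, 1, function(row) registry$source[row],
                   simplify = FALSE)
  n_modalities <- apply(member, 1, function(row) {
    length(unique(registry$modality[row]))
  })
  tibble::tibble(
    bitmask = apply(member, 1, function(row)
      paste(as.integer(row), collapse = "")),
    sources = sources,
    n_sources = rowSums(member),
    n_modalities = n_modalities
  )
}

#' Subset bitmask helpers
#'
#' `subset_bitmask()` encodes a set of source names as a fixed-width 0/1
#' string over the canonical registry order; `bitmask_sources()` decodes
#' it back.
#'
#' @param sources character vector of source names.
#' @param bitmask character scalar of 0/1 over the registry order.
#' @param registry source registry tibble.
#' @return A bitmask string / a character vector of source names.
#' @export
subset_bitmask <- function(sources, registry = source_registry()) {
  bad <- setdiff(sources, registry$source)
  if (length(bad) > 0) abort(paste0("Unknown sources: ",
                                    paste(bad, collapse = ", ")))
  paste(as.integer(registry$source %in% sources), collapse = "")
}

#' @rdname subset_bitmask
#' @export
bitmask_sources <- function(bitmask, registry = source_registry()) {
  bits <- as.integer(strsplit(bitmask, "")[[1]])
  if (length(bits) != nrow(registry)) {
    abort("Bitmask width does not match the registry.")
  }
  registry$source[bits == 1]
}
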