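#' Build the coalition value function from an AUROC table
#'
#' Wraps a completed subset-ablation table as the value function of a
#' cooperative game whose players are the data sources: `v(S)` is the mean
#' test AUROC of the model trained on subset `S`, and the empty coalition
#' is valued at 0.5 (the AUROC of a model with no data is chance).
#'
#' @param table an `ehrf_auroc_table` covering every non-empty subset of
#'   its sources.
#' @param v_empty value of the empty coalition (default 0.5).
#' @return A list of class `ehrf_value_function` with fields `sources`,
#'   `modality` (named vector), `v` (lookup by mask integer) and
#'   `v_empty`.
#' @export
value_function <- function(table, v_empty = 0.5) {
  layout <- attr(table, "layout")
  width <- nchar(table$bitmask[1])
  # restrict to the sources that actually vary in the table
  bits <- do.call(rbind, lapply(strsplit(table$bitmask, ""), as.integer))
  active <- which(colSums(bits) > 0)
  k <- length(active)
  if (2^k - 1 != nrow(table) ||
      nrow(unique(as.data.frame(bits[, active, drop = FALSE]))) != nrow(table)) {
    abort("Table must contain every non-empty subset of its sources exactly once.")
  }
  mask <- as.integer(bits[, active, drop = FALSE] %*% 2^(seq_len(k) - 1))
  v <- rep(NA_real_, 2^k)
  v[1] <- v_empty
  v[mask + 1] <- table$auroc_mean
  srcs <- if (!is.null(layout)) layout$source[active] else
    paste0("s", seq_len(k))
  modality <- if (!is.null(layout)) {
    stats::setNames(layout$modality[active], srcs)
  } else {
    stats::setNames(rep(NA_character_, k), srcs)
  }
  structure(list(sources = srcs, modality = modality, v = v,
                 v_empty = v_empty, width = width, active = active),
            class = "ehrf_value_function")
}

# accept either an ehrf_value_function or a plain named numeric vector v
# indexed by mask + 1 (v[1] = empty coalition)
as_game <- function(v, sources = NULL) {
  if (inherits(v, "ehrf_value_function")) return(v)
  if (inherits(v, "ehrf_auroc_table")) return(value_function(v))
  if (is.null(sources)) abort("Supply `sources` with a raw value vector.")
  k <- length(sources)
  if (length(v) != 2^k) abort(paste0("Raw value vector must have length 2^",
                                     k, "."))
  if (any(is.na(v))) abort("Value function has missing subset values.")
  structure(list(sources = sources,
                 modality = stats::setNames(rep(NA_character_, k), sources),
                 v = as.numeric(v), v_empty = v[1]),
            class = "ehrf_value_function")
}

#' Exact Shapley values of the data sources
#'
#' Computes, for every source i, the exact Shapley value
#' \deqn{\phi_i = \sum_{S \subseteq N \setminus \{i\}}
#'   \frac{|S|!\,(k-|S|-1)!}{k!}\,[v(S \cup \{i\}) - v(S)]}
#' by full summation over all `2^(k-1)` coalitions per source. Efficiency
#' (`sum(phi) = v(N) - v(empty)`) holds by construction; the residual
#' after floating-point summation is reported, never absorbed.
#'
#' @param v an `ehrf_value_function`, an `ehrf_auroc_table`, or a raw
#'   numeric vector of length `2^k` indexed by coalition mask + 1.
#' @param sources player names (required only with a raw vector).
#' @return An `ehrf_attribution`: tibble with columns `source`,
#'   `modality`, `phi`, and attributes `v_full`, `v_empty`, `residual`.
#' @examples
#' # two-player game: v(0)=.5, v(A)=.7, v(B)=.6, v(AB)=.8
#' shapley_sources(c(.5, .7, .6, .8), sources = c("A", "B"))
#' @export
shapley_sources <- function(v, sources = NULL) {
  g <- as_game(v, sources)
  k <- length(g$sources)
  if (k > 15) {
    abort(paste0("Exact Shapley enumeration capped at 15 sources (got ", k,
                 "); subsample the game or aggregate sources first."))
  }
  if (any(is.na(g$v))) {
    miss <- which(is.na(g$v)) - 1
    abort(paste0("Value function missing subset(s), e.g. mask ", miss[1], "."))
  }
  masks <- 0:(2^k - 1)
  sizes <- vapply(masks, function(m) sum(bitwAnd(m, 2^(0:(k - 1))) > 0),
                  numeric(1))
  lf <- lfactorial(0:k)
  # weight |S|! (k-|S|-1)! / k! for a coalition S not containing i;
  # the full coalition never occurs as such an S, so its weight is moot
  w <- numeric(length(masks))
  proper <- sizes < k
  w[proper] <- exp(lf[sizes[proper] + 1] + lf[k - sizes[proper]] - lf[k + 1])
  phi <- numeric(k)
  for (i in seq_len(k)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- masks[bitwAnd(masks, bit) == 0]
    phi[i] <- sum(w[without + 1] *
                    (g$v[bitwOr(without, bit) + 1] - g$v[without + 1]))
  }
  v_full <- g$v[2^k]
  out <- tibble::tibble(source = g$sources,
                        modality = unname(g$modality[g$sources]),
                        phi = phi)
  structure(out,
            v_full = v_full, v_empty = g$v_empty,
            residual = sum(phi) - (v_full - g$v_empty),
            class = c("ehrf_attribution", class(out)))
}

#' Permutation-based Shapley oracle
#'
#' Independent cross-check of [shapley_sources()]: averages each source's
#' marginal contribution over all `k!` orderings. Factorial cost, so it
#' refuses games with more than 8 players.
#'
#' @inheritParams shapley_sources
#' @return Named numeric vector of Shapley values.
#' @export
shapley_permutation <- function(v, sources = NULL) {
  g <- as_game(v, sources)
  k <- length(g$sources)
  if (k > 8) abort("Permutation oracle refuses k > 8 (factorial blow-up).")
  perms <- permutations_of(k)
  phi <- numeric(k)
  for (p in perms) {
    mask <- 0L
    for (i in p) {
      new_mask <- bitwOr(mask, bitwShiftL(1L, i - 1L))
      phi[i] <- phi[i] + g$v[new_mask + 1] - g$v[mask + 1]
      mask <- new_mask
    }
  }
  stats::setNames(phi / length(perms), g$sources)
}

permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  sub <- permutations_of(k - 1L)
  out <- list()
  for (p in sub) {
    for (pos in 0:(k - 1L)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos)
    }
  }
  out
}

#' Aggregate source Shapley values into modality values
#'
#' The modality-level attribution is the sum of its member sources'
#' Shapley values, so efficiency carries through:
#' `sum(Phi) = sum(phi) = v(full) - v(empty)`.
#'
#' @param attribution an `ehrf_attribution` from [shapley_sources()]. If
#'   its `modality` column is empty, supply `registry`.
#' @param registry optional source registry to look modalities up in.
#' @return Tibble with columns `modality`, `Phi`.
#' @export
aggregate_modalities <- function(attribution, registry = NULL) {
  mod <- attribution$modality
  if (any(is.na(mod))) {
    if (is.null(registry)) abort("Sources lack modality assignments; supply `registry`.")
    mod <- registry$modality[match(attribution$source, registry$source)]
    if (any(is.na(mod))) {
      abort(paste0("Source(s) not in registry: ",
                   paste(attribution$source[is.na(mod)], collapse = ", ")))
    }
  }
  tibble::tibble(modality = mod, phi = attribution$phi) %>%
    dplyr::group_by(.data$modality) %>%
    dplyr::summarise(Phi = sum(.data$phi), .groups = "drop")
}

#' The four-player modality game
#'
#' Alternative modality-level attribution: a cooperative game whose
#' players are the modalities themselves. The value of a modality
#' coalition M is the average AUROC over all subsets in the table whose
#' modality coverage is exactly M (for a single modality this averages all
#' models built from that modality's sources); the empty coalition is
#' 0.5. Emitted alongside the source-sum aggregation because the two
#' readings of "aggregated" modality values differ and both are
#' defensible.
#'
#' @param table an `ehrf_auroc_table`.
#' @param v_empty empty-coalition value (default 0.5).
#' @return An `ehrf_attribution` over modalities.
#' @export
shapley_modality_game <- function(table, v_empty = 0.5) {
  layout <- attr(table, "layout")
  if (is.null(layout)) abort("Table lacks a registry layout attribute.")
  mods <- unique(layout$modality)
  k <- length(mods)
  cover <- vapply(strsplit(table$bitmask, ""), function(bits) {
    m <- unique(layout$modality[which(bits == "1")])
    sum(2^(match(m, mods) - 1))
  }, numeric(1))
  v <- rep(NA_real_, 2^k)
  v[1] <- v_empty
  means <- tapply(table$auroc_mean, cover, mean)
  v[as.integer(names(means)) + 1] <- as.numeric(means)
  if (any(is.na(v))) {
    abort("Some modality coalitions have no subsets in the table.")
  }
  out <- shapley_sources(v, sources = mods)
  out$modality <- mods
  out
}

#' @export
print.ehrf_attribution <- function(x, ...) {
  cat("<ehrf_attribution>  v(full) = ", round(attr(x, "v_full"), 4),
      ", v(empty) = ", attr(x, "v_empty"),
      ", efficiency residual = ", format(attr(x, "residual"), digits = 3),
      "\n", sep = "")
  NextMethod()
}
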