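#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an attribution result
#'
#' @param x an `ehrf_attribution`.
#' @param ... unused.
#' @return Tibble with `source`, `modality`, `phi` and the cumulative
#'   value `v_cum = v(empty) + cumsum(phi)` used by waterfall displays.
#' @method tidy ehrf_attribution
#' @export
tidy.ehrf_attribution <- function(x, ...) {
  tibble::tibble(
    source = x$source,
    modality = x$modality,
    phi = x$phi,
    v_cum = attr(x, "v_empty") + cumsum(x$phi)
  )
}

#' Glance at an attribution result
#'
#' @param x an `ehrf_attribution`.
#' @param ... unused.
#' @return One-row tibble: number of players, `v_full`, `v_empty`, the
#'   attributed total `sum(phi)` and the efficiency residual.
#' @method glance ehrf_attribution
#' @export
glance.ehrf_attribution <- function(x, ...) {
  tibble::tibble(
    n_players = nrow(x),
    v_full = attr(x, "v_full"),
    v_empty = attr(x, "v_empty"),
    phi_total = sum(x$phi),
    residual = attr(x, "residual")
  )
}

#' Glance at an AUROC table
#'
#' @param x an `ehrf_auroc_table`.
#' @param ... unused.
#' @return One-row tibble: subset count, best subset and its AUROC, mean
#'   single-source AUROC and the full-fusion AUROC.
#' @method glance ehrf_auroc_table
#' @export
glance.ehrf_auroc_table <- function(x, ...) {
  best <- which.max(x$auroc_mean)
  tibble::tibble(
    n_subsets = nrow(x),
    best_bitmask = x$bitmask[best],
    best_auroc = x$auroc_mean[best],
    single_source_mean = mean(x$auroc_mean[x$n_sources == 1]),
    full_fusion_auroc = x$auroc_mean[which.max(x$n_sources)]
  )
}
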