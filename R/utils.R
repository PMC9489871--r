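#' @importFrom rlang abort warn .data
#' @importFrom dplyr %>%
NULL

assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min) {
    abort(paste0("`", name, "` must be a single finite number",
                 if (is.finite(min)) paste0(" >= ", min), "."))
  }
  invisible(x)
}

# Lehmer / Park-Miller generator with Schrage's decomposition; gives the
# deterministic stub encoders a random stream that never touches R's
# global RNG state.  All arithmetic stays below 2^31 so doubles are exact.
lehmer_stream <- function(seed, n) {
  m <- 2147483647
  a <- 16807
  q <- 127773 # m %/% a
  r <- 2836   # m %% a
  s <- seed %% m
  if (s <= 0) s <- s + m - 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    hi <- s %/% q
    lo <- s %% q
    s <- a * lo - r * hi
    if (s <= 0) s <- s + m
    out[i] <- s / m
  }
  out
}

# polynomial rolling hash of a character vector -> integer in [1, 2^31-2]
string_hash <- function(x, seed = 1L) {
  m <- 2147483647
  h <- seed %% m
  for (tok in x) {
    for (code in utf8ToInt(tok)) {
      # h = (h*31 + code) mod m, kept exact in doubles via splitting
      h <- (h * 31 + code) %% m
    }
    h <- (h * 31 + 7) %% m
  }
  h + 1
}

`%||%` <- function(x, y) if (is.null(x)) y else x

sort_by_name <- function(x) {
  if (length(x) <= 1 || is.null(names(x))) return(x)
  x[order(names(x))]
}
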