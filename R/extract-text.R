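#' Split a token sequence into encoder-sized chunks
#'
#' Greedy contiguous chunking into the smallest possible number of pieces
#' of at most `max_tokens` tokens (`ceiling(n / max_tokens)` chunks);
#' concatenating the chunks reproduces the input exactly.
#'
#' @param tokens character vector of tokens.
#' @param max_tokens maximum chunk length (default 512, the usual
#'   transformer-encoder input limit).
#' @return List of character vectors; empty input gives an empty list.
#' @export
chunk_text <- function(tokens, max_tokens = 512) {
  assert_scalar_number(max_tokens, "max_tokens", min = 1)
  n <- length(tokens)
  if (n == 0) return(list())
  starts <- seq(1, n, by = max_tokens)
  lapply(starts, function(s) tokens[s:min(s + max_tokens - 1, n)])
}

#' Whitespace tokenizer
#'
#' Default tokenizer used for chunking: splits on runs of whitespace and
#' drops empty tokens. Real encoder plug-ins may supply their own
#' tokenizer; the chunking contract only needs a consistent count.
#'
#' @param text a single string.
#' @return Character vector of tokens.
#' @export
tokenize_whitespace <- function(text) {
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Construct a text-encoder contract
#'
#' A text encoder is a deterministic function from a token chunk (at most
#' `max_tokens` tokens) to a fixed 768-dimensional vector, plus the
#' tokenizer it expects. [embed_text_source()] enforces the output
#' dimension on every call.
#'
#' @param encode `function(tokens) -> numeric(768)`.
#' @param tokenizer `function(text) -> character vector`
#'   (default [tokenize_whitespace()]).
#' @param max_tokens chunk size limit (default 512).
#' @param output_dim encoder output dimension (default 768).
#' @return An object of class `text_encoder`.
#' @export
text_encoder <- function(encode, tokenizer = tokenize_whitespace,
                         max_tokens = 512, output_dim = 768) {
  structure(list(encode = encode, tokenizer = tokenizer,
                 max_tokens = max_tokens, output_dim = output_dim),
            class = "text_encoder")
}

#' Embed one free-text note source
#'
#' Concatenates all note bodies in time order into one continuous string,
#' tokenizes, splits into the minimal number of `max_tokens`-sized chunks,
#' encodes each chunk, and returns the unweighted element-wise mean of the
#' chunk vectors. No notes (or all-empty text) gives the zero vector, so
#' the fusion layout stays fixed when a source is absent.
#'
#' @param notes tibble with columns `time_hours`, `text` (may have 0 rows).
#' @param encoder a [text_encoder()].
#' @return Numeric vector of length `encoder$output_dim`.
#' @export
embed_text_source <- function(notes, encoder) {
  if (!inherits(encoder, "text_encoder")) abort("`encoder` must be a text_encoder.")
  d <- encoder$output_dim
  if (is.null(notes) || nrow(notes) == 0) return(numeric(d))
  txt <- paste(notes$text[order(notes$time_hours)], collapse = " ")
  tokens <- encoder$tokenizer(txt)
  if (length(tokens) == 0) return(numeric(d))
  chunks <- chunk_text(tokens, encoder$max_tokens)
  vecs <- lapply(chunks, function(ch) {
    v <- encoder$encode(ch)
    if (length(v) != d || !all(is.finite(v))) {
      abort(paste0("Text encoder contract violated: expected finite ",
                   "vector of length ", d, ", got length ", length(v), "."))
    }
    v
  })
  rowMeans(matrix(unlist(vecs), nrow = d))
}
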