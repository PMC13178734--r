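#' Tokenize text for hashing and keyword scoring
#'
#' Case-folds, then extracts contiguous runs of letters; CJK (Han, kana,
#' Hangul) characters are emitted as single-character tokens so the scheme
#' works without a word segmenter.
#'
#' @param text Character vector.
#' @return List of character vectors, one per input element.
#' @export
tokenize_text <- function(text) {
  cjk <- "\\p{Han}\\p{Hiragana}\\p{Katakana}\\p{Hangul}"
  pat <- sprintf("[%s]|[[\\p{L}]-[%s]]+", cjk, cjk)
  stringr::str_extract_all(stringr::str_to_lower(text), pat)
}

#' Hash a token to a bucket index
#'
#' Fixed, seedless djb2-style hash over code points, reduced modulo `dim`.
#' Exposed so tests can verify bucket assignments of chosen tokens.
#'
#' @param token Character vector of tokens.
#' @param dim Number of buckets.
#' @return Integer bucket indices in `1:dim`.
#' @export
hash_bucket <- function(token, dim) {
  vapply(token, function(tok) {
    h <- 5381
    for (c in utf8ToInt(tok)) h <- (h * 33 + c) %% 2147483647
    as.integer(h %% dim) + 1L
  }, integer(1), USE.NAMES = FALSE)
}

#' Deterministic hashed term-frequency embedding
#'
#' The default text embedder: token frequencies hashed into `dim` buckets
#' with a fixed seedless hash, then L2-normalized. Deterministic, needs no
#' model download, and honors the embedding contract (unit norm, or the zero
#' vector for empty text); any stronger sentence embedder with the same
#' contract can be plugged into the downstream graph builders.
#'
#' @param text A single string.
#' @param dim Embedding dimension (>= 8), default 256.
#' @return Numeric vector of length `dim` with unit L2 norm (or all zeros).
#' @export
embed_text <- function(text, dim = 256L) {
  stopifnot(dim >= 8)
  v <- numeric(dim)
  if (is.na(text) || !nzchar(text)) return(v)
  toks <- tokenize_text(text)[[1]]
  if (length(toks) == 0) return(v)
  tab <- table(hash_bucket(toks, dim))
  v[as.integer(names(tab))] <- as.numeric(tab)
  v / sqrt(sum(v^2))
}

#' Embed many texts into a matrix
#'
#' @param texts Named character vector (names become row names).
#' @param dim Embedding dimension.
#' @return Matrix with one unit-norm (or zero) row per text.
#' @export
embed_texts <- function(texts, dim = 256L) {
  m <- t(vapply(texts, embed_text, numeric(dim), dim = dim))
  rownames(m) <- names(texts)
  m
}

#' @rdname embed_texts
#' @param corpus A [med_corpus()].
#' @export
embed_documents <- function(corpus, dim = 256L) {
  embed_texts(
    stats::setNames(corpus$documents$text, corpus$documents$doc_id), dim
  )
}

#' @rdname embed_texts
#' @export
embed_paragraphs <- function(corpus, dim = 256L) {
  embed_texts(
    stats::setNames(corpus$paragraphs$text, corpus$paragraphs$par_id), dim
  )
}

#' Cosine similarity of two embedding vectors
#'
#' For unit vectors this is the dot product; pairs involving a zero vector
#' have similarity 0 by convention.
#'
#' @param u,v Numeric vectors of equal length.
#' @return Similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) {
    stop("dimension mismatch: ", length(u), " vs ", length(v), call. = FALSE)
  }
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  min(1, max(-1, sum(u * v) / (nu * nv)))
}

# all-pairs cosine for rows of a matrix; zero rows give 0 similarity
cosine_matrix <- function(m) {
  norms <- sqrt(rowSums(m^2))
  safe <- ifelse(norms == 0, 1, norms)
  u <- m / safe
  s <- tcrossprod(u)
  s[] <- pmin(1, pmax(-1, s))
  s
}
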