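#' Deterministic hashed character n-gram encoder
#'
#' An *encoder* maps text to a fixed-dimension unit-norm vector; mentions
#' and dictionary terms are embedded independently and compared by cosine
#' similarity (the biencoder architecture). The reference encoder is a
#' deterministic, download-free instance of that contract: the text is
#' case-folded, padded with boundary markers, decomposed into character
#' n-grams, each n-gram hashed into one of `dim` buckets, the bucket counts
#' term-frequency weighted and L2-normalized. Identical strings always map
#' to identical unit vectors, and strings sharing substrings share n-gram
#' mass, so lexical similarity translates into cosine similarity. Trained
#' sentence embedders plug into the same contract for production use.
#'
#' @param dim Embedding dimension; a power of two, at least 1024.
#' @param ngram Character n-gram size (default 3).
#' @return An object of class `"phen_encoder"` with elements `embed`
#'   (`function(texts)` returning a `length(texts) x dim` matrix of unit
#'   rows), `dim` and `ngram`.
#' @examples
#' enc <- reference_encoder()
#' v <- enc$embed(c("Hypotonia", "Generalized hypotonia"))
#' sum(v[1, ] * v[2, ])   # cosine similarity
#' @export
reference_encoder <- function(dim = 1024L, ngram = 3L) {
  dim <- as.integer(dim)
  if (dim < 1024L || bitwAnd(dim, dim - 1L) != 0L) {
    abort("`dim` must be a power of two >= 1024.")
  }
  ngram <- as.integer(ngram)
  stopifnot(ngram >= 1L)
  pad <- strrep("#", ngram - 1L)

  embed_one <- function(text) {
    if (is.na(text) || !nzchar(trimws(text))) {
      abort("Cannot embed empty text (zero information).")
    }
    x <- paste0(pad, tolower(trimws(text)), pad)
    n <- nchar(x)
    grams <- substring(x, seq_len(n - ngram + 1L), seq_len(n - ngram + 1L) + ngram - 1L)
    buckets <- vapply(grams, hash_gram, integer(1), dim = dim, USE.NAMES = FALSE)
    v <- numeric(dim)
    tab <- table(buckets)
    v[as.integer(names(tab)) + 1L] <- as.numeric(tab)
    v / sqrt(sum(v^2))
  }

  structure(
    list(
      embed = function(texts) {
        out <- t(vapply(as.character(texts), embed_one, numeric(dim),
                        USE.NAMES = FALSE))
        if (length(texts) == 0L) out <- matrix(numeric(0), 0L, dim)
        out
      },
      dim = dim,
      ngram = ngram
    ),
    class = "phen_encoder"
  )
}

# Polynomial byte hash into [0, dim). Deterministic across platforms.
hash_gram <- function(gram, dim) {
  h <- 0
  for (b in utf8ToInt(gram)) {
    h <- (h * 131 + b) %% dim
  }
  as.integer(h)
}
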