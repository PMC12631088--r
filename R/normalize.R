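#' Embedding index over a dictionary
#'
#' Embeds every dictionary surface (synonyms are separate rows -- candidate
#' generation operates on surfaces, not on deduplicated identifiers) with a
#' fixed encoder. Rows of the embedding matrix align with dictionary rows.
#' Rebuilding from the same inputs is bitwise reproducible.
#'
#' @param dict A dictionary tibble (see [load_dictionary()]).
#' @param encoder A `"phen_encoder"` (default [reference_encoder()]).
#' @return An object of class `"phen_index"`.
#' @export
build_index <- function(dict, encoder = reference_encoder()) {
  dict <- validate_dictionary(dict)
  stopifnot(inherits(encoder, "phen_encoder"))
  structure(
    list(
      entries = dict,
      embeddings = encoder$embed(dict$surface),
      encoder = encoder
    ),
    class = "phen_index"
  )
}

#' @export
print.phen_index <- function(x, ...) {
  cat(sprintf("<phen_index> %d surfaces, %d identifiers, dim %d\n",
              nrow(x$entries), length(unique(x$entries$hpo_id)),
              x$encoder$dim))
  invisible(x)
}

#' Generate normalization candidates by cosine similarity
#'
#' Scores the mention surface against every indexed dictionary surface by
#' cosine similarity and returns the top `k`, sorted by score descending
#' with deterministic tie-breaking (surface, then identifier). The same
#' identifier may appear more than once when several of its synonyms rank
#' highly; `k` counts surfaces, not identifiers.
#'
#' @param surface Non-empty mention surface.
#' @param index A `"phen_index"` from [build_index()].
#' @param k Number of candidates to retrieve (default 30).
#' @return A tibble of candidates: `hpo_id`, `surface`, `is_preferred`,
#'   `score` (non-increasing, in `[-1, 1]`).
#' @export
generate_candidates <- function(surface, index, k = 30L) {
  stopifnot(inherits(index, "phen_index"))
  if (!is.character(surface) || length(surface) != 1L || is.na(surface) ||
      !nzchar(trimws(surface))) {
    abort("`surface` must be a non-empty string.")
  }
  if (nrow(index$entries) == 0L) abort("Empty index.")
  q <- index$encoder$embed(surface)[1L, ]
  scores <- pmin(pmax(as.vector(index$embeddings %*% q), -1), 1)
  ord <- order(-scores, index$entries$surface, index$entries$hpo_id)
  take <- ord[seq_len(min(as.integer(k), length(ord)))]
  out <- index$entries[take, ]
  out$score <- scores[take]
  out
}

#' Token-set Dice reranker
#'
#' A *reranker* scores a (mention surface, candidate term) pair jointly; the
#' reference reranker is the Dice coefficient over case-folded word token
#' sets, `2|A . B| / (|A| + |B|)`. It is deterministic and dependency-free
#' while preserving the cross-encoder architecture: candidates retrieved by
#' the biencoder are independently rescored pairwise. Trained cross-encoders
#' satisfy the same contract.
#'
#' @return A function `function(surface, term)` returning a scalar score,
#'   of class `"phen_reranker"`.
#' @examples
#' rr <- dice_reranker()
#' rr("Abdominal wall hernia", "Hernia of the abdominal wall")
#' @export
dice_reranker <- function() {
  token_set <- function(x) unique(strsplit(tolower(trimws(x)), "\\s+")[[1]])
  structure(
    function(surface, term) {
      a <- token_set(surface)
      b <- token_set(term)
      if (length(a) + length(b) == 0L) return(0)
      2 * length(intersect(a, b)) / (length(a) + length(b))
    },
    class = c("phen_reranker", "function")
  )
}

#' Rerank candidates with a pairwise scorer
#'
#' Rescores every candidate with the reranker and re-sorts descending with
#' the same tie rule as [generate_candidates()] (score, surface,
#' identifier). The candidate set itself is unchanged -- reranking is a
#' permutation.
#'
#' @param surface Mention surface.
#' @param candidates Candidate tibble from [generate_candidates()].
#' @param reranker A reranker function (default [dice_reranker()]).
#' @return The candidate tibble reordered, with `score` replaced by the
#'   reranker score.
#' @export
rerank <- function(surface, candidates, reranker = dice_reranker()) {
  stopifnot(is.data.frame(candidates))
  if (nrow(candidates) == 0L) abort("Candidate list is empty.")
  scores <- vapply(candidates$surface, function(term) reranker(surface, term),
                   numeric(1), USE.NAMES = FALSE)
  out <- candidates
  out$score <- scores
  out[order(-scores, candidates$surface, candidates$hpo_id), ]
}

#' Normalize a mention surface to an HPO identifier
#'
#' Runs candidate generation then reranking and returns the identifier of
#' the top-ranked candidate -- only the top score is kept.
#'
#' @param surface Mention surface (scalar for `normalize_mention()`; a
#'   vector for `normalize_mentions()`).
#' @param index A `"phen_index"`, or a dictionary tibble (then embedded with
#'   `encoder` on the fly).
#' @param reranker A reranker function (default [dice_reranker()]).
#' @param k Candidate list size (default 30).
#' @param encoder Used only when `index` is a dictionary tibble.
#' @return The winning `hpo_id` (character).
#' @examples
#' dict <- tibble::tibble(hpo_id = c("HP:0001252", "HP:0001290"),
#'                        surface = c("Hypotonia", "Generalized hypotonia"),
#'                        is_preferred = TRUE)
#' normalize_mention("Hypotonia", dict)
#' @export
normalize_mention <- function(surface, index, reranker = dice_reranker(),
                              k = 30L, encoder = reference_encoder()) {
  index <- as_phen_index(index, encoder)
  reranked <- rerank(surface, generate_candidates(surface, index, k), reranker)
  reranked$hpo_id[[1L]]
}

#' @rdname normalize_mention
#' @export
normalize_mentions <- function(surface, index, reranker = dice_reranker(),
                               k = 30L, encoder = reference_encoder()) {
  index <- as_phen_index(index, encoder)
  map_chr(surface, normalize_mention, index = index, reranker = reranker, k = k)
}

as_phen_index <- function(index, encoder) {
  if (inherits(index, "phen_index")) return(index)
  build_index(index, encoder)
}
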