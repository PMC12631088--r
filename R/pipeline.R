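#' Run the two-stage extraction and normalization pipeline
#'
#' For every observation: generate a target string with the backend, decode
#' it into labeled surfaces, ground each surface to character offsets, and
#' normalize the grounded key findings to HPO identifiers (normal findings
#' are kept in the span output but never enter normalization -- they have no
#' HPO representation). Ungrounded surfaces and unparseable segments are
#' dropped from the output but counted, since they cost precision and must
#' stay visible.
#'
#' @param observations A tibble with columns `observation_id` and `text`
#'   (e.g. [corpus_observations()] of a gold corpus).
#' @param backend A generation backend (see [stub_backend()]).
#' @param index A `"phen_index"` or a dictionary tibble (embedded with
#'   `encoder` on the fly); `NULL` skips normalization entirely.
#' @param reranker,k,encoder Normalization components, as in
#'   [normalize_mention()].
#' @param max_fragments Passed to [ground_surface()].
#' @return A predictions corpus tibble. Attributes `"n_skipped"` (segments
#'   without a recognized label) and `"n_ungrounded"` (surfaces with no
#'   feasible placement) carry the loss counts; `"ungrounded"` holds the
#'   dropped surfaces themselves.
#' @export
run_pipeline <- function(observations, backend, index = NULL,
                         reranker = dice_reranker(), k = 30L,
                         encoder = reference_encoder(), max_fragments = 3L) {
  stopifnot(is.data.frame(observations),
            all(c("observation_id", "text") %in% names(observations)),
            is.function(backend))
  if (!is.null(index)) index <- as_phen_index(index, encoder)
  if (nrow(observations) == 0L) {
    return(structure(phen_corpus(character(), character())[0L, ],
                     n_skipped = 0L, n_ungrounded = 0L,
                     ungrounded = tibble(observation_id = character(),
                                         label = character(),
                                         surface = character())))
  }
  n_skipped <- 0L
  ungrounded <- list()
  norm_cache <- new.env(parent = emptyenv())

  rows <- lapply(seq_len(nrow(observations)), function(i) {
    oid <- observations$observation_id[[i]]
    text <- observations$text[[i]]
    result <- tryCatch({
      decoded <- decode_target(backend(text))
      n_skipped <<- n_skipped + attr(decoded, "n_skipped")
      g <- ground_all(text, decoded, max_fragments, observation_id = oid)
      if (nrow(g$ungrounded) > 0L) {
        ungrounded[[length(ungrounded) + 1L]] <<-
          mutate(g$ungrounded, observation_id = oid)
      }
      mentions <- g$mentions
      if (!is.null(index) && nrow(mentions) > 0L) {
        keyf_idx <- which(mentions$label == "KEYF")
        if (length(keyf_idx) > 0L) {
          frag_list <- parse_spans(mentions$spans[keyf_idx])
          surfaces <- map_chr(seq_along(keyf_idx), function(j) {
            mention_surface(text, frag_list[[j]])
          })
          mentions$hpo_id[keyf_idx] <- map_chr(surfaces, function(s) {
            key <- s
            if (is.null(norm_cache[[key]])) {
              norm_cache[[key]] <- normalize_mention(s, index, reranker, k)
            }
            norm_cache[[key]]
          })
        }
      }
      if (nrow(mentions) == 0L) {
        tibble(observation_id = oid, text = text, label = NA_character_,
               hpo_id = NA_character_, spans = NA_character_)
      } else {
        mentions
      }
    }, error = function(e) {
      abort(sprintf("Pipeline failed on observation '%s': %s",
                    oid, conditionMessage(e)), parent = e)
    })
    result
  })
  out <- validate_corpus(bind_rows(rows))
  structure(out,
            n_skipped = n_skipped,
            n_ungrounded = sum(map_int(ungrounded, nrow)),
            ungrounded = bind_rows(ungrounded))
}
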