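#' Linearized sequence-to-sequence targets
#'
#' For generative NER the annotations of one observation are serialized into
#' a single target string: each mention surface is prefixed with its label
#' and the segments are joined with `"; "`, e.g.
#' `"KEYF: Excess nuchal skin; NORMF: NECK: no webbing; NORMF: NECK: no cysts"`.
#' No task prefix is added. Discontinuous mentions need no special markup:
#' their surface is simply the fragment substrings joined by spaces.
#'
#' Segments are ordered deterministically: KEYF segments before NORMF
#' segments; within a label by the mention's fragment-start vector
#' (lexicographically, a shorter prefix first); remaining ties by surface.
#'
#' @param corpus A corpus tibble (see [phen_corpus()]).
#' @return A tibble with one row per observation: `observation_id`, `text`,
#'   `target`. Mention-less observations get an empty target string.
#' @examples
#' corpus <- phen_corpus("OBS1", "EYES: Sparse eyebrow hair.",
#'                       label = "KEYF", spans = "6-20")
#' encode_targets(corpus)$target
#' @export
encode_targets <- function(corpus) {
  corpus <- validate_corpus(corpus)
  obs <- corpus_observations(corpus)
  mentions <- corpus_mentions(corpus)
  if (nrow(mentions) > 0L) {
    frag_list <- parse_spans(mentions$spans)
    mentions$surface <- map_chr(seq_len(nrow(mentions)), function(i) {
      mention_surface(mentions$text[[i]], frag_list[[i]])
    })
    # zero-padded start vector -> plain string sort == lexicographic numeric
    mentions$..startkey <- map_chr(frag_list, function(f) {
      paste(sprintf("%09d", f[, "start"]), collapse = ",")
    })
    targets <- mentions |>
      mutate(..labord = ifelse(.data$label == "KEYF", 0L, 1L)) |>
      group_by(.data$observation_id) |>
      arrange(.data$..labord, .data$..startkey, .data$surface, .by_group = TRUE) |>
      summarise(
        target = paste(sprintf("%s: %s", .data$label, .data$surface),
                       collapse = "; "),
        .groups = "drop"
      )
  } else {
    targets <- tibble(observation_id = character(), target = character())
  }
  obs |>
    left_join(targets, by = "observation_id") |>
    mutate(target = ifelse(is.na(.data$target), "", .data$target))
}

#' Decode a generated target string
#'
#' Inverse of [encode_targets()] for well-formed targets, but defensive:
#' model output is untrusted. The string is split on `";"`; each segment must
#' start with a `KEYF:` or `NORMF:` label prefix (only the first colon is
#' consumed, so surfaces containing further colons, such as
#' `"NECK: no webbing"`, survive intact). Segments without a recognized label
#' are skipped, never fatal; duplicates of the same (label, surface) pair are
#' collapsed keeping the first.
#'
#' @param target A single target string.
#' @return A tibble with columns `label` and `surface`. The character vector
#'   of skipped segments is attached as attribute `"skipped"` (and its length
#'   as `"n_skipped"`).
#' @examples
#' decode_target("KEYF: Sparse eyebrow; NORMF: Normal lids")
#' @export
decode_target <- function(target) {
  stopifnot(is.character(target), length(target) == 1L)
  empty <- tibble(label = character(), surface = character())
  if (is.na(target) || !nzchar(trimws(target))) {
    return(structure(empty, skipped = character(), n_skipped = 0L))
  }
  segments <- trimws(strsplit(target, ";", fixed = TRUE)[[1]])
  segments <- segments[nzchar(segments)]
  m <- regmatches(segments, regexec("^(KEYF|NORMF)\\s*:\\s*(.*)$", segments))
  parsed <- map(m, function(g) {
    if (length(g) == 3L && nzchar(trimws(g[[3]]))) {
      tibble(label = g[[2]], surface = trimws(g[[3]]))
    } else {
      NULL
    }
  })
  skipped <- segments[map_lgl(parsed, is.null)]
  out <- bind_rows(parsed)
  if (nrow(out) == 0L) out <- empty
  out <- distinct(out, .data$label, .data$surface)
  structure(out, skipped = skipped, n_skipped = length(skipped))
}
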