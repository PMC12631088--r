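#' Generation backends
#'
#' A *backend* is any function mapping an observation text to a target
#' string parseable by [decode_target()]. Fine-tuned sequence-to-sequence
#' transformers satisfy this contract in production; [stub_backend()] builds
#' a deterministic dictionary scanner satisfying the same contract for
#' desk-scale pipelines and tests.
#'
#' The stub scans the text left-to-right for the longest case-insensitive
#' dictionary-surface match at each position (matches must fall on word
#' boundaries and never overlap) and emits each hit as a `KEYF` segment. If
#' the word token immediately preceding a hit is a negation cue (default
#' `"no"`, `"normal"`, `"intact"`) the segment label flips to `NORMF`.
#'
#' @param dictionary An ontology dictionary tibble (see [load_dictionary()]).
#' @param negation_cues Character vector of lowercase cue words.
#' @return A function of class `"phen_backend"`: `function(text)` returning
#'   a target string.
#' @examples
#' dict <- tibble::tibble(hpo_id = "HP:0000001", surface = "hooding",
#'                        is_preferred = TRUE)
#' backend <- stub_backend(dict)
#' backend("EYES: normal brows, mild hooding.")
#' @export
stub_backend <- function(dictionary, negation_cues = c("no", "normal", "intact")) {
  dictionary <- validate_dictionary(dictionary)
  surfaces <- unique(dictionary$surface)
  patterns <- sprintf("\\b%s\\b", escape_regex(surfaces))
  cues <- tolower(negation_cues)

  backend <- function(text) {
    stopifnot(is.character(text), length(text) == 1L)
    if (is.na(text) || !nzchar(text)) return("")
    hits <- purrr::map_dfr(seq_along(patterns), function(i) {
      m <- gregexpr(patterns[[i]], text, ignore.case = TRUE, perl = TRUE)[[1]]
      if (m[[1]] == -1L) return(NULL)
      tibble(start = as.integer(m),
             len = attr(m, "match.length"))
    })
    if (nrow(hits) == 0L) return("")
    # longest match wins at each position; then left-to-right, non-overlapping
    hits <- arrange(hits, .data$start, dplyr::desc(.data$len))
    taken <- integer(0)
    segs <- character(0)
    last_end <- 0L
    for (i in seq_len(nrow(hits))) {
      s <- hits$start[[i]]
      e <- s + hits$len[[i]] - 1L
      if (s <= last_end) next
      surface <- substr(text, s, e)
      prev <- preceding_token(text, s)
      label <- if (!is.na(prev) && tolower(prev) %in% cues) "NORMF" else "KEYF"
      segs <- c(segs, sprintf("%s: %s", label, surface))
      last_end <- e
    }
    paste(segs, collapse = "; ")
  }
  structure(backend, class = c("phen_backend", "function"))
}

# Last word token (punctuation stripped) before 1-based position `pos`.
preceding_token <- function(text, pos) {
  if (pos <= 1L) return(NA_character_)
  before <- substr(text, 1L, pos - 1L)
  toks <- regmatches(before, gregexpr("\\S+", before))[[1]]
  if (length(toks) == 0L) return(NA_character_)
  core <- strip_punct(toks[[length(toks)]])
  if (!nzchar(core)) NA_character_ else core
}

escape_regex <- function(x) {
  gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
}
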