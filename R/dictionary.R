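#' Ontology dictionaries
#'
#' A dictionary is a tibble mapping surface terms to HPO identifiers, with
#' columns `hpo_id`, `surface` and `is_preferred` (exactly one preferred
#' term per identifier; the rest are synonyms). The conventional input
#' file is two tab-separated columns: term, identifier; the first surface
#' seen for an identifier becomes its preferred term.
#'
#' @param file Path or connection to a two-column tab-separated file.
#' @return A dictionary tibble.
#' @export
load_dictionary <- function(file) {
  raw <- readr::read_tsv(
    file,
    col_names = c("surface", "hpo_id"),
    col_types = readr::cols(.default = readr::col_character()),
    na = character(),
    quote = "",
    progress = FALSE
  )
  if (nrow(raw) == 0L) {
    abort("Dictionary file is empty; an empty dictionary is unusable.")
  }
  bad <- !nzchar(trimws(raw$surface))
  if (any(bad)) {
    abort(sprintf("Dictionary row %d has an empty term.", which(bad)[[1L]]))
  }
  raw <- mutate(raw, surface = trimws(.data$surface), hpo_id = trimws(.data$hpo_id))
  odd <- !grepl("^HP:[0-9]{7}$", raw$hpo_id)
  if (any(odd)) {
    warn(sprintf("%d dictionary identifier(s) do not match 'HP:' + 7 digits (e.g. '%s'); kept verbatim.",
                 sum(odd), raw$hpo_id[odd][[1L]]))
  }
  dict <- distinct(raw, .data$surface, .data$hpo_id) |>
    group_by(.data$hpo_id) |>
    mutate(is_preferred = row_number() == 1L) |>
    ungroup() |>
    select("hpo_id", "surface", "is_preferred")
  validate_dictionary(dict)
}

validate_dictionary <- function(dict) {
  required <- c("hpo_id", "surface", "is_preferred")
  missing <- setdiff(required, names(dict))
  if (length(missing) > 0L) {
    abort(paste0("Dictionary is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(dict) == 0L) abort("Dictionary has no entries.")
  if (any(!nzchar(dict$surface) | is.na(dict$surface))) {
    abort("Dictionary surfaces must be non-empty.")
  }
  if (anyDuplicated(dict[, c("surface", "hpo_id")]) > 0L) {
    abort("Dictionary contains duplicate (surface, hpo_id) pairs.")
  }
  n_pref <- dict |>
    group_by(.data$hpo_id) |>
    summarise(n = sum(.data$is_preferred), .groups = "drop")
  if (any(n_pref$n != 1L)) {
    abort(sprintf("Identifier %s must have exactly one preferred surface.",
                  n_pref$hpo_id[n_pref$n != 1L][[1L]]))
  }
  as_tibble(dict)
}

#' Augment a dictionary with synonyms from an annotated corpus
#'
#' Every KEYF mention surface observed in `corpus` is added as a
#' non-preferred synonym of its annotated identifier, unless that surface
#' already maps to the identifier. NORMF mentions are ignored (they have no
#' HPO representation); KEYF mentions lacking an identifier are skipped and
#' counted in the `"n_skipped"` attribute. The input dictionary is never
#' modified: the result is a strict superset of its rows.
#'
#' @param dict A dictionary tibble.
#' @param corpus A corpus tibble whose KEYF mentions carry `hpo_id`.
#' @return The augmented dictionary tibble.
#' @export
augment_dictionary <- function(dict, corpus) {
  dict <- validate_dictionary(dict)
  corpus <- validate_corpus(corpus)
  keyf <- filter(corpus_mentions(corpus), .data$label == "KEYF")
  n_skipped <- sum(is.na(keyf$hpo_id))
  keyf <- filter(keyf, !is.na(.data$hpo_id))
  if (nrow(keyf) > 0L) {
    frag_list <- parse_spans(keyf$spans)
    new <- tibble(
      hpo_id = keyf$hpo_id,
      surface = map_chr(seq_len(nrow(keyf)),
                        ~ mention_surface(keyf$text[[.x]], frag_list[[.x]])),
      is_preferred = FALSE
    ) |>
      distinct(.data$hpo_id, .data$surface, .keep_all = TRUE) |>
      dplyr::anti_join(dict, by = c("hpo_id", "surface"))
    # an identifier unseen in the dictionary gets its first observed surface
    # as the preferred term
    novel <- !new$hpo_id %in% dict$hpo_id
    new$is_preferred <- novel & !duplicated(new$hpo_id)
    dict <- bind_rows(dict, new)
  }
  structure(validate_dictionary(dict), n_skipped = n_skipped)
}

#' @rdname load_dictionary
#' @param dict A dictionary tibble.
#' @return `write_dictionary()`: `dict`, invisibly.
#' @export
write_dictionary <- function(dict, file) {
  dict <- validate_dictionary(dict)
  lines <- sprintf("%s\t%s", dict$surface, dict$hpo_id)
  if (is.character(file)) {
    con <- file(file, open = "wb")
    on.exit(close(con))
  } else {
    con <- file
  }
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(dict)
}
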