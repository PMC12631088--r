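#' Annotated corpora as tibbles
#'
#' A corpus is a tibble with one row per mention and columns:
#' \describe{
#'   \item{observation_id}{opaque identifier of the clinical observation}
#'   \item{text}{raw observation text (repeated across that observation's mentions)}
#'   \item{label}{`"KEYF"` (key finding, an abnormality that maps to HPO) or
#'     `"NORMF"` (normal finding, excluded from normalization)}
#'   \item{hpo_id}{HPO identifier `"HP:"` + 7 digits, or `NA`}
#'   \item{spans}{serialized offset fragments, see [parse_spans()]}
#' }
#' An observation with no mentions is represented by a single row whose
#' `label`, `hpo_id` and `spans` are all `NA` (its text is retained).
#'
#' @param observation_id,text,label,hpo_id,spans Column vectors, recycled to
#'   a common length.
#' @return A validated corpus tibble.
#' @export
phen_corpus <- function(observation_id, text, label = NA_character_,
                        hpo_id = NA_character_, spans = NA_character_) {
  out <- tibble(
    observation_id = as.character(observation_id),
    text = as.character(text),
    label = as.character(label),
    hpo_id = as.character(hpo_id),
    spans = as.character(spans)
  )
  validate_corpus(out)
}

validate_corpus <- function(corpus, check_spans = TRUE) {
  required <- c("observation_id", "text", "label", "hpo_id", "spans")
  missing <- setdiff(required, names(corpus))
  if (length(missing) > 0L) {
    abort(paste0("Corpus is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(is.na(corpus$observation_id) | !nzchar(corpus$observation_id))) {
    abort("Every corpus row needs a non-empty observation_id.")
  }
  if (any(is.na(corpus$text) | !nzchar(corpus$text))) {
    abort("Every corpus row needs non-empty observation text.")
  }
  bad_label <- !is.na(corpus$label) & !corpus$label %in% c("KEYF", "NORMF")
  if (any(bad_label)) {
    abort(sprintf("Unknown mention label '%s'.", corpus$label[bad_label][1L]))
  }
  if (check_spans) {
    has_mention <- !is.na(corpus$label)
    purrr::walk(which(has_mention), function(i) {
      frags <- parse_span_field(corpus$spans[[i]])
      validate_fragments(frags, text = corpus$text[[i]])
    })
  }
  as_tibble(corpus)
}

corpus_header <- c("ObservationID", "Text", "HPO", "Polarity", "Spans")

#' Read a tab-separated annotation file
#'
#' The file layout has five columns: observation ID, observation text, HPO
#' identifier, polarity, and offset spans. Polarity `"X"` marks a normal
#' finding (NORMF); `"NA"` or `"N/A"` marks a key finding (KEYF).
#' Discontinuous mentions carry comma-separated offset ranges in the spans
#' column. A header line is detected automatically (its spans cell does not
#' parse as offsets).
#'
#' @param file Path or connection to a UTF-8, tab-separated file.
#' @param strict If `TRUE` (default) a row that fails validation is an error
#'   identifying the row; if `FALSE` such rows are skipped with a warning.
#'   Source corpora are known to contain occasional offset inconsistencies,
#'   which the lenient mode tolerates.
#' @return A corpus tibble (see [phen_corpus()]), rows grouped by observation
#'   in first-seen order.
#' @export
read_annotations <- function(file, strict = TRUE) {
  raw <- readr::read_tsv(
    file,
    col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(),
    quote = "",
    progress = FALSE
  )
  if (nrow(raw) == 0L) {
    return(phen_corpus(character(), character())[0L, ])
  }
  if (ncol(raw) != 5L) {
    abort(sprintf("Annotation file must have 5 tab-separated columns, found %d.",
                  ncol(raw)), class = "phenospan_format_error")
  }
  names(raw) <- c("observation_id", "text", "hpo_id", "polarity", "spans")
  # Header row: the spans cell of real data always parses as offsets.
  if (!grepl("^\\s*[0-9]+-[0-9]+", raw$spans[[1L]])) {
    raw <- raw[-1L, , drop = FALSE]
  }
  if (nrow(raw) == 0L) {
    return(phen_corpus(character(), character())[0L, ])
  }

  rows <- purrr::imap(seq_len(nrow(raw)), function(i, ...) {
    row <- raw[i, ]
    tryCatch({
      pol <- trimws(row$polarity)
      label <- if (identical(pol, "X")) "NORMF"
        else if (pol %in% c("NA", "N/A")) "KEYF"
        else abort(sprintf("Unknown polarity value '%s'.", pol),
                   class = "phenospan_format_error")
      hpo <- trimws(row$hpo_id)
      if (!nzchar(hpo)) hpo <- NA_character_
      if (!is.na(hpo) && !grepl("^HP:[0-9]{7}$", hpo)) {
        warn(sprintf("Row %d: HPO identifier '%s' does not match 'HP:' + 7 digits; kept verbatim.",
                     i, hpo))
      }
      frags <- parse_span_field(row$spans)
      validate_fragments(frags, text = row$text)
      tibble(observation_id = row$observation_id, text = row$text,
             label = label, hpo_id = hpo, spans = format_span_field(frags))
    }, phenospan_format_error = function(e) {
      msg <- sprintf("Row %d: %s", i, conditionMessage(e))
      if (strict) abort(msg, class = "phenospan_format_error") else warn(msg)
      NULL
    })
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    return(phen_corpus(character(), character())[0L, ])
  }
  # Group rows of the same observation together, first-seen order.
  out$..ord <- match(out$observation_id, unique(out$observation_id))
  out <- arrange(out, .data$..ord)
  out$..ord <- NULL
  validate_corpus(out)
}

#' Write a corpus in the five-column annotation format
#'
#' One row per mention (observation-only rows are omitted), tab-separated,
#' UTF-8, LF line endings, with a header line. Polarity is written as `"X"`
#' for NORMF and `"NA"` for KEYF; a missing `hpo_id` becomes an empty cell.
#' `read_annotations()` inverts this exactly.
#'
#' @param corpus A corpus tibble.
#' @param file Output path or connection.
#' @return `corpus`, invisibly.
#' @export
write_predictions <- function(corpus, file) {
  corpus <- validate_corpus(corpus)
  rows <- filter(corpus, !is.na(.data$label))
  lines <- c(
    paste(corpus_header, collapse = "\t"),
    sprintf("%s\t%s\t%s\t%s\t%s",
            rows$observation_id,
            rows$text,
            ifelse(is.na(rows$hpo_id), "", rows$hpo_id),
            ifelse(rows$label == "NORMF", "X", "NA"),
            rows$spans)
  )
  if (is.character(file)) {
    con <- file(file, open = "wb")
    on.exit(close(con))
  } else {
    con <- file
  }
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(corpus)
}

# Observations table (one row per distinct observation) from a corpus.
#' Distinct observations of a corpus
#'
#' @param corpus A corpus tibble.
#' @return A tibble with columns `observation_id` and `text`, one row per
#'   observation in first-seen order.
#' @export
corpus_observations <- function(corpus) {
  distinct(corpus, .data$observation_id, .data$text)
}

# Mention rows only (drops observation-only placeholder rows).
corpus_mentions <- function(corpus) {
  filter(corpus, !is.na(.data$label))
}
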