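#' Character-offset span model
#'
#' Mentions are anchored to their observation text by one to three character
#' offset *fragments*. Offsets are 0-based and half-open: a fragment
#' `start-end` covers characters `start, ..., end - 1`. A continuous mention
#' has a single fragment; a discontinuous (disjoint) mention has two or three
#' fragments, sorted by start, pairwise non-overlapping and separated by at
#' least one character.
#'
#' In tibbles a fragment list is carried as its serialized form, e.g.
#' `"17-27,37-42"`; [parse_spans()] and [format_spans()] convert between that
#' string and an integer matrix with columns `start` and `end`.
#'
#' @param spans Character vector of span fields, each a comma-separated list
#'   of `start-end` integer ranges (spaces around commas tolerated).
#' @return `parse_spans()`: a list of integer matrices (one per input string)
#'   with columns `start`, `end`, rows sorted by `start`.
#' @examples
#' parse_spans("17-27,37-42")
#' format_spans(list(cbind(start = c(17L, 37L), end = c(27L, 42L))))
#' @export
parse_spans <- function(spans) {
  map(as.character(spans), parse_span_field)
}

parse_span_field <- function(field) {
  if (is.na(field) || !nzchar(trimws(field))) {
    abort("Empty span field.", class = "phenospan_format_error")
  }
  tokens <- trimws(strsplit(field, ",", fixed = TRUE)[[1]])
  if (length(tokens) > 3L) {
    abort(
      sprintf("Span field '%s' has %d ranges; at most 3 are allowed.",
              field, length(tokens)),
      class = "phenospan_format_error"
    )
  }
  bad <- tokens[!grepl("^[0-9]+-[0-9]+$", tokens)]
  if (length(bad) > 0L) {
    abort(
      sprintf("Malformed span range '%s' in field '%s'.", bad[[1]], field),
      class = "phenospan_format_error"
    )
  }
  parts <- strsplit(tokens, "-", fixed = TRUE)
  frags <- cbind(
    start = as.integer(map_chr(parts, 1L)),
    end   = as.integer(map_chr(parts, 2L))
  )
  degen <- frags[, "start"] >= frags[, "end"]
  if (any(degen)) {
    abort(
      sprintf("Span range '%s' is empty or reversed (start >= end).",
              tokens[which(degen)[1L]]),
      class = "phenospan_format_error"
    )
  }
  frags <- frags[order(frags[, "start"]), , drop = FALSE]
  validate_fragments(frags, field = field)
  frags
}

# Shared structural validation for a fragment matrix. `text` adds the
# bounds check against the owning observation.
validate_fragments <- function(frags, text = NULL, field = NULL) {
  label <- field %||% format_span_field(frags)
  if (nrow(frags) < 1L || nrow(frags) > 3L) {
    abort(sprintf("Mention '%s' must have 1-3 fragments.", label),
          class = "phenospan_format_error")
  }
  if (any(frags[, "start"] >= frags[, "end"]) || any(frags < 0L)) {
    abort(sprintf("Invalid fragment bounds in '%s'.", label),
          class = "phenospan_format_error")
  }
  if (nrow(frags) > 1L) {
    if (is.unsorted(frags[, "start"], strictly = TRUE)) {
      abort(sprintf("Fragments in '%s' must be sorted by start.", label),
            class = "phenospan_format_error")
    }
    gap <- frags[-1L, "start"] - frags[-nrow(frags), "end"]
    if (any(gap < 1L)) {
      abort(
        sprintf("Fragments in '%s' overlap or are adjacent; they must be separated by at least one character.",
                label),
        class = "phenospan_format_error"
      )
    }
  }
  if (!is.null(text)) {
    if (any(frags[, "end"] > nchar(text))) {
      abort(
        sprintf("Fragment in '%s' extends past the end of the observation text (%d characters).",
                label, nchar(text)),
        class = "phenospan_format_error"
      )
    }
  }
  invisible(frags)
}

#' @rdname parse_spans
#' @param fragments A list of fragment matrices as returned by
#'   [parse_spans()] (a bare matrix is also accepted).
#' @return `format_spans()`: a character vector of serialized span fields.
#' @export
format_spans <- function(fragments) {
  if (is.matrix(fragments)) fragments <- list(fragments)
  map_chr(fragments, function(frags) {
    validate_fragments(as_fragment_matrix(frags))
    format_span_field(frags)
  })
}

format_span_field <- function(frags) {
  paste(sprintf("%d-%d", frags[, "start"], frags[, "end"]), collapse = ",")
}

as_fragment_matrix <- function(frags) {
  m <- matrix(as.integer(frags), ncol = 2L)
  colnames(m) <- c("start", "end")
  m
}

#' Extract the surface text of a mention
#'
#' Takes the substring of `text` under each fragment and joins the pieces
#' with a single space, regardless of how much text the gaps skip. For the
#' observation `"HANDS FEET: Both thumbs are long and broad"` the fragments
#' `17-27,37-42` yield `"thumbs are broad"`.
#'
#' @param text Observation text (scalar character).
#' @param fragments A fragment matrix, a span string such as `"17-27,37-42"`,
#'   or a list of either (vectorized over the list).
#' @return Character vector of mention surfaces.
#' @examples
#' mention_surface("HANDS FEET: Both thumbs are long and broad", "17-27,37-42")
#' @export
mention_surface <- function(text, fragments) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (is.matrix(fragments) || is.character(fragments)) {
    fragments <- if (is.matrix(fragments)) list(fragments) else parse_spans(fragments)
  }
  map_chr(fragments, function(frags) {
    frags <- as_fragment_matrix(frags)
    validate_fragments(frags, text = text)
    # 0-based half-open -> substr's 1-based inclusive
    paste(substr(rep(text, nrow(frags)), frags[, "start"] + 1L, frags[, "end"]),
          collapse = " ")
  })
}
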