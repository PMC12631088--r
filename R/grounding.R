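#' Ground a mention surface to character offsets
#'
#' Recovers offset fragments for mention text produced by a generative model.
#' If the surface occurs contiguously in the text, the leftmost contiguous
#' occurrence is returned as a single fragment. Otherwise the text is
#' tokenized on whitespace (offsets retained) and the surface's tokens are
#' partitioned into at most `max_fragments` runs, each run matching a
#' contiguous run of text tokens, runs strictly left-to-right with at least
#' one text token between them. Among feasible placements the one minimizing
#' (fragment count, then fragment starts lexicographically, then fragment
#' ends lexicographically) is returned, so contiguous readings are always
#' preferred and the result is deterministic.
#'
#' Matching is case-sensitive with a full case-insensitive fallback pass.
#' When exact token equality fails, tokens are compared with leading/trailing
#' punctuation stripped, so the surface token `"hooding"` matches the text
#' token `"hooding."` (the returned fragment excludes the punctuation).
#'
#' @param text Observation text.
#' @param surface Non-empty mention surface string.
#' @param max_fragments Maximum number of fragments (default 3, matching the
#'   2-3 constituent parts observed in dysmorphology corpora).
#' @return An integer fragment matrix (columns `start`, `end`), or `NULL` if
#'   no placement within `max_fragments` exists (an *ungrounded* surface --
#'   a value, not an error; callers decide whether to drop or report).
#' @examples
#' ground_surface("HANDS FEET: Both thumbs are long and broad",
#'                "thumbs are broad")
#' @export
ground_surface <- function(text, surface, max_fragments = 3L) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!is.character(surface) || length(surface) != 1L || is.na(surface) ||
      !nzchar(trimws(surface))) {
    abort("`surface` must be a non-empty string.")
  }
  surface <- trimws(surface)
  for (fold in c(FALSE, TRUE)) {
    hit <- ground_pass(text, surface, max_fragments, fold = fold)
    if (!is.null(hit)) return(hit)
  }
  NULL
}

ground_pass <- function(text, surface, max_fragments, fold) {
  t <- if (fold) tolower(text) else text
  s <- if (fold) tolower(surface) else surface
  # Phase 1: leftmost contiguous occurrence as one fragment.
  pos <- regexpr(s, t, fixed = TRUE)
  if (pos > 0L) {
    return(as_fragment_matrix(cbind(pos - 1L, pos - 1L + nchar(s))))
  }
  # Phase 2: token-run placement search.
  toks <- tokenize_offsets(text)
  if (nrow(toks) == 0L) return(NULL)
  stoks <- strsplit(s, "\\s+")[[1]]
  stoks <- stoks[nzchar(stoks)]
  m <- length(stoks)
  if (m == 0L) return(NULL)
  ttoks <- if (fold) tolower(toks$token) else toks$token
  # ranges[[i]][[j]]: matched char range of surface token i on text token j
  ranges <- lapply(stoks, function(st) {
    lapply(seq_along(ttoks), function(j) {
      match_token_range(st, ttoks[[j]], toks$start[[j]])
    })
  })
  matches <- vapply(ranges, function(r) !vapply(r, is.null, TRUE), logical(length(ttoks)))
  matches <- matrix(matches, nrow = length(ttoks))  # text tokens x surface tokens
  if (any(colSums(matches) == 0L)) return(NULL)

  n <- length(ttoks)
  best <- NULL
  for (f in seq_len(min(max_fragments, m))) {
    placements <- list()
    for (split in compositions(m, f)) {
      # run r covers surface tokens run_from[r] .. run_to[r]
      run_to <- cumsum(split)
      run_from <- run_to - split + 1L
      # feasible text starts for each run
      run_starts <- lapply(seq_len(f), function(r) {
        len <- split[[r]]
        ok <- integer(0)
        for (j in seq_len(n - len + 1L)) {
          if (all(matches[cbind(j:(j + len - 1L), run_from[[r]]:run_to[[r]])])) {
            ok <- c(ok, j)
          }
        }
        ok
      })
      collect <- function(r, min_j, acc) {
        if (r > f) {
          placements[[length(placements) + 1L]] <<- acc
          return(invisible(NULL))
        }
        for (j in run_starts[[r]]) {
          if (j >= min_j) {
            collect(r + 1L, j + split[[r]] + 1L, c(acc, j))
          }
        }
      }
      collect(1L, 1L, integer(0))
      # attach split length so char offsets can be reconstructed
      if (length(placements) > 0L) {
        placements <- lapply(placements, function(p) {
          if (is.null(attr(p, "split"))) attr(p, "split") <- split
          p
        })
      }
    }
    if (length(placements) > 0L) {
      keys <- lapply(placements, function(p) {
        placement_fragments(p, attr(p, "split"), ranges, toks, cumsum(attr(p, "split")))
      })
      ord <- order_placements(keys)
      return(keys[[ord]])
    }
  }
  NULL
}

# fragment matrix for a placement: run r = text tokens p[r] .. p[r]+len-1,
# start char from the matched range of its first token, end char from the
# matched range of its last token.
placement_fragments <- function(p, split, ranges, toks, run_to) {
  run_from <- run_to - split + 1L
  frags <- t(vapply(seq_along(p), function(r) {
    j1 <- p[[r]]
    j2 <- p[[r]] + split[[r]] - 1L
    c(ranges[[run_from[[r]]]][[j1]][[1L]], ranges[[run_to[[r]]]][[j2]][[2L]])
  }, integer(2)))
  as_fragment_matrix(frags)
}

order_placements <- function(frag_list) {
  keys <- vapply(frag_list, function(f) {
    paste(sprintf("%09d", c(f[, "start"], f[, "end"])), collapse = ",")
  }, character(1))
  order(keys)[[1L]]
}

# contiguous compositions of m into f positive parts
compositions <- function(m, f) {
  if (f == 1L) return(list(m))
  out <- list()
  recurse <- function(remaining, parts_left, acc) {
    if (parts_left == 1L) {
      out[[length(out) + 1L]] <<- c(acc, remaining)
      return(invisible(NULL))
    }
    for (take in seq_len(remaining - parts_left + 1L)) {
      recurse(remaining - take, parts_left - 1L, c(acc, take))
    }
  }
  recurse(m, f, integer(0))
  out
}

strip_punct <- function(x) {
  gsub("^[[:punct:]]+|[[:punct:]]+$", "", x)
}

# Matched character range (0-based, half-open, absolute) of surface token
# `st` against text token `tt` starting at absolute offset `tstart`;
# NULL if no match.
match_token_range <- function(st, tt, tstart) {
  if (identical(st, tt)) {
    return(c(tstart, tstart + nchar(tt)))
  }
  lead <- nchar(tt) - nchar(sub("^[[:punct:]]+", "", tt))
  core <- strip_punct(tt)
  if (!nzchar(core)) return(NULL)
  if (identical(st, core) || identical(strip_punct(st), core)) {
    return(c(tstart + lead, tstart + lead + nchar(core)))
  }
  NULL
}

# Whitespace tokenization with 0-based half-open character offsets.
tokenize_offsets <- function(text) {
  m <- gregexpr("\\S+", text)[[1]]
  if (m[[1]] == -1L) {
    return(tibble(token = character(), start = integer(), end = integer()))
  }
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  tibble(
    token = regmatches(text, gregexpr("\\S+", text))[[1]],
    start = starts,
    end = starts + lens
  )
}

#' Ground all decoded mentions of one observation
#'
#' Applies [ground_surface()] to each decoded mention independently.
#' Grounded mentions keep their label and carry no HPO id yet; duplicates by
#' (label, fragments) are collapsed. Surfaces with no feasible placement are
#' returned separately so callers can log them -- they are dropped from span
#' output, which costs precision and must stay visible.
#'
#' @param text Observation text.
#' @param decoded A tibble with columns `label`, `surface`
#'   (as from [decode_target()]).
#' @param max_fragments Passed to [ground_surface()].
#' @param observation_id Optional id attached to the output rows.
#' @return A list with elements `mentions` (corpus-shaped tibble) and
#'   `ungrounded` (tibble of `label`, `surface`).
#' @export
ground_all <- function(text, decoded, max_fragments = 3L,
                       observation_id = NA_character_) {
  stopifnot(is.data.frame(decoded))
  empty_m <- tibble(observation_id = character(), text = character(),
                    label = character(), hpo_id = character(), spans = character())
  empty_u <- tibble(label = character(), surface = character())
  if (nrow(decoded) == 0L) {
    return(list(mentions = empty_m, ungrounded = empty_u))
  }
  frags <- map(decoded$surface, ~ ground_surface(text, .x, max_fragments))
  ok <- !map_lgl(frags, is.null)
  mentions <- empty_m
  if (any(ok)) {
    mentions <- tibble(
      observation_id = observation_id,
      text = text,
      label = decoded$label[ok],
      hpo_id = NA_character_,
      spans = map_chr(frags[ok], format_span_field)
    ) |>
      distinct(.data$label, .data$spans, .keep_all = TRUE)
  }
  ungrounded <- tibble(label = decoded$label[!ok], surface = decoded$surface[!ok])
  list(mentions = mentions, ungrounded = ungrounded)
}
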