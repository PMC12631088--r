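# Independent oracles: deliberately naive re-implementations used only to
# check the package's optimized code paths on small inputs.

# Exhaustive enumeration of all <= max_fragments placements of `surface`
# inside `text` at whitespace-token granularity, under the objective
# (fragment count, starts lexicographic, ends lexicographic). Fixture texts
# are single-space separated and punctuation-free, so token equality is
# plain string equality and fragments cover whole tokens.
oracle_ground <- function(text, surface, max_fragments = 3L) {
  ttoks <- strsplit(text, " ", fixed = TRUE)[[1]]
  stoks <- strsplit(surface, " ", fixed = TRUE)[[1]]
  tstart <- integer(length(ttoks))
  pos <- 0L
  for (i in seq_along(ttoks)) {
    tstart[[i]] <- pos
    pos <- pos + nchar(ttoks[[i]]) + 1L
  }
  tend <- tstart + nchar(ttoks)

  m <- length(stoks)
  n <- length(ttoks)
  best <- NULL
  best_key <- NULL
  # enumerate every assignment of surface tokens to strictly increasing text
  # positions, then group into runs and keep assignments whose runs are
  # contiguous, separated by >= 1 token, and within the fragment budget
  assignments <- list(integer(0))
  for (s in seq_len(m)) {
    nxt <- list()
    for (a in assignments) {
      from <- if (length(a) == 0L) 1L else a[[length(a)]] + 1L
      for (j in if (from <= n) from:n else integer(0)) {
        if (identical(ttoks[[j]], stoks[[s]])) nxt[[length(nxt) + 1L]] <- c(a, j)
      }
    }
    assignments <- nxt
    if (length(assignments) == 0L) return(NULL)
  }
  for (a in assignments) {
    runs <- split(a, cumsum(c(1L, diff(a) != 1L)))
    # runs must be separated by at least one intervening text token
    gaps_ok <- TRUE
    if (length(runs) > 1L) {
      for (r in seq_len(length(runs) - 1L)) {
        if (runs[[r + 1L]][[1L]] - runs[[r]][[length(runs[[r]])]] < 2L) {
          gaps_ok <- FALSE
        }
      }
    }
    if (!gaps_ok || length(runs) > max_fragments) next
    frags <- t(vapply(runs, function(run) {
      c(tstart[[run[[1L]]]], tend[[run[[length(run)]]]])
    }, integer(2)))
    key <- c(nrow(frags), frags[, 1L], frags[, 2L])
    if (is.null(best) ||
        nrow(frags) < nrow(best) ||
        (nrow(frags) == nrow(best) &&
         paste(sprintf("%06d", key), collapse = "") <
         paste(sprintf("%06d", c(nrow(best), best[, 1L], best[, 2L])), collapse = ""))) {
      best <- frags
      best_key <- key
    }
  }
  if (is.null(best)) return(NULL)
  dimnames(best) <- list(NULL, c("start", "end"))
  best
}

# Naive one-to-one matcher over two mention lists of a single observation.
# Mentions: list(frags = matrix, id = chr). Character/token overlap computed
# with explicit position sets.
oracle_chars <- function(frags) {
  out <- integer(0)
  for (i in seq_len(nrow(frags))) {
    out <- c(out, seq.int(frags[i, 1L], frags[i, 2L] - 1L))
  }
  out
}

oracle_tokens <- function(frags, text) {
  hits <- character(0)
  m <- gregexpr("[^ ]+", text)[[1]]
  for (i in seq_along(m)) {
    tok <- substr(text, m[[i]], m[[i]] + attr(m, "match.length")[[i]] - 1L)
    core <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", tok)
    if (!nzchar(core)) next
    lead <- regexpr(core, tok, fixed = TRUE) - 1L
    s <- m[[i]] - 1L + lead
    e <- s + nchar(core)
    for (f in seq_len(nrow(frags))) {
      if (frags[f, 1L] <= s && e <= frags[f, 2L]) {
        hits <- c(hits, sprintf("%d:%d", s, e))
        break
      }
    }
  }
  hits
}

oracle_match <- function(text, gold, pred, mode, require_id = FALSE) {
  compat <- matrix(FALSE, length(gold), length(pred))
  shared <- matrix(0L, length(gold), length(pred))
  for (i in seq_along(gold)) {
    for (j in seq_along(pred)) {
      gf <- gold[[i]]$frags
      pf <- pred[[j]]$frags
      ok <- if (mode == "exact") {
        nrow(gf) == nrow(pf) && all(gf == pf)
      } else {
        length(intersect(oracle_tokens(gf, text), oracle_tokens(pf, text))) > 0L
      }
      if (ok && require_id) {
        ok <- !is.na(gold[[i]]$id) && !is.na(pred[[j]]$id) &&
          gold[[i]]$id == pred[[j]]$id
      }
      compat[i, j] <- ok
      shared[i, j] <- length(intersect(oracle_chars(gf), oracle_chars(pf)))
    }
  }
  gold_used <- rep(FALSE, length(gold))
  pred_used <- rep(FALSE, length(pred))
  tp <- 0L
  repeat {
    best <- NULL
    for (i in seq_along(gold)) {
      for (j in seq_along(pred)) {
        if (compat[i, j] && !gold_used[[i]] && !pred_used[[j]]) {
          if (is.null(best) || shared[i, j] > shared[best[1], best[2]]) {
            best <- c(i, j)
          }
        }
      }
    }
    if (is.null(best)) break
    gold_used[[best[1]]] <- TRUE
    pred_used[[best[2]]] <- TRUE
    tp <- tp + 1L
  }
  c(tp = tp, fp = sum(!pred_used), fn = sum(!gold_used))
}

# corpus-level wrapper over oracle_match
oracle_match_corpus <- function(gold, pred, mode, require_id = FALSE,
                                labels = c("KEYF", "NORMF")) {
  to_obs <- function(corpus) {
    rows <- corpus[!is.na(corpus$label) & corpus$label %in% labels, ]
    split(
      lapply(seq_len(nrow(rows)), function(i) {
        list(frags = parse_spans(rows$spans[[i]])[[1]], id = rows$hpo_id[[i]])
      }),
      rows$observation_id[seq_len(nrow(rows))]
    )
  }
  gl <- to_obs(gold)
  pl <- to_obs(pred)
  texts <- unique(rbind(gold[c("observation_id", "text")],
                        pred[c("observation_id", "text")]))
  total <- c(tp = 0L, fp = 0L, fn = 0L)
  for (i in seq_len(nrow(texts))) {
    id <- texts$observation_id[[i]]
    total <- total + oracle_match(texts$text[[i]],
                                  gl[[id]] %||% list(),
                                  pl[[id]] %||% list(),
                                  mode, require_id)
  }
  total
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# fixture vocabulary for grounding oracle tests: pairwise substring-free
oracle_vocab <- c("alpha", "bravo", "charl", "delta", "echo", "foxt",
                  "golf", "hotel", "india", "juliet", "kilo", "lima")
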