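#' Precision, recall and F1 from confusion counts
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)` and the harmonic
#' mean `f1 = 2PR / (P + R)`; any degenerate denominator yields 0. With the
#' counts tp = 44, fp = 34, fn = 34 this gives F1 = 0.564 to three decimals.
#'
#' @param tp,fp,fn Non-negative confusion counts (vectorized).
#' @return A tibble of class `"phen_eval"` with columns `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`.
#' @examples
#' prf(44, 34, 34)
#' @export
prf <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) abort("Confusion counts must be non-negative.")
  p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  out <- tibble(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
                precision = p, recall = r, f1 = f1)
  class(out) <- c("phen_eval", class(out))
  out
}

# ---- per-observation matching machinery ------------------------------------

# Token cores of a text: maximal non-whitespace runs with leading/trailing
# punctuation stripped. Partial matching and overlap categorization work at
# this granularity so that gold fragments that exclude sentence punctuation
# still own their token.
token_cores <- function(text) {
  toks <- tokenize_offsets(text)
  if (nrow(toks) == 0L) return(toks)
  lead <- nchar(toks$token) - nchar(sub("^[[:punct:]]+", "", toks$token))
  core <- strip_punct(toks$token)
  out <- tibble(token = core,
                start = toks$start + lead,
                end = toks$start + lead + nchar(core))
  out[nzchar(core), ]
}

# Indices of tokens whose core is fully covered by some fragment.
covered_tokens <- function(frags, cores) {
  which(vapply(seq_len(nrow(cores)), function(i) {
    any(frags[, "start"] <= cores$start[[i]] & cores$end[[i]] <= frags[, "end"])
  }, logical(1)))
}

covered_chars <- function(frags) {
  unlist(lapply(seq_len(nrow(frags)), function(i) {
    seq.int(frags[i, "start"], frags[i, "end"] - 1L)
  }))
}

# One-to-one greedy matching for a single observation. gold/pred are lists
# with elements frags (matrix), id (chr). Returns matched index pairs.
match_one <- function(text, gold, pred, mode, require_id = FALSE) {
  mode <- match.arg(mode, c("exact", "partial"))
  ng <- length(gold)
  np <- length(pred)
  if (ng == 0L || np == 0L) {
    return(list(pairs = matrix(integer(0), 0L, 2L),
                tp = 0L, fp = np, fn = ng,
                matched_pred = logical(np), matched_gold = logical(ng)))
  }
  cores <- token_cores(text)
  gtok <- lapply(gold, function(m) covered_tokens(m$frags, cores))
  ptok <- lapply(pred, function(m) covered_tokens(m$frags, cores))
  gchr <- lapply(gold, function(m) covered_chars(m$frags))
  pchr <- lapply(pred, function(m) covered_chars(m$frags))

  cand <- list()
  for (i in seq_len(ng)) {
    for (j in seq_len(np)) {
      ok <- if (mode == "exact") {
        identical(dim(gold[[i]]$frags), dim(pred[[j]]$frags)) &&
          all(gold[[i]]$frags == pred[[j]]$frags)
      } else {
        length(intersect(gtok[[i]], ptok[[j]])) > 0L
      }
      if (ok && require_id) {
        ok <- !is.na(gold[[i]]$id) && !is.na(pred[[j]]$id) &&
          gold[[i]]$id == pred[[j]]$id
      }
      if (ok) {
        cand[[length(cand) + 1L]] <-
          c(i, j, length(intersect(gchr[[i]], pchr[[j]])))
      }
    }
  }
  matched_gold <- logical(ng)
  matched_pred <- logical(np)
  pairs <- matrix(integer(0), 0L, 2L)
  if (length(cand) > 0L) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand[, 3L], cand[, 1L], cand[, 2L]), , drop = FALSE]
    for (row in seq_len(nrow(cand))) {
      i <- cand[row, 1L]
      j <- cand[row, 2L]
      if (!matched_gold[[i]] && !matched_pred[[j]]) {
        matched_gold[[i]] <- TRUE
        matched_pred[[j]] <- TRUE
        pairs <- rbind(pairs, c(i, j))
      }
    }
  }
  list(pairs = pairs, tp = nrow(pairs),
       fp = sum(!matched_pred), fn = sum(!matched_gold),
       matched_pred = matched_pred, matched_gold = matched_gold)
}

# Split a corpus into per-observation mention lists, pairing gold and pred
# by observation id. Errors if the same id carries different text.
paired_observations <- function(gold, pred) {
  gold <- validate_corpus(gold)
  pred <- validate_corpus(pred)
  gm <- corpus_mentions(gold)
  pm <- corpus_mentions(pred)
  texts <- dplyr::bind_rows(corpus_observations(gold), corpus_observations(pred)) |>
    distinct()
  if (anyDuplicated(texts$observation_id) > 0L) {
    dup <- texts$observation_id[duplicated(texts$observation_id)][[1L]]
    abort(sprintf("Observation '%s' has different texts in gold and predictions.",
                  dup))
  }
  to_list <- function(df) {
    if (nrow(df) == 0L) return(list())
    frag_list <- parse_spans(df$spans)
    split(
      lapply(seq_len(nrow(df)), function(i) {
        list(frags = frag_list[[i]], id = df$hpo_id[[i]], label = df$label[[i]])
      }),
      factor(df$observation_id, levels = texts$observation_id)
    )
  }
  gl <- to_list(gm)
  pl <- to_list(pm)
  lapply(seq_len(nrow(texts)), function(i) {
    id <- texts$observation_id[[i]]
    list(id = id, text = texts$text[[i]],
         gold = gl[[id]] %||% list(), pred = pl[[id]] %||% list())
  })
}

sum_counts <- function(per_obs) {
  prf(sum(map_int(per_obs, "tp")),
      sum(map_int(per_obs, "fp")),
      sum(map_int(per_obs, "fn")))
}

#' Span-matching evaluation
#'
#' Matches predicted mention spans against gold spans one-to-one, greedily
#' by descending shared-character count (ties by gold offset order). Under
#' `"exact"` matching a prediction matches a gold mention only when their
#' fragment sets are identical; under `"partial"` matching it suffices to
#' share at least one whole token (a maximal non-whitespace run, compared on
#' its punctuation-stripped core). `tp` counts matched pairs, `fp` unmatched
#' predictions, `fn` unmatched gold mentions, summed over observations.
#'
#' @param gold,pred Corpus tibbles covering the same observations (an
#'   observation with different texts on the two sides is an error).
#' @param mode `"exact"` or `"partial"`.
#' @return A `"phen_eval"` report (see [prf()]).
#' @export
match_spans <- function(gold, pred, mode = c("exact", "partial")) {
  mode <- match.arg(mode)
  per_obs <- lapply(paired_observations(gold, pred), function(o) {
    match_one(o$text, o$gold, o$pred, mode)
  })
  sum_counts(per_obs)
}

#' Normalization-only evaluation
#'
#' Scores the assigned HPO identifiers alone: per observation, the multiset
#' intersection of gold and predicted identifiers counts as true positives
#' and the leftovers as false positives / negatives. Spans are ignored
#' entirely. Only mentions with the given labels participate (key findings
#' by default -- they are the only entities the normalizer sees); mentions
#' lacking an identifier are excluded from the multisets and reported via
#' the `"n_missing_id"` attribute.
#'
#' @inheritParams match_spans
#' @param labels Mention labels to score (default `"KEYF"`).
#' @return A `"phen_eval"` report.
#' @export
evaluate_normalization <- function(gold, pred, labels = "KEYF") {
  per_obs <- lapply(paired_observations(gold, pred), function(o) {
    gids <- unlist(lapply(o$gold, function(m) if (m$label %in% labels) m$id))
    pids <- unlist(lapply(o$pred, function(m) if (m$label %in% labels) m$id))
    miss <- sum(is.na(gids)) + sum(is.na(pids))
    gids <- gids[!is.na(gids)]
    pids <- pids[!is.na(pids)]
    gt <- table(gids)
    pt <- table(pids)
    common <- intersect(names(gt), names(pt))
    tp <- sum(pmin(as.integer(gt[common]), as.integer(pt[common])))
    list(tp = tp, fp = length(pids) - tp, fn = length(gids) - tp, miss = miss)
  })
  out <- sum_counts(per_obs)
  attr(out, "n_missing_id") <- sum(map_int(per_obs, "miss"))
  out
}

#' Combined extraction-and-normalization evaluation
#'
#' Measures both pipeline stages together: a (gold, prediction) pair counts
#' as a true positive only if the spans match under `mode` *and* the HPO
#' identifiers are equal; matching is one-to-one as in [match_spans()].
#' Restricted to key findings by default.
#'
#' @inheritParams evaluate_normalization
#' @param mode `"exact"` or `"partial"`.
#' @return A `"phen_eval"` report.
#' @export
evaluate_combined <- function(gold, pred, mode = c("exact", "partial"),
                              labels = "KEYF") {
  mode <- match.arg(mode)
  per_obs <- lapply(paired_observations(gold, pred), function(o) {
    g <- keep(o$gold, ~ .x$label %in% labels)
    p <- keep(o$pred, ~ .x$label %in% labels)
    match_one(o$text, g, p, mode, require_id = TRUE)
  })
  sum_counts(per_obs)
}

#' Disjoint-only span evaluation
#'
#' Restricts scoring to discontinuous mentions: gold mentions with at least
#' two fragments are retained; predictions matched to a retained gold count
#' as true positives, unmatched predictions count as false positives only
#' when they are themselves discontinuous (contiguous predictions are
#' excluded from the stratum), and unmatched disjoint golds are false
#' negatives.
#'
#' @inheritParams match_spans
#' @return A `"phen_eval"` report.
#' @export
disjoint_only <- function(gold, pred, mode = c("exact", "partial")) {
  mode <- match.arg(mode)
  per_obs <- lapply(paired_observations(gold, pred), function(o) {
    g <- keep(o$gold, ~ nrow(.x$frags) >= 2L)
    m <- match_one(o$text, g, o$pred, mode)
    pred_disc <- map_lgl(o$pred, ~ nrow(.x$frags) >= 2L)
    list(tp = m$tp, fn = m$fn,
         fp = sum(!m$matched_pred & pred_disc))
  })
  sum_counts(per_obs)
}

#' Class-wise span evaluation
#'
#' Restricts both corpora to one mention label (KEYF or NORMF) before span
#' matching, so recognition quality can be compared across finding classes.
#'
#' @inheritParams match_spans
#' @param label `"KEYF"` or `"NORMF"`.
#' @return A `"phen_eval"` report.
#' @export
classwise <- function(gold, pred, mode = c("exact", "partial"),
                      label = c("KEYF", "NORMF")) {
  mode <- match.arg(mode)
  label <- match.arg(label)
  per_obs <- lapply(paired_observations(gold, pred), function(o) {
    match_one(o$text,
              keep(o$gold, ~ .x$label == label),
              keep(o$pred, ~ .x$label == label),
              mode)
  })
  sum_counts(per_obs)
}

# ---- discontinuity structure ------------------------------------------------

#' Categorize the overlap structure of discontinuous mentions
#'
#' Discontinuous mentions arising from coordination ellipsis often share
#' tokens (a *shared head*) with sibling mentions of the same observation.
#' Each mention is assigned one of: `"contiguous"` (a single fragment),
#' `"no_overlap"` (no token shared with any sibling), `"left_overlap"` /
#' `"right_overlap"` (all shared tokens lie in the mention's leftmost /
#' rightmost fragment, one sharing sibling), or `"multiple_overlap"`
#' (shared regions at more than one position, or two or more sharing
#' siblings). Tokens are compared on punctuation-stripped cores.
#'
#' @param corpus A corpus tibble.
#' @return `corpus` with an added `disc_category` column (`NA` for
#'   observation-only rows).
#' @export
categorize_disc <- function(corpus) {
  corpus <- validate_corpus(corpus)
  corpus$disc_category <- NA_character_
  mention_idx <- which(!is.na(corpus$label))
  if (length(mention_idx) == 0L) return(corpus)
  frag_list <- parse_spans(corpus$spans[mention_idx])
  by_obs <- split(seq_along(mention_idx), corpus$observation_id[mention_idx])
  for (rows in by_obs) {
    text <- corpus$text[[mention_idx[[rows[[1L]]]]]]
    cores <- token_cores(text)
    toksets <- lapply(rows, function(r) covered_tokens(frag_list[[r]], cores))
    for (pos in seq_along(rows)) {
      r <- rows[[pos]]
      corpus$disc_category[[mention_idx[[r]]]] <- disc_category_one(
        frag_list[[r]], toksets[[pos]], toksets[-pos], cores
      )
    }
  }
  corpus
}

disc_category_one <- function(frags, toks, sibling_toks, cores) {
  if (nrow(frags) < 2L) return("contiguous")
  shared_by_sib <- lapply(sibling_toks, function(s) intersect(toks, s))
  sharing <- sum(map_int(shared_by_sib, length) > 0L)
  if (sharing == 0L) return("no_overlap")
  if (sharing >= 2L) return("multiple_overlap")
  shared <- unlist(shared_by_sib)
  # which fragment of the mention holds each shared token
  frag_of <- vapply(shared, function(i) {
    which(frags[, "start"] <= cores$start[[i]] &
            cores$end[[i]] <= frags[, "end"])[[1L]]
  }, integer(1))
  if (all(frag_of == 1L)) return("left_overlap")
  if (all(frag_of == nrow(frags))) return("right_overlap")
  "multiple_overlap"
}

# ---- corpus statistics ------------------------------------------------------

#' Percentage of disjoint mentions
#'
#' `100 * n_disjoint / n_entities`, rounded to one decimal (the convention
#' used in corpus summary tables); 0 for an empty corpus.
#'
#' @param n_disjoint,n_entities Non-negative counts.
#' @return A numeric percentage.
#' @examples
#' disjoint_percent(369, 2562)
#' @export
disjoint_percent <- function(n_disjoint, n_entities) {
  ifelse(n_entities > 0, round(100 * n_disjoint / n_entities, 1), 0)
}

#' Corpus summary statistics
#'
#' Counts observations, entities, disjoint (multi-fragment) mentions and
#' their 2-part / 3-part breakdown, finding classes, and the percentage of
#' disjoint mentions.
#'
#' @param corpus A corpus tibble.
#' @return A one-row tibble of class `"phen_stats"`.
#' @export
corpus_stats <- function(corpus) {
  corpus <- validate_corpus(corpus)
  mentions <- corpus_mentions(corpus)
  n_parts <- if (nrow(mentions) > 0L) {
    map_int(parse_spans(mentions$spans), nrow)
  } else {
    integer(0)
  }
  out <- tibble(
    n_observations = nrow(corpus_observations(corpus)),
    n_entities = nrow(mentions),
    n_disjoint = sum(n_parts >= 2L),
    pct_disjoint = disjoint_percent(sum(n_parts >= 2L), nrow(mentions)),
    n_disjoint_2part = sum(n_parts == 2L),
    n_disjoint_3part = sum(n_parts == 3L),
    n_normf = sum(mentions$label == "NORMF"),
    n_keyf = sum(mentions$label == "KEYF")
  )
  class(out) <- c("phen_stats", class(out))
  out
}

# ---- report assembly, broom-style accessors, plotting -----------------------

#' Full evaluation report across strata and modes
#'
#' Assembles the standard result table: overall span matching (exact and
#' partial), disjoint-only span matching, class-wise span matching,
#' normalization-only, and combined extraction + normalization.
#'
#' @inheritParams match_spans
#' @return A `"phen_eval"` tibble with one row per (stratum, mode).
#' @export
evaluation_report <- function(gold, pred) {
  with_meta <- function(report, stratum, mode) {
    report$stratum <- stratum
    report$mode <- mode
    dplyr::relocate(as_tibble(report), "stratum", "mode")
  }
  out <- bind_rows(
    with_meta(match_spans(gold, pred, "exact"), "spans", "exact"),
    with_meta(match_spans(gold, pred, "partial"), "spans", "partial"),
    with_meta(disjoint_only(gold, pred, "exact"), "disjoint", "exact"),
    with_meta(disjoint_only(gold, pred, "partial"), "disjoint", "partial"),
    with_meta(classwise(gold, pred, "exact", "KEYF"), "keyf", "exact"),
    with_meta(classwise(gold, pred, "exact", "NORMF"), "normf", "exact"),
    with_meta(evaluate_normalization(gold, pred), "normalization", "ids"),
    with_meta(evaluate_combined(gold, pred, "exact"), "combined", "exact"),
    with_meta(evaluate_combined(gold, pred, "partial"), "combined", "partial")
  )
  class(out) <- c("phen_eval", class(out))
  out
}

#' @export
tidy.phen_eval <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  tidyr::pivot_longer(out,
                      cols = c("precision", "recall", "f1"),
                      names_to = "metric", values_to = "value")
}

#' @export
glance.phen_eval <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @export
autoplot.phen_eval <- function(object, ...) {
  long <- tidy(object)
  if (!"stratum" %in% names(long)) long$stratum <- "all"
  if (!"mode" %in% names(long)) long$mode <- ""
  long$panel <- trimws(paste(long$stratum, long$mode))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~panel) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Span extraction and normalization scores")
}
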