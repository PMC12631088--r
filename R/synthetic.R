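# Vocabulary for the synthetic finding grammar. All words are pairwise
# substring-free (no word, filler, cue or header contains another), which
# keeps surface placements unambiguous inside one observation.
syn_vocab <- list(
  parts = c("thumbs", "eyebrows", "nostrils", "philtrum", "earlobes",
            "knuckles", "eyelids", "cheeks", "ankles", "wrists", "elbows",
            "shoulders", "gums", "tongue", "scalp", "navel", "spine",
            "heels", "palms", "soles", "temples", "clavicles", "kneecaps",
            "shins", "forearms", "insteps"),
  qualities = c("broad", "sparse", "slender", "shallow", "crowded", "tapered",
                "webbed", "cupped", "notched", "ridged", "pitted", "mottled",
                "bulky", "angular", "drooping", "flared", "sunken", "coarse",
                "uneven", "rigid", "bowed", "furrowed", "speckled", "blotchy",
                "scaly", "puffy", "arched", "splayed", "stubby", "wrinkled"),
  suffixes = c("creases", "folds", "margins", "contours", "borders",
               "patches", "grooves", "whorls"),
  fillers = c("slightly", "mildly", "faintly", "barely", "visibly",
              "somewhat", "oddly", "rather"),
  cues = c("no", "normal"),
  headers = c("EXAM", "EYES", "FACE", "NECK", "MOUTH", "EARS", "NOSE",
              "SKIN", "CHEST", "BACK", "LIMBS", "ABDOMEN")
)

maybe_seeded <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Generate a toy ontology dictionary
#'
#' Builds `n_ids` identifiers (`"HP:"` + 7 zero-padded digits), each with one
#' preferred surface and `synonyms_per_id` synonyms. Surfaces come from a
#' finding grammar over body parts and qualities in three shapes --
#' `"quality part"`, `"part quality"` and `"quality part suffix"` -- cycled
#' so that every shape is represented; all surfaces are distinct. Fully
#' reproducible for a given seed.
#'
#' @param n_ids Number of identifiers (>= 1).
#' @param synonyms_per_id Synonyms per identifier (>= 0).
#' @param seed Optional integer seed.
#' @return A dictionary tibble (see [load_dictionary()]).
#' @export
make_dictionary <- function(n_ids, synonyms_per_id = 0L, seed = NULL) {
  stopifnot(n_ids >= 1L, synonyms_per_id >= 0L)
  maybe_seeded(seed, {
    v <- syn_vocab
    # partition the quality x part grid between the two 2-token orientations
    # so no two surfaces in the dictionary share a word token set (keeps
    # token-set rerank scores tie-free for exact surface matches)
    grid <- expand.grid(q = v$qualities, p = v$parts,
                        stringsAsFactors = FALSE)
    grid <- grid[sample.int(nrow(grid)), ]
    half <- nrow(grid) %/% 2L
    t1 <- paste(grid$q[seq_len(half)], grid$p[seq_len(half)])     # quality part
    t2 <- paste(grid$p[-seq_len(half)], grid$q[-seq_len(half)])   # part quality
    t3 <- as.vector(outer(paste(grid$q, grid$p), v$suffixes, paste))
    pools <- list(sample(t1), sample(t2), sample(t3))
    total <- n_ids * (1L + synonyms_per_id)
    if (total > sum(lengths(pools))) {
      abort(sprintf("Requested %d surfaces but the grammar yields only %d.",
                    total, sum(lengths(pools))))
    }
    taken <- c(0L, 0L, 0L)
    surfaces <- character(total)
    for (i in seq_len(total)) {
      pool <- ((i - 1L) %% 3L) + 1L
      while (taken[[pool]] >= length(pools[[pool]])) pool <- pool %% 3L + 1L
      taken[[pool]] <- taken[[pool]] + 1L
      surfaces[[i]] <- pools[[pool]][[taken[[pool]]]]
    }
    ids <- sprintf("HP:%07d", sample.int(9999999L, n_ids))
    validate_dictionary(tibble(
      hpo_id = rep(ids, each = 1L + synonyms_per_id),
      surface = surfaces,
      is_preferred = rep(c(TRUE, rep(FALSE, synonyms_per_id)), times = n_ids)
    ))
  })
}

# ---- corpus generation ------------------------------------------------------

# classify a dictionary surface by its token shape
surface_shape <- function(surface) {
  toks <- strsplit(surface, " ", fixed = TRUE)[[1]]
  if (length(toks) == 3L) return("t3")
  if (toks[[1]] %in% syn_vocab$parts) "t2" else "t1"
}

#' Generate a seeded synthetic corpus of annotated observations
#'
#' Emits sectioned clinical observations (`"EYES: ..."`) whose mentions are
#' dictionary surfaces, so every key finding carries a gold HPO identifier.
#' Discontinuous mentions are realized either by interrupting a surface with
#' filler modifiers (non-overlapping disjoint mentions) or by coordination
#' with a shared head (`"thumbs broad and slender"` style), producing left-,
#' right- and multiple-overlap structures. Normal findings are realized as a
#' negation cue followed by a surface, with the gold span covering the
#' surface only. Gold offsets are recorded exactly during text assembly, and
#' within one observation every mention surface has a unique placement (no
#' dictionary word repeats).
#'
#' Default rates mirror the published corpus analysis: 14.4% disjoint
#' mentions, a ~12.8% normal-finding share, and a 3-part share of 11/369
#' among disjoint mentions.
#'
#' @param dictionary A dictionary tibble (see [make_dictionary()]).
#' @param n_obs Number of observations.
#' @param disjoint_rate Probability that a mention slot is discontinuous.
#' @param normf_rate Probability that a continuous slot is a normal finding.
#' @param overlap_mix Named probabilities over
#'   `c("no_overlap", "left_overlap", "right_overlap", "multiple_overlap")`.
#' @param parts_mix Named probabilities over `c("2", "3")` constituent parts
#'   for non-overlapping disjoint mentions.
#' @param seed Optional integer seed.
#' @return A corpus tibble (see [phen_corpus()]).
#' @export
generate_corpus <- function(dictionary,
                            n_obs = 200L,
                            disjoint_rate = 0.144,
                            normf_rate = 0.128,
                            overlap_mix = c(no_overlap = 0.26, left_overlap = 0.42,
                                            right_overlap = 0.20, multiple_overlap = 0.12),
                            parts_mix = c("2" = 0.97, "3" = 0.03),
                            seed = NULL) {
  dictionary <- validate_dictionary(dictionary)
  for (rate in c(disjoint_rate, normf_rate)) {
    if (rate < 0 || rate > 1) abort("Rates must lie in [0, 1].")
  }
  overlap_mix <- check_mix(overlap_mix, c("no_overlap", "left_overlap",
                                          "right_overlap", "multiple_overlap"),
                           "overlap_mix")
  parts_mix <- check_mix(parts_mix, c("2", "3"), "parts_mix")

  shapes <- vapply(dictionary$surface, surface_shape, character(1), USE.NAMES = FALSE)
  id_of <- setNames(dictionary$hpo_id, dictionary$surface)
  pool2 <- dictionary$surface[shapes != "t3"]
  pool_t3 <- dictionary$surface[shapes == "t3"]
  pool_all <- dictionary$surface
  # coordination pair pools
  tok1 <- function(s) vapply(strsplit(s, " "), `[[`, "", 1L)
  tok2 <- function(s) vapply(strsplit(s, " "), function(x) x[[2]], "")
  t2s <- dictionary$surface[shapes == "t2"]
  t1s <- dictionary$surface[shapes == "t1"]
  left_groups <- split(t2s, tok1(t2s))        # part quality, share leading part
  left_groups <- left_groups[lengths(left_groups) >= 2L]
  right_groups <- split(t1s, tok2(t1s))       # quality part, share trailing part
  right_groups <- right_groups[lengths(right_groups) >= 2L]
  multi_key <- function(s) {
    toks <- strsplit(s, " ")
    vapply(toks, function(x) paste(x[[1]], x[[3]]), "")
  }
  multi_groups <- if (length(pool_t3) > 0L) split(pool_t3, multi_key(pool_t3)) else list()
  multi_groups <- multi_groups[lengths(multi_groups) >= 2L]

  maybe_seeded(seed, {
    obs_rows <- vector("list", n_obs)
    for (i in seq_len(n_obs)) {
      obs_rows[[i]] <- generate_observation(
        id = sprintf("OBS%05d", i),
        header = sample(syn_vocab$headers, 1L),
        disjoint_rate = disjoint_rate, normf_rate = normf_rate,
        overlap_mix = overlap_mix, parts_mix = parts_mix,
        pools = list(all = pool_all, two = pool2, t3 = pool_t3,
                     left = left_groups, right = right_groups,
                     multi = multi_groups),
        id_of = id_of
      )
    }
    validate_corpus(bind_rows(obs_rows))
  })
}

check_mix <- function(mix, keys, what) {
  if (!all(keys %in% names(mix)) || any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
    abort(sprintf("`%s` must be non-negative probabilities over {%s} summing to 1.",
                  what, paste(keys, collapse = ", ")))
  }
  mix[keys]
}

words_of <- function(surfaces) unlist(strsplit(surfaces, " ", fixed = TRUE))

# draw a surface whose words are all unused; NULL when the pool is exhausted
draw_surface <- function(pool, used) {
  for (s in sample(pool)) {
    if (!any(words_of(s) %in% used)) return(s)
  }
  NULL
}

# draw a within-group pair whose combined words are unused
draw_pair <- function(groups, used) {
  if (length(groups) == 0L) return(NULL)
  for (g in sample(groups)) {
    free <- g[!vapply(g, function(s) any(words_of(s) %in% used), TRUE)]
    if (length(free) >= 2L) return(sample(free, 2L))
  }
  NULL
}

generate_observation <- function(id, header, disjoint_rate, normf_rate,
                                 overlap_mix, parts_mix, pools, id_of) {
  n_slots <- 1L + rbinom(1L, 2L, 0.25)
  disjoint <- runif(n_slots) < disjoint_rate
  labels <- ifelse(!disjoint & runif(n_slots) < normf_rate, "NORMF", "KEYF")

  used <- character(0)
  chunks <- list()
  partner_free <- which(!disjoint & labels == "KEYF")   # candidate coordination partners
  disc_free <- which(disjoint)
  consumed <- logical(n_slots)

  for (slot in seq_len(n_slots)) {
    if (consumed[[slot]]) next
    consumed[[slot]] <- TRUE
    if (!disjoint[[slot]]) {
      surface <- draw_surface(pools$all, used)
      if (is.null(surface)) abort("Dictionary too small for the requested corpus.")
      used <- c(used, words_of(surface))
      chunks[[length(chunks) + 1L]] <-
        chunk_continuous(surface, labels[[slot]], id_of)
      next
    }
    cat <- sample(names(overlap_mix), 1L, prob = overlap_mix)
    pair <- NULL
    # a category the mix *forces* must be realizable from the dictionary;
    # categories drawn with probability < 1 quietly fall back to no_overlap
    # when no suitable surface pair exists
    if (cat == "left_overlap" && overlap_mix[["left_overlap"]] >= 1 &&
        length(pools$left) == 0L) {
      abort("overlap_mix forces left-overlap pairs but the dictionary has no two part-quality surfaces sharing a part.")
    }
    if (cat == "right_overlap" && overlap_mix[["right_overlap"]] >= 1 &&
        length(pools$right) == 0L) {
      abort("overlap_mix forces right-overlap pairs but the dictionary has no two quality-part surfaces sharing a part.")
    }
    if (cat == "multiple_overlap" && overlap_mix[["multiple_overlap"]] >= 1 &&
        length(pools$multi) == 0L) {
      abort("overlap_mix forces multiple-overlap pairs but the dictionary has no two three-token surfaces sharing quality and suffix.")
    }
    if (cat %in% c("left_overlap", "right_overlap")) {
      partner <- setdiff(partner_free, which(consumed))
      pair <- draw_pair(pools[[if (cat == "left_overlap") "left" else "right"]], used)
      if (length(partner) == 0L || is.null(pair)) cat <- "no_overlap"
    }
    if (cat == "multiple_overlap") {
      other <- setdiff(disc_free, which(consumed))
      pair <- draw_pair(pools$multi, used)
      if (length(other) == 0L || is.null(pair)) cat <- "no_overlap"
    }
    chunk <- switch(
      cat,
      no_overlap = {
        k <- as.integer(sample(names(parts_mix), 1L, prob = parts_mix))
        pool <- if (k == 3L) pools$t3 else pools$two
        if (length(pool) == 0L) {
          abort(sprintf("parts_mix requests %d-part disjoint mentions but the dictionary has no %d-token surface.",
                        k, k))
        }
        surface <- draw_surface(pool, used)
        if (is.null(surface)) abort("Dictionary too small for the requested corpus.")
        chunk_interrupted(surface, k, id_of)
      },
      left_overlap = {
        consumed[[partner[[1L]]]] <- TRUE
        chunk_left(pair, id_of)
      },
      right_overlap = {
        consumed[[partner[[1L]]]] <- TRUE
        chunk_right(pair, id_of)
      },
      multiple_overlap = {
        consumed[[other[[1L]]]] <- TRUE
        chunk_multi(pair, id_of)
      }
    )
    used <- c(used, unique(words_of(chunk$surfaces)))
    chunks[[length(chunks) + 1L]] <- chunk
  }

  assemble_observation(id, header, sample(chunks))
}

# A chunk: words (character vector) plus mentions, each mention a list with
# label, hpo_id and runs -- a list of (from, to) word index ranges.
chunk_continuous <- function(surface, label, id_of) {
  toks <- words_of(surface)
  if (label == "NORMF") {
    cue <- sample(syn_vocab$cues, 1L)
    list(words = c(cue, toks), surfaces = surface,
         mentions = list(list(label = "NORMF", hpo_id = id_of[[surface]],
                              runs = list(c(2L, length(toks) + 1L)))))
  } else {
    list(words = toks, surfaces = surface,
         mentions = list(list(label = "KEYF", hpo_id = id_of[[surface]],
                              runs = list(c(1L, length(toks))))))
  }
}

chunk_interrupted <- function(surface, k, id_of) {
  toks <- words_of(surface)
  fillers <- sample(syn_vocab$fillers, k - 1L)
  if (k == 2L) {
    words <- c(toks[[1]], fillers[[1]], toks[[2]])
    runs <- list(c(1L, 1L), c(3L, 3L))
  } else {
    words <- c(toks[[1]], fillers[[1]], toks[[2]], fillers[[2]], toks[[3]])
    runs <- list(c(1L, 1L), c(3L, 3L), c(5L, 5L))
  }
  list(words = words, surfaces = surface,
       mentions = list(list(label = "KEYF", hpo_id = id_of[[surface]],
                            runs = runs)))
}

chunk_left <- function(pair, id_of) {
  # pair: "p q1", "p q2" -> "p q1 and q2"
  t1 <- words_of(pair[[1]])
  t2 <- words_of(pair[[2]])
  list(words = c(t1[[1]], t1[[2]], "and", t2[[2]]), surfaces = pair,
       mentions = list(
         list(label = "KEYF", hpo_id = id_of[[pair[[1]]]],
              runs = list(c(1L, 2L))),
         list(label = "KEYF", hpo_id = id_of[[pair[[2]]]],
              runs = list(c(1L, 1L), c(4L, 4L)))
       ))
}

chunk_right <- function(pair, id_of) {
  # pair: "q1 p", "q2 p" -> "q1 and q2 p"
  t1 <- words_of(pair[[1]])
  t2 <- words_of(pair[[2]])
  list(words = c(t1[[1]], "and", t2[[1]], t2[[2]]), surfaces = pair,
       mentions = list(
         list(label = "KEYF", hpo_id = id_of[[pair[[1]]]],
              runs = list(c(1L, 1L), c(4L, 4L))),
         list(label = "KEYF", hpo_id = id_of[[pair[[2]]]],
              runs = list(c(3L, 4L)))
       ))
}

chunk_multi <- function(pair, id_of) {
  # pair: "q p1 s", "q p2 s" -> "q p1 and p2 s"
  t1 <- words_of(pair[[1]])
  t2 <- words_of(pair[[2]])
  list(words = c(t1[[1]], t1[[2]], "and", t2[[2]], t1[[3]]), surfaces = pair,
       mentions = list(
         list(label = "KEYF", hpo_id = id_of[[pair[[1]]]],
              runs = list(c(1L, 2L), c(5L, 5L))),
         list(label = "KEYF", hpo_id = id_of[[pair[[2]]]],
              runs = list(c(1L, 1L), c(4L, 5L)))
       ))
}

assemble_observation <- function(id, header, chunks) {
  text <- paste0(header, ":")
  pos <- nchar(text)
  rows <- list()
  for (ci in seq_along(chunks)) {
    chunk <- chunks[[ci]]
    starts <- integer(length(chunk$words))
    ends <- integer(length(chunk$words))
    for (wi in seq_along(chunk$words)) {
      text <- paste0(text, " ", chunk$words[[wi]])
      starts[[wi]] <- pos + 1L
      pos <- pos + 1L + nchar(chunk$words[[wi]])
      ends[[wi]] <- pos
    }
    if (ci < length(chunks)) {
      text <- paste0(text, ",")
      pos <- pos + 1L
    }
    for (m in chunk$mentions) {
      frags <- t(vapply(m$runs, function(run) {
        c(starts[[run[[1]]]], ends[[run[[2]]]])
      }, integer(2)))
      rows[[length(rows) + 1L]] <- tibble(
        observation_id = id, label = m$label, hpo_id = m$hpo_id,
        spans = format_span_field(as_fragment_matrix(frags))
      )
    }
  }
  text <- paste0(text, ".")
  out <- bind_rows(rows)
  out$text <- text
  select(out, "observation_id", "text", "label", "hpo_id", "spans")
}

# ---- prediction perturbation ------------------------------------------------

#' Perturb a corpus into controlled imperfect predictions
#'
#' Applies independent, seeded perturbations to every mention: deletion with
#' `drop_rate`, a one-token fragment boundary shift with
#' `boundary_shift_rate`, and replacement of the HPO identifier with a
#' different one (drawn from the corpus) with `id_corrupt_rate`. Output is
#' structurally valid; observations whose mentions are all dropped are kept
#' as mention-less rows so the observation set is preserved.
#'
#' @param corpus A corpus tibble.
#' @param drop_rate,boundary_shift_rate,id_corrupt_rate Probabilities in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A perturbed corpus tibble.
#' @export
perturb_predictions <- function(corpus, drop_rate = 0, boundary_shift_rate = 0,
                                id_corrupt_rate = 0, seed = NULL) {
  corpus <- validate_corpus(corpus)
  for (rate in c(drop_rate, boundary_shift_rate, id_corrupt_rate)) {
    if (rate < 0 || rate > 1) abort("Rates must lie in [0, 1].")
  }
  maybe_seeded(seed, {
    obs <- corpus_observations(corpus)
    mentions <- corpus_mentions(corpus)
    ids <- unique(mentions$hpo_id[!is.na(mentions$hpo_id)])
    keep_row <- runif(nrow(mentions)) >= drop_rate
    shift_row <- runif(nrow(mentions)) < boundary_shift_rate
    corrupt_row <- runif(nrow(mentions)) < id_corrupt_rate
    out <- mentions[keep_row, ]
    shift_row <- shift_row[keep_row]
    corrupt_row <- corrupt_row[keep_row]
    if (nrow(out) > 0L) {
      out$spans <- map_chr(seq_len(nrow(out)), function(i) {
        if (!shift_row[[i]]) return(out$spans[[i]])
        shift_boundary(out$text[[i]], out$spans[[i]])
      })
      out$hpo_id <- map_chr(seq_len(nrow(out)), function(i) {
        if (!corrupt_row[[i]] || is.na(out$hpo_id[[i]])) return(out$hpo_id[[i]])
        alt <- setdiff(ids, out$hpo_id[[i]])
        if (length(alt) == 0L) "HP:9999999" else sample(alt, 1L)
      })
    }
    # restore observations that lost all their mentions
    lost <- dplyr::anti_join(obs, out, by = "observation_id")
    if (nrow(lost) > 0L) {
      lost <- mutate(lost, label = NA_character_, hpo_id = NA_character_,
                     spans = NA_character_)
      out <- bind_rows(out, lost)
      out$..ord <- match(out$observation_id, obs$observation_id)
      out <- arrange(out, .data$..ord)
      out$..ord <- NULL
    }
    validate_corpus(out)
  })
}

# Move one fragment boundary by one token, keeping the mention valid.
# Falls back to the unchanged spans when no legal move exists.
shift_boundary <- function(text, spans) {
  frags <- parse_span_field(spans)
  cores <- token_cores(text)
  for (fi in seq_len(nrow(frags))) {
    e <- frags[fi, "end"]
    nxt <- which(cores$start > e)
    if (length(nxt) > 0L) {
      new_end <- cores$end[[nxt[[1L]]]]
      limit <- if (fi < nrow(frags)) frags[fi + 1L, "start"] else nchar(text) + 1L
      if (new_end < limit) {
        cand <- frags
        cand[fi, "end"] <- new_end
        return(format_span_field(cand))
      }
    }
    covered <- covered_tokens(frags[fi, , drop = FALSE], cores)
    if (length(covered) >= 2L) {
      cand <- frags
      cand[fi, "start"] <- cores$start[[covered[[2L]]]]
      return(format_span_field(cand))
    }
  }
  spans
}
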