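test_that("precision, recall and F1 follow the harmonic-mean definition", {
  r <- prf(44, 34, 34)
  expect_equal(round(r$f1, 3), 0.564)
  expect_equal(r$precision, 44 / 78)
  expect_equal(prf(0, 0, 0)[, c("precision", "recall", "f1")],
               tibble::tibble(precision = 0, recall = 0, f1 = 0),
               ignore_attr = TRUE)
  r2 <- prf(1, 1, 0)
  expect_equal(unlist(r2[, 4:6]), c(precision = 0.5, recall = 1, f1 = 2 / 3))
  # scale-free in the counts
  expect_equal(prf(44, 34, 34)[, 4:6], prf(440, 340, 340)[, 4:6])
  expect_error(prf(-1, 0, 0), "non-negative")
})

mk <- function(spans, ids = NA_character_, labels = "KEYF",
               text = "HANDS FEET: Both thumbs are long and broad",
               obs = "O1") {
  phen_corpus(obs, text, label = labels, hpo_id = ids, spans = spans)
}

test_that("exact matching requires identical fragment sets", {
  gold <- mk("17-27,37-42")
  expect_identical(match_spans(gold, mk("17-27,37-42"), "exact")$tp, 1L)
  r <- match_spans(gold, mk("37-42"), "exact")
  expect_identical(unlist(r[, 1:3]), c(tp = 0L, fp = 1L, fn = 1L))
})

test_that("partial matching needs one whole shared token", {
  gold <- mk("17-27,37-42")
  r <- match_spans(gold, mk("37-42"), "partial")
  expect_identical(unlist(r[, 1:3]), c(tp = 1L, fp = 0L, fn = 0L))
  # disjoint spans share nothing in either mode
  gold2 <- mk("0-5")
  for (mode in c("exact", "partial")) {
    r <- match_spans(gold2, mk("12-16"), mode)
    expect_identical(unlist(r[, 1:3]), c(tp = 0L, fp = 1L, fn = 1L))
  }
  # a partial-character (sub-token) overlap is not enough
  r <- match_spans(mk("17-23"), mk("23-27"), "partial")
  expect_identical(r$tp, 0L)
})

test_that("matching is one-to-one: a prediction consumes one gold at most", {
  gold <- phen_corpus("O1", "aa bb cc dd", label = "KEYF",
                      spans = c("0-2", "3-5"))
  pred <- phen_corpus("O1", "aa bb cc dd", label = "KEYF", spans = "0-5")
  r <- match_spans(gold, pred, "partial")
  expect_identical(unlist(r[, 1:3]), c(tp = 1L, fp = 0L, fn = 1L))
})

test_that("normalization scoring uses per-observation id multisets", {
  text <- "HANDS FEET: Both thumbs are long and broad"
  gold <- mk("17-27,37-42", ids = "HP:0001252")
  expect_identical(evaluate_normalization(gold, gold)$f1, 1)
  wrong <- mk("17-27,37-42", ids = "HP:0001290")
  r <- evaluate_normalization(gold, wrong)
  expect_identical(unlist(r[, 1:3]), c(tp = 0L, fp = 1L, fn = 1L))
  # multiset semantics: {A, A} vs {A}
  gold2 <- phen_corpus("O1", text, label = "KEYF", hpo_id = "HP:0000001",
                       spans = c("17-27", "37-42"))
  pred2 <- phen_corpus("O1", text, label = "KEYF", hpo_id = "HP:0000001",
                       spans = "17-27")
  r2 <- evaluate_normalization(gold2, pred2)
  expect_identical(unlist(r2[, 1:3]), c(tp = 1L, fp = 0L, fn = 1L))
  # spans are ignored entirely: same ids on different spans still match
  moved <- mk("0-5", ids = "HP:0001252")
  expect_identical(evaluate_normalization(gold, moved)$f1, 1)
  # mentions lacking ids are excluded but reported
  noid <- mk("17-27,37-42")
  r3 <- evaluate_normalization(gold, noid)
  expect_identical(attr(r3, "n_missing_id"), 1L)
})

test_that("combined scoring demands span match and id equality together", {
  gold <- mk("17-27,37-42", ids = "HP:0001252")
  right <- mk("17-27,37-42", ids = "HP:0001252")
  wrong_id <- mk("17-27,37-42", ids = "HP:0001290")
  expect_identical(evaluate_combined(gold, right, "exact")$tp, 1L)
  r <- evaluate_combined(gold, wrong_id, "exact")
  expect_identical(unlist(r[, 1:3]), c(tp = 0L, fp = 1L, fn = 1L))
  # correct id on a one-token subspan: tp under partial only
  sub <- mk("37-42", ids = "HP:0001252")
  expect_identical(evaluate_combined(gold, sub, "exact")$tp, 0L)
  expect_identical(evaluate_combined(gold, sub, "partial")$tp, 1L)
})

test_that("disjoint-only scoring excludes contiguous mentions on both sides", {
  gold <- snippet_corpus()
  r <- disjoint_only(gold, gold, "exact")
  expect_identical(unlist(r[, 1:3]), c(tp = 1L, fp = 0L, fn = 0L))
  # zero disjoint golds: every disjoint prediction is a false positive
  cont <- mk("17-32")
  disc <- mk("17-27,37-42")
  r2 <- disjoint_only(cont, disc, "exact")
  expect_identical(unlist(r2[, 1:3]), c(tp = 0L, fp = 1L, fn = 0L))
  # contiguous predictions never count as disjoint false positives
  r3 <- disjoint_only(cont, cont, "exact")
  expect_identical(unlist(r3[, 1:3]), c(tp = 0L, fp = 0L, fn = 0L))
})

test_that("overlap structures are categorized from shared tokens", {
  # shared head at the leftmost fragment: left overlap
  snip <- categorize_disc(snippet_corpus())
  expect_identical(snip$disc_category[[2]], "left_overlap")
  expect_identical(snip$disc_category[[3]], "contiguous")
  expect_identical(snip$disc_category[[1]], "contiguous")

  # no sibling shares a token: no overlap
  lone <- phen_corpus("O1", "FACE: triangular slightly inverted shaped",
                      label = "KEYF", spans = "0-4,6-16,35-41")
  expect_identical(categorize_disc(lone)$disc_category, "no_overlap")

  # shared tokens at the rightmost fragment
  right <- phen_corpus("O1", "bowed and arched shins here",
                       label = "KEYF", spans = c("0-5,17-22", "10-22"))
  expect_identical(categorize_disc(right)$disc_category[[1]], "right_overlap")

  # first token shared with one sibling, last with another
  multi <- phen_corpus(
    "O1", "deep palmar and plantar creases noted",
    label = "KEYF",
    spans = c("0-11,24-31", "0-4,16-31", "0-4")
  )
  cats <- categorize_disc(multi)$disc_category
  expect_identical(cats[[1]], "multiple_overlap")
  expect_identical(cats[[2]], "multiple_overlap")
})

test_that("class-wise reports pool to the unrestricted counts", {
  dict <- make_dictionary(80, 1, seed = 61)
  gold <- generate_corpus(dict, n_obs = 40, seed = 62)
  pred <- perturb_predictions(gold, drop_rate = 0.2, boundary_shift_rate = 0.2,
                              seed = 63)
  for (mode in c("exact", "partial")) {
    keyf <- classwise(gold, pred, mode, "KEYF")
    normf <- classwise(gold, pred, mode, "NORMF")
    pooled <- match_spans(gold, pred, mode)
    # same-label matching partitions the corpus, so counts add up
    expect_identical(keyf$tp + normf$tp, pooled$tp)
    expect_identical(keyf$fn + normf$fn, pooled$fn)
  }
  # a label absent from both corpora gives an all-zero report
  keyf_only <- gold[!is.na(gold$label) & gold$label == "KEYF", ]
  r <- classwise(keyf_only, keyf_only, "exact", "NORMF")
  expect_identical(unlist(r[, 1:3]), c(tp = 0L, fp = 0L, fn = 0L))
})

test_that("a fixture with the published NORMF confusion counts scores 0.564", {
  # 44 matched, 34 spurious, 34 missed normal findings across observations
  texts <- "aa bb cc dd ee ff gg hh ii jj kk ll"
  starts <- seq(0, 33, 3)
  span_at <- function(k) sprintf("%d-%d", starts[k %% 12 + 1],
                                 starts[k %% 12 + 1] + 2)
  gold <- dplyr::bind_rows(lapply(1:78, function(k) {
    phen_corpus(sprintf("G%02d", k), texts, label = "NORMF", spans = span_at(k))
  }))
  pred <- dplyr::bind_rows(
    lapply(1:44, function(k) {     # 44 exact hits
      phen_corpus(sprintf("G%02d", k), texts, label = "NORMF", spans = span_at(k))
    }),
    lapply(45:78, function(k) {    # 34 misplaced -> fp + fn
      phen_corpus(sprintf("G%02d", k), texts, label = "NORMF",
                  spans = span_at(k + 1))
    })
  )
  r <- classwise(gold, pred, "exact", "NORMF")
  expect_identical(unlist(r[, 1:3]), c(tp = 44L, fp = 34L, fn = 34L))
  expect_equal(round(r$f1, 3), 0.564)
})

test_that("evaluation counts equal the brute-force matcher on perturbed corpora", {
  dict <- make_dictionary(60, 1, seed = 71)
  for (rep in 1:20) {
    gold <- generate_corpus(dict, n_obs = 6, seed = 700 + rep)
    pred <- perturb_predictions(gold, drop_rate = 0.25,
                                boundary_shift_rate = 0.3,
                                id_corrupt_rate = 0.3, seed = 800 + rep)
    for (mode in c("exact", "partial")) {
      got <- match_spans(gold, pred, mode)
      want <- oracle_match_corpus(gold, pred, mode)
      expect_identical(unlist(got[, 1:3]), want)
      gotc <- evaluate_combined(gold, pred, mode)
      wantc <- oracle_match_corpus(gold, pred, mode, require_id = TRUE,
                                   labels = "KEYF")
      expect_identical(unlist(gotc[, 1:3]), wantc)
    }
  }
})

test_that("combined true positives never exceed span or id true positives", {
  dict <- make_dictionary(60, 1, seed = 72)
  gold <- generate_corpus(dict, n_obs = 30, seed = 73)
  pred <- perturb_predictions(gold, drop_rate = 0.1, boundary_shift_rate = 0.2,
                              id_corrupt_rate = 0.2, seed = 74)
  for (mode in c("exact", "partial")) {
    comb <- evaluate_combined(gold, pred, mode)
    spans <- classwise(gold, pred, mode, "KEYF")
    ids <- evaluate_normalization(gold, pred)
    expect_lte(comb$tp, spans$tp)
    expect_lte(comb$tp, ids$tp)
  }
})

test_that("corpus statistics count entities, classes and disjoint parts", {
  s <- corpus_stats(snippet_corpus())
  expect_identical(unlist(s[, c("n_observations", "n_entities", "n_disjoint",
                                "n_disjoint_2part", "n_disjoint_3part",
                                "n_normf", "n_keyf")]),
                   c(n_observations = 2L, n_entities = 3L, n_disjoint = 1L,
                     n_disjoint_2part = 1L, n_disjoint_3part = 0L,
                     n_normf = 1L, n_keyf = 2L))
  empty <- corpus_stats(phen_corpus("O1", "no findings at all"))
  expect_identical(empty$n_entities, 0L)
  expect_identical(empty$pct_disjoint, 0)
  # internal consistency on synthetic data
  dict <- make_dictionary(60, 0, seed = 75)
  s2 <- corpus_stats(generate_corpus(dict, n_obs = 50, seed = 76))
  expect_identical(s2$n_disjoint, s2$n_disjoint_2part + s2$n_disjoint_3part)
  expect_identical(s2$n_entities, s2$n_keyf + s2$n_normf)
})

test_that("mismatched texts for one observation are rejected", {
  a <- phen_corpus("O1", "text one here", label = "KEYF", spans = "0-4")
  b <- phen_corpus("O1", "different text", label = "KEYF", spans = "0-4")
  expect_error(match_spans(a, b), "different texts")
})
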