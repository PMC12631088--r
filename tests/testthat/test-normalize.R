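test_that("the reference encoder produces deterministic unit vectors", {
  enc <- reference_encoder()
  v <- enc$embed(c("Hypotonia", "Hypotonia", "abc"))
  expect_equal(sum(v[1, ]^2), 1, tolerance = 1e-12)
  expect_equal(sum(v[3, ]^2), 1, tolerance = 1e-12)
  expect_identical(v[1, ], v[2, ])
  expect_equal(sum(v[1, ] * v[2, ]), 1, tolerance = 1e-12)
  # shared substrings raise cosine similarity above unrelated terms
  w <- enc$embed(c("Hypotonia", "Generalized hypotonia", "Oral leukoplakia"))
  expect_gt(sum(w[1, ] * w[2, ]), sum(w[1, ] * w[3, ]))
  expect_error(enc$embed(""), "empty")
  expect_error(reference_encoder(dim = 1000), "power of two")
  expect_error(reference_encoder(dim = 512), "power of two")
})

test_that("the index has one row per surface, aligned and reproducible", {
  dict <- norm_toy_dictionary()
  idx <- build_index(dict)
  expect_identical(nrow(idx$embeddings), nrow(dict))
  expect_identical(idx$entries$surface, dict$surface)
  idx2 <- build_index(dict)
  expect_identical(idx$embeddings, idx2$embeddings)
  # synonyms of one id are separate rows
  syn <- tibble::tibble(hpo_id = "HP:0000001",
                        surface = c("a term", "a synonym", "another synonym"),
                        is_preferred = c(TRUE, FALSE, FALSE))
  expect_identical(nrow(build_index(syn)$embeddings), 3L)
})

test_that("candidate generation matches brute-force cosine ranking", {
  dict <- make_dictionary(10, 0, seed = 51)
  enc <- reference_encoder()
  idx <- build_index(dict, enc)
  surface <- "broad thumbs"
  cand <- generate_candidates(surface, idx, k = 10)
  # brute force: cosine against every embedding without assuming unit norms
  q <- enc$embed(surface)[1, ]
  brute <- vapply(dict$surface, function(s) {
    e <- enc$embed(s)[1, ]
    sum(q * e) / (sqrt(sum(q^2)) * sqrt(sum(e^2)))
  }, numeric(1), USE.NAMES = FALSE)
  ord <- order(-brute, dict$surface, dict$hpo_id)
  expect_identical(cand$surface, dict$surface[ord])
  expect_equal(cand$score, brute[ord], tolerance = 1e-9)
})

test_that("candidate lists are sorted, bounded and score-clamped", {
  dict <- make_dictionary(5, 0, seed = 52)
  idx <- build_index(dict)
  cand <- generate_candidates("anything odd", idx, k = 100)
  expect_identical(nrow(cand), 5L)
  expect_true(all(diff(cand$score) <= 0))
  expect_true(all(cand$score >= -1 & cand$score <= 1))
  expect_identical(nrow(generate_candidates("anything odd", idx, k = 2)), 2L)
})

test_that("an exact surface match ranks first with score 1", {
  dict <- norm_toy_dictionary()
  idx <- build_index(dict)
  cand <- generate_candidates("Hypotonia", idx)
  expect_identical(cand$surface[[1]], "Hypotonia")
  expect_equal(cand$score[[1]], 1, tolerance = 1e-9)
})

test_that("reranking is a permutation with deterministic ties", {
  dict <- norm_toy_dictionary()
  idx <- build_index(dict)
  cand <- generate_candidates("hernia", idx)
  constant <- structure(function(surface, term) 0.5, class = "phen_reranker")
  same <- rerank("hernia", cand, constant)
  expect_identical(sort(same$surface), sort(cand$surface))
  # constant scores fall back to the (surface, id) tie rule
  expect_identical(same$surface, sort(cand$surface))
  one <- rerank("hernia", cand[1, ], dice_reranker())
  expect_identical(one$surface, cand$surface[[1]])
})

test_that("the Dice reranker prefers full token overlap", {
  rr <- dice_reranker()
  # hand-computed: {abdominal,wall,hernia} vs {hernia} -> 2*1/4 = 0.5;
  # vs {hernia,of,the,abdominal,wall} -> 2*3/8 = 0.75
  expect_equal(rr("Abdominal wall hernia", "Hernia"), 0.5)
  expect_equal(rr("Abdominal wall hernia", "Hernia of the abdominal wall"), 0.75)
  cand <- generate_candidates("Abdominal wall hernia",
                              build_index(norm_toy_dictionary()))
  top <- rerank("Abdominal wall hernia", cand, rr)
  expect_identical(top$surface[[1]], "Hernia of the abdominal wall")
})

test_that("normalization picks the reranked top-1 identifier", {
  dict <- norm_toy_dictionary()[1:2, ]
  expect_identical(normalize_mention("Hypotonia", dict), "HP:0001252")
  # a synonym added by augmentation wins by exact match
  base <- norm_toy_dictionary()
  corpus <- phen_corpus("A", "note: odd lumpy finding", label = "KEYF",
                        hpo_id = "HP:0100790", spans = "6-23")
  aug <- augment_dictionary(base, corpus)
  expect_identical(normalize_mention("odd lumpy finding", aug), "HP:0100790")
})

test_that("end-to-end normalization equals a brute-force re-implementation", {
  dict <- make_dictionary(20, 1, seed = 53)
  enc <- reference_encoder()
  idx <- build_index(dict, enc)
  rr <- dice_reranker()
  queries <- c(dict$surface[c(3, 8, 25)], "webbed thumbs", "scalp borders")
  for (q in queries) {
    got <- normalize_mention(q, idx, rr, k = 30)
    # brute force: cosine to all, top 30 by the tie rule, Dice over those
    qv <- enc$embed(q)[1, ]
    cos <- vapply(dict$surface,
                  function(s) sum(qv * enc$embed(s)[1, ]), numeric(1),
                  USE.NAMES = FALSE)
    keep <- order(-cos, dict$surface, dict$hpo_id)[1:min(30, nrow(dict))]
    dice <- vapply(dict$surface[keep], function(s) rr(q, s), numeric(1),
                   USE.NAMES = FALSE)
    best <- keep[order(-dice, dict$surface[keep], dict$hpo_id[keep])][1]
    expect_identical(got, dict$hpo_id[[best]])
  }
})

test_that("exact-surface queries hit their own entry across a full dictionary", {
  dict <- make_dictionary(50, 1, seed = 54)
  idx <- build_index(dict)
  for (i in seq_len(nrow(dict))) {
    cand <- generate_candidates(dict$surface[[i]], idx, k = 1)
    expect_identical(cand$surface[[1]], dict$surface[[i]])
    expect_equal(cand$score[[1]], 1, tolerance = 1e-9)
  }
})
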