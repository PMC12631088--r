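---
title: "Recognizing and normalizing discontinuous phenotype mentions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing and normalizing discontinuous phenotype mentions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenospan)
```

## The task and the pipeline model

Clinical observations from dysmorphology examinations contain *key
findings* (KEYF) — phenotypic abnormalities that should be mapped to Human
Phenotype Ontology (HPO) concepts — and *normal findings* (NORMF), which
state the absence of an abnormality and have no HPO representation. A
substantial minority of mentions are **discontinuous**: their tokens are
non-consecutive, represented as 2–3 character-offset fragments (0-based,
half-open, sorted, non-overlapping, separated by at least one character).
Discontinuity arises two ways: filler tokens interrupting a single mention
(non-overlapping), and coordination ellipsis producing several mentions
that share a head token run (overlapping disjoint spans).

`phenospan` implements a two-stage pipeline around a generative NER model:

1. **Extraction.** A sequence-to-sequence backend maps the observation text
   to a linearized target listing each mention as `"<LABEL>: <surface>"`,
   segments joined with `"; "`. This sidesteps the main weakness of
   sequence-labeling schemes: a discontinuous mention needs no special tag
   alphabet, its surface is simply the fragment substrings joined by
   spaces. Decoded surfaces are then *grounded* back to character offsets.
2. **Normalization.** Each grounded KEYF surface is embedded and compared
   against every dictionary surface by cosine similarity (biencoder); the
   top `k = 30` candidates are rescored pairwise (cross-encoder role) and
   the top-1 identifier is kept. NORMF mentions are carried in the span
   output but never normalized or scored for normalization.

The model-sized components are **contracts**, not bundled weights: any
`function(text) -> target` is a backend, any deterministic
`text -> unit vector` embedder is an encoder, any deterministic
`(surface, term) -> score` is a reranker. The package ships deterministic
desk-scale reference implementations of each so that the whole pipeline
runs and is testable offline; trained transformers plug into the same
surfaces.

## Key algorithmic choices

### Target serialization order

Targets place KEYF segments before NORMF segments. Within a label,
mentions are ordered by their fragment-start vector (lexicographically,
shorter prefix first), with the surface string as the final tie-break. A
surface-lexicographic tie-break directly after the *first* fragment start
was rejected: when two normal findings share both a section-header fragment
and a negation fragment (`"NECK: no webbing"` / `"NECK: no cysts"`), only
the full start-vector order reproduces the natural reading order of the
serialized example this scheme is modeled on. Decoding splits on `";"`,
consumes only the first `KEYF:`/`NORMF:` prefix (surfaces may contain
further colons), skips unrecognized segments into a warnings channel, and
collapses duplicate (label, surface) pairs — generative output is treated
as untrusted.

### Grounding

A surface that occurs contiguously in the text is grounded to the leftmost
occurrence as a single fragment. Otherwise both text and surface are
whitespace-tokenized and the surface tokens are partitioned into at most
`max_fragments = 3` runs, each matching a contiguous run of text tokens,
runs strictly left-to-right with at least one intervening text token.
Among feasible placements the objective minimizes, in order: fragment
count, fragment starts (lexicographic), fragment ends (lexicographic). The
first two components make contiguous readings win and results leftmost;
the third is a tie-break the first two leave open (placements identical in
starts but differing in run splits) and was added purely for determinism.
Matching is case-sensitive first with a full case-insensitive second pass,
and token comparison falls back to punctuation-stripped cores, so
`"hooding"` matches the text token `"hooding."` with the returned fragment
excluding the period. `max_fragments` defaults to 3 because corpora in
this domain record at most 3 constituent parts. A surface with no feasible
placement is *ungrounded* — returned as a value, dropped from span output,
but always counted, because it silently costs precision otherwise.

### Normalization

The reference encoder hashes character 3-grams (case-folded, boundary
padded `##`) into a 1024-bucket term-frequency vector, L2-normalized. It
is deterministic and download-free, and shared substrings yield cosine
similarity — sufficient for the architecture's contract, not a claim of
semantic equivalence to a trained sentence embedder. Candidates are
generated **per surface**: synonyms are separate index rows and one
identifier may appear several times in a top-`k` list; collapsing to
unique identifiers would silently change the meaning of `k`. Ties are
broken (score, surface, identifier) everywhere, because floating-point
ties on short strings are common. The reference reranker is the Dice
coefficient over case-folded word-token sets — deterministic,
dependency-free, and genuinely pairwise, preserving the retrieve-then
-rescore architecture. Dictionary augmentation adds every annotated KEYF
surface as a non-preferred synonym of its gold identifier (first observed
surface becomes preferred for identifiers new to the dictionary); the
input dictionary rows are never mutated.

### Evaluation

F1 is the harmonic mean `2PR/(P+R)` with degenerate denominators defined
as 0. Matching is one-to-one and greedy by descending shared-character
count with ties broken in gold offset order; greedy matching is used
because it is deterministic and makes exact-mode true positives a subset
of partial-mode true positives, which in turn makes the dominance
invariant (partial P, R, F1 each at least exact P, R, F1) provable rather
than empirical. *Exact* requires identical fragment sets; *partial*
requires at least one whole shared token, where tokens are maximal
non-whitespace runs compared on punctuation-stripped cores — core
comparison is needed because gold fragments exclude sentence punctuation
that the raw token carries. The disjoint-only stratum keeps gold mentions
with 2 or more fragments, counts matched predictions as true positives,
and counts an unmatched prediction as a false positive only if it is
itself discontinuous: filtering both sides to disjoint mentions is the
reading that makes "scoring restricted to discontinuous mentions"
self-consistent. Normalization-only and combined scoring default to KEYF
mentions, the only class the normalizer sees; mentions lacking an
identifier are excluded from the identifier multisets and surfaced via an
attribute instead of being silently folded into false counts. Overlap
categorization assigns each discontinuous mention `no_overlap`,
`left_overlap`, `right_overlap` or `multiple_overlap` from the fragment
positions of tokens shared with sibling mentions (token granularity; a
fragment-granularity reading was rejected as it cannot distinguish a
shared head inside a two-token fragment).

## The synthetic generator

`generate_corpus()` emulates the structural regime of the corpus this
machinery targets: sectioned observations (`"EYES: ..."`), 1–3 mentions
each (mean 1.5), every mention surface drawn from the dictionary so every
KEYF carries a gold identifier, and exact gold offsets recorded during
text assembly. Defaults mirror the published corpus analysis:
`disjoint_rate = 0.144`, `normf_rate = 0.128` (normal-finding share), and
a 3-part share of about 3% among disjoint mentions (11/369). Each mention
slot flips an independent coin for discontinuity, so the realized disjoint
count is exactly binomial in the entity count — the calibration the
acceptance checks verify against exact 99% binomial intervals.

Structural templates: interrupting fillers realize non-overlapping
disjoint mentions; coordination templates (`"p q1 and q2"`,
`"q1 and q2 p"`, `"q p1 and p2 s"`) realize left, right and multiple
overlap. Coordinations need a partner slot in the same observation (a
contiguous KEYF for left/right, a second disjoint slot for multiple); when
none is available the draw falls back to `no_overlap`, so the realized
overlap mix is conditional on slot availability and skews toward
`no_overlap` at realistic rates — an accepted distortion that keeps the
disjoint count exactly binomial. A category the mix *forces* (probability
1) that the dictionary cannot realize is an error naming the config key.

The generator's vocabulary is built so no word is a substring of another
and no dictionary word repeats within an observation, making every gold
surface's placement unique — this is what licenses the gold-recovery
grounding tests. The quality-by-part grid is partitioned between the two
two-token surface orientations so no two dictionary surfaces share a word
token set; otherwise the order-insensitive Dice reranker could tie an
exact surface match against its own reversal.

What the generator deliberately does **not** emulate: real clinical
language (abbreviations, misspellings, inconsistent offsets), mentions
whose surfaces are not dictionary terms, semantic coordination requiring
number resolution ("3rd and 4th digits"), and discontinuous normal
findings (normal findings are realized as a negation cue preceding the
surface, with the gold span covering the surface only). Passing the
synthetic suites therefore establishes correctness of the machinery —
parsing, grounding geometry, scoring algebra, calibration — not
extraction quality on real reports, which is a property of the trained
backend plugged into the contracts.

## Numerical and degenerate-input conventions

- Confusion counts with zero denominators yield P = R = F1 = 0.
- Candidate scores are clamped to `[-1, 1]` against floating-point drift;
  encoder self-similarity is asserted to 1 only within numeric tolerance.
- An empty target decodes to zero mentions; a mention-less observation
  encodes to an empty string; an empty observation list yields an empty
  prediction corpus.
- Empty dictionaries are an error (the pipeline is unusable without one);
  empty mention surfaces are an error at every entry point.
- The low-rank merge validates shape conformity (`ncol(B) == nrow(A)`,
  rank at most `min(d, k)`) and reads the `alpha/r` constant as the scale
  applied to `B %*% A` — the only dimensionally coherent reading.
- Corpus readers run strict by default (row-level errors with row
  numbers); a lenient mode skips and warns, since source corpora are known
  to contain occasional offset inconsistencies.

## Problem sizes used by the test suite

The suites run at desk scale, chosen to finish in a couple of minutes
while leaving the statistical checks sharp: grounding oracle equivalence
on 80–150 random texts of at most 12 tokens; evaluation oracle equivalence
on 200 seeded perturbation corpora of 4 observations; round-trip identity
on a 1000-observation corpus; calibration intervals on a
2000-observation corpus; exact-surface normalization over a 200-identifier
dictionary (600 surfaces). The acceptance script mirrors these sizes.

## Known limitations

- The grounding token-run model cannot place a surface whose fragments
  split inside a text token, and morphological variants ("thumb" vs
  "thumbs") do not match; the fallbacks cover case and punctuation only.
- Greedy one-to-one matching is not maximum matching; on adversarial
  overlap patterns it can undercount true positives relative to an optimal
  assignment. It is deterministic and order-stable, which the evaluation
  contract values more.
- The reference encoder and reranker are lexical; they cannot resolve
  synonymy that shares no character n-grams or tokens ("white plaque
  under the tongue" vs "Oral leukoplakia"). Production use is expected to
  plug trained models into the encoder/reranker contracts.
- The stub backend cannot emit discontinuous surfaces, which is precisely
  why the disjoint-only stratum exists in its evaluation output.
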