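---
title: "Segmentation Synonym Sentence Synthesis: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmentation Synonym Sentence Synthesis: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssss)
```

## The problem

Clinical named-entity recognition on Chinese electronic medical records is
dominated by two data problems: annotated corpora are small (privacy and
annotation cost), and entity mentions are wildly non-uniform — the same
exam can be written 盆腔MRI or 盆腔核磁共振检查, the same symptom 头昏 or
头晕. A tagger trained on one spelling routinely misses the others. Framed
in terms of the training set, the failures concentrate in test mentions
whose `(surface, type)` pair occurred zero times (*unknown*) or fewer than
5 times (*low-frequency*) in training.

Segmentation Synonym Sentence Synthesis (SSSS) manufactures exactly those
missing spellings. It is a label-preserving data augmentation: every
synthesized sentence keeps the entity count, types, and context of its
parent, so annotation effort is reused rather than redone.

## The procedure

For a sentence with entity spans `(start, end, type)` over 0-based
half-open character offsets:

1. **Segment** each entity surface into "simple words" with
   `segment_text()`: greedy forward maximum matching against a word list,
   falling back to single characters, with ASCII letter/digit runs (`MRI`,
   `3.5`) kept atomic. The built-in segmenter is deliberately
   deterministic — a pure function of `(text, lexicon)` — so results are
   reproducible without an external statistical model; `as_segmenter()`
   wraps a production segmenter (e.g. a jieba port) under a concatenation
   contract when parity with a deployed system matters.
2. **Search synonyms** for each segment with `find_synonyms()`. A headword
   query returns its lexicon group. A query absent from the lexicon is
   located by Levenshtein edit distance: every headword within `max_dist`
   edits contributes itself and its group. Candidates are ranked by edit
   distance to the query, then cosine similarity of embedding vectors when
   available, then lexicographically, and truncated to `top_k`.
3. **Synthesize**: each accepted substitution rewrites the sentence text
   and re-projects every span (`project_span()`): the containing span
   absorbs the length difference `Δ = len(replacement) − len(region)`,
   later spans shift by `Δ`, earlier spans are untouched, and all surfaces
   are re-sliced and re-validated.

`augment_corpus()` applies this to every sentence and returns originals
plus variants with full provenance (`parent_id`, substitution log) and a
pre/post expansion report.

## Tunable parameters

| Parameter | Default | Meaning |
| --- | --- | --- |
| `min_segments` | 1 | entity eligibility: minimum number of simple words |
| `top_k` | 5 | synonym candidates kept per segment |
| `max_dist` | 2 | edit-distance radius for locating lexicon entries |
| `policy` | `"single"` | one substitution per variant, or per-entity cross products |
| `max_variants` | `Inf` | per-sentence cap, enforced by seeded uniform sampling |
| `dedupe` | `TRUE` | drop variants equal to the original or to each other |
| `substitute_context` | `FALSE` | allow substitutions outside entity spans |
| `seed` | 42 | drives all sampling |

Points where the design was genuinely open, and what this package chose:

* **Eligibility threshold.** A common formulation restricts synonym
  expansion to compound mentions (more than two simple words), yet the
  canonical worked examples substitute single-word mentions (头昏 → 头晕).
  The default is therefore `min_segments = 1` — every entity is eligible —
  which reproduces all worked substitutions; the threshold remains a
  configuration knob for the restrictive reading.
* **Context substitution.** Replacing vocabulary in the non-entity context
  would diversify sentences further but risks silently corrupting unlabeled
  mentions; the default substitutes only inside entity spans
  (`substitute_context = FALSE`).
* **Emission policy.** `"single"` emits one variant per
  (entity, segment, candidate) triple, keeping variant counts linear and
  analyzable (the count is exactly `Σᵢ Σⱼ kᵢⱼ` for segment synonym counts
  `kᵢⱼ`); `"cross"` additionally emits per-entity combinations of segment
  choices. Large corpus growth is achievable either way; single is the
  default because its accounting is closed-form.
* **Edit distance: filter vs rank.** The lexicon query uses edit distance
  both to *locate* entries for unknown queries (radius `max_dist`) and to
  *rank* all candidates; ranking ties are broken by embedding similarity,
  then lexicographically, so results are total-ordered and deterministic.
  A near-headword is additionally required to be nearer than the query's
  own length — a distance-2 "match" on a 2-character query shares no
  content and would make every short word a synonym of every other.
* **Inherited labels.** Variants inherit the parent's entity types
  unchanged; no re-annotation step exists, which is safe precisely because
  substitutions stay inside typed spans.

## Numerical and representational choices

* **Offsets** are 0-based half-open everywhere (the JSONL interchange
  convention); inclusive-end corpora are converted once at the reader
  boundary (`span_convention = "inclusive"`). Surfaces are always
  re-sliced and checked after any offset arithmetic, so a projection bug
  cannot survive validation silently.
* **Sentence splitting** keeps the separator (default 。) attached to the
  preceding sentence, making character conservation exact; an entity
  straddling a period is a hard error by default (well-formed corpora have
  none) with a `keep-record` fallback. A trailing empty segment is dropped.
* **BIO conversion** is strict: an orphan `I-` tag is an error unless
  `strict = FALSE` requests the conventional repair (orphan `I` → `B`).
* **Levenshtein distance** is delegated to base R's `adist()` (unit-cost,
  per code point); the test suite pins it against a naive recursive oracle,
  exhaustively over the full universe of strings up to length 6 on a
  4-symbol alphabet.
* **Determinism.** Corpus augmentation is byte-reproducible: the
  `max_variants` cap samples from a per-sentence RNG stream derived from
  `(seed, sentence ordinal)`, so capping one sentence cannot shift the
  draws of another.
* **Degenerate inputs.** Empty corpora, empty lexicons, entities with no
  candidates, and empty prediction sets are all defined, not errors:
  augmentation returns the originals (factor 1), and precision is flagged
  `NA` ("undefined") when there are no predictions to judge, with F1 falling
  back to 0.

## Evaluation

Scoring is strict entity-level matching: a prediction is correct only if
start, end and type all equal an unmatched gold span; matching is
one-to-one. Metrics are micro-averaged percentages, overall and per type
(per-type counts sum to the overall counts by construction).

Frequency stratification assigns each gold test entity to *unknown*
(training frequency 0), *low* (1 to threshold−1, default threshold 5) or
*high* (≥ threshold) by its exact `(surface, type)` count over training
annotations; `key = "surface"` switches to surface-only counting. In
stratified scoring, a matched prediction is credited to its gold entity's
stratum and an unmatched gold entity debited there; an *unmatched
prediction* has no gold stratum, so it is assigned by its own
`(surface, type)` training frequency. That FP rule is a package decision —
strict-match evaluations rarely state one — and is therefore isolated in
`score_by_stratum()` where it can be changed in one place.

## The synthetic benchmark

`synthetic_spec()`/`generate_corpus()` produce a hermetic corpus so every
claim in the test suite is checkable without licensed clinical data. The
default specification emulates the *structure* of clinical NER corpora:

* five entity types with the characteristic imbalance — exam/anatomy
  mentions frequent, disease/treatment scarce;
* template sentences (患者…处不适。, 行…检查。, …) with one typed slot,
  packed three sentences to a record so sentence splitting is exercised;
* exact per-surface frequency plans (realized counts equal the plan, not
  in expectation), including surfaces placed at the stratum boundaries
  (frequency 4 vs 5);
* a synonym lexicon whose groups connect training surfaces to reserved
  variant surfaces that occur *only* in the test set — the constructor
  verifies each reserved surface is reachable from a training surface by
  one SSSS substitution;
* a compound mention (盆腔MRI) whose variant arises from segment-level
  substitution rather than whole-mention lookup.

On this benchmark the gazetteer reference tagger — longest-match dictionary
lookup over training surfaces, majority-voted types — shows the
augmentation effect mechanically: without augmentation its unknown-stratum
recall is exactly 0 (the surfaces are absent from the dictionary) and
partial matches inside unknown mentions create false positives that
depress low-stratum precision; with SSSS augmentation the synthesized
surfaces enter the dictionary, unknown recall reaches 100% and
low-frequency F1 rises strictly (60% → 100% under the default plan). The
gazetteer is a deliberate stand-in for neural taggers: it makes the
benefit checkable at desk scale, but it has no generalization of its own,
so the benchmark demonstrates the *mechanism*, not the magnitude, of gains
a learned model would show.

What the generator does **not** emulate: real clinical narrative (surfaces
are realistic but sentences are templated), annotation noise, boundary
ambiguity, nested or discontinuous mentions, segmentation ambiguity, and
the coverage limits of a real synonym database. Passing tests therefore
certify the algorithmic contracts — span arithmetic, determinism, counting
identities, stratification — not clinical-grade recognition quality.

## Problem sizes in the test suite

The suite verifies the round-trip identity on 10,000 property-generated
sentences, scorer agreement with a brute-force oracle on 500 random
corpora (plus per-stratum agreement), the closed-form variant count on 200
random synthesis fixtures, and the edit-distance oracle on all ~29.8
million ordered string pairs up to length 6 over a 4-symbol alphabet
(evaluated bottom-up); these sizes keep the full suite to a few minutes on
one CPU.

## Known limitations

* No grammaticality or semantic-equivalence checking of synthesized
  sentences; a synonym that is valid in isolation may read awkwardly in
  context. Substituted text is validated structurally, not linguistically.
* Only contiguous, non-nested entities in the BIO scheme are supported
  (no BIOES/BILOU, no discontinuous mentions).
* Greedy forward maximum matching cannot resolve genuine segmentation
  ambiguity; plug in a statistical segmenter via `as_segmenter()` when
  that matters, and record its version — segmenter and synonym-database
  versions both change augmentation output.
* The gazetteer tagger is a diagnostic baseline, not a competitive model;
  the `as_tagger()` contract is the intended attachment point for neural
  sequence labelers.
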