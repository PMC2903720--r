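---
title: "Recommending ontologies by annotation scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recommending ontologies by annotation scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OntoRecommender)
```

# The problem

Given a text corpus or a keyword list, which of the ontologies in a
repository should be used to annotate it? OntoRecommender treats this as
an annotation-scoring problem: annotate the input with a dictionary
compiled from all candidate ontologies, weight each annotation by how it
arose, and rank ontologies by aggregate weight. Two heuristics map onto
the questions users actually ask:

* **CR + score** — which ontologies offer maximum coverage of the data?
* **CR+M + score** — which ontologies are the *reference* ontologies for
  the data, i.e. the common targets of cross-ontology mappings?
* **CR + normalized score** — which small ontologies are specialized for
  the data?

# The model

## Direct annotations

The dictionary holds one entry per concept preferred name and per
synonym, normalized by case-folding and whitespace collapsing. Matching
is purely syntactic: a dictionary term matches wherever its token
sequence occurs in the input, aligned to token boundaries on both ends
(tokens are maximal runs of Unicode letters/digits, so "eye" never fires
inside "dyeing"). A window with no exact dictionary match is retried
with a trailing "s" stripped from its tokens — naive English plural
folding, enough for "melanocytes" to reach *Melanocyte*; tokens of three
characters or fewer, and tokens ending in "ss", are never stripped, so
"mass" is not folded to "mas". Every occurrence of a term annotates once
per matching entry, so a term shared by two ontologies credits both.

Three filters keep the dictionary sane, mirroring the annotation
service's standard parameters:

* `minTermSize = 3` — normalized terms shorter than 3 characters are
  excluded (they are almost always abbreviations that over-match);
* a fixed ~60-word English stopword list (shipped as a plain-text
  resource, overridable) blocks *single-token* entries only — a
  multi-word term such as "state of the art" is kept;
* `longestOnly` — when on, an annotation whose span is strictly
  contained in another annotation's span is suppressed, regardless of
  which ontology produced either. Equal spans never suppress each other:
  "longest" means strict containment, so overlapping-but-not-nested and
  tied matches all survive. The switch defaults to on for keyword input
  (a keyword list is a set of deliberate phrases; partial hits are
  noise) and off for corpus input (running prose rewards every match).

## Expanded annotations

With the CR+M method, each direct annotation on concept *c* also
annotates every concept *c′* reachable by one directed point-to-point
mapping *c → c′*, with the seed's span. Expansion is deliberately
single-hop: mappings of mapped concepts are not followed, because
chaining through hub ontologies would double-count them, and mapped
annotations never re-seed other expansions. When the mapped target is
itself directly matched on the same span, no expansion is emitted — the
direct annotation already carries the higher weight under the default
table, and keeping the direct one preserves the invariant that CR+M
only ever adds to CR. (Under a custom table where the mapped weight
exceeded the direct weights this rule degenerates to "keep the direct
annotation"; we accept that in exchange for monotonicity.)

An `is_a` expansion is implemented with the same span-conservation and
deduplication rules (each ancestor annotated once per span, at its
minimal edge distance, breadth-first), but recommendation runs do not
use it: ancestor credit rewards deep hierarchies rather than fit to the
input, so only mapping expansion feeds rankings.

## Weights and aggregation

| context                    | weight               |
|----------------------------|----------------------|
| preferred-name match       | 10                   |
| synonym match              | 8                    |
| mapping expansion          | 7                    |
| ancestor at level *n*      | ⌊1 + 10·e^(−0.2·n)⌋  |

The ancestor decay is floored *per annotation*, before summation: the
floor is what reproduces the tabulated example weights (9, 7, 4, 3, 1
at n = 1, 2, 5, 8, >12) — conventional rounding would give 8 at n = 2.
The weight is non-increasing in *n* and bounded in [1, 9] for n ≥ 1.
All weights are configurable (`weightTable()`, or the `preferred` /
`synonym` / `mapped` / `ancestor_*` keys of a run-configuration file);
the defaults above are asserted to be ordered preferred ≥ synonym ≥
mapped.

Per ontology, `score` is the sum of its annotations' weights and
`normalized score` divides by the ontology's *concept count* (not its
term count — synonyms make an ontology easier to hit, but they do not
make it bigger). Ontologies with no annotation are omitted rather than
reported as zero. Rankings sort by the chosen value descending, break
ties by ascending ontology id, and give tied values the smaller rank.
Scores are plain doubles; normalized scores are printed at 4 decimals
in the text/XML/cloud renderings, while the JSON rendering keeps full
precision so `parseRankingJSON(renderRanking(x, "json"))` is lossless.

```{r}
repo <- workedExampleRepository()
rankingEntries(recommend(workedExampleText(), repo,
                         runConfig(method = "CR_M")))
```

# Design choices where the design was open

* **Span convention.** 0-based half-open character offsets internally
  (`start`, `end` in the annotation frame); the surface slice is always
  `substr(text, start + 1, end)`.
* **Mapping directionality.** One mapping row is one directed link;
  symmetry is never assumed. The worked-example fixture encodes exactly
  the two directions its annotation set needs (NCI melanocyte → FMA,
  FMA eye → NCI).
* **No implicit concept unification.** Two concepts sharing a
  CUI-like local id are still distinct; cross-ontology identity exists
  only where a mapping row says so. This keeps behaviour reproducible
  from explicit fixtures.
* **Fixture naming.** Two worked-example concepts carry preferred names
  that do not occur in the example sentence (NCI "Eye structure", FMA
  "Epidermal melanocyte"). Both are required for the pinned totals:
  each of those concepts must be credited through its mapping (weight
  7), not by a direct match (weight 10).
* **Duplicate ontologies** (the same ontology loaded from two sources)
  are not merged; both rank. Keyword input splits on newlines only, so
  commas can appear inside a phrase.
* **Tag-cloud scaling** is linear min–max onto [1, 10]; when all
  selected values are equal every ontology gets weight 10.
* **Degenerate inputs.** Empty input text is an error; input with no
  dictionary hit is a warning plus an empty (but renderable) ranking;
  an empty mappings file is a no-op; mapping rows whose endpoints are
  not loaded are skipped with a counted warning, not an error.

# The synthetic generator

`generateRepository()` emulates the gross shape of a public ontology
repository at desk scale: a 47/36/17 small/medium/large mix (5–15,
20–50, 60–120 concepts — the real-world classes are <1K, 1–20K, >20K
concepts, scaled down so that a full property run takes seconds), every
preferred name and synonym a unique pronounceable token, `is_a` parents
drawn only among earlier concepts (acyclic by construction), and
mappings sampled toward a designated hub fraction at the configured
density with a 4× weaker non-hub baseline, reproducing the elevated
in-degree of reference terminologies. `generateCorpus()` samples terms
from one source ontology and interleaves noise tokens drawn from a
character alphabet disjoint from the vocabulary's, so noise can never
hit the dictionary. Everything is determined by the spec's seed.

What passing tests on this generator show — and what they do not: the
planted-source-recovery property (the corpus's source ontology ranks
first under CR + score in ≥ 95 of 100 seeded trials at 30 terms and 30%
noise) demonstrates that the pipeline's plumbing credits the right
ontology when terms are lexically unambiguous. Real ontologies share
terms, have skewed synonym counts and ambiguous strings; recovery rates
there would be lower and are not claimed. The matcher is separately
checked against a brute-force try-every-term-at-every-window oracle on
random texts, which *is* a faithful statement about matching semantics.

# Problem sizes used in the checks

The package's own verification runs at small, fixed sizes chosen to
exercise every code path: the matcher oracle on dozens of random
dictionary/text pairs (≤ 25 tokens, ≤ 8 terms), the CR ⊆ CR+M
monotonicity and score-conservation properties on 100 seeded 4-ontology
repositories, and recovery on 100 seeded 5-ontology repositories. The
worked example itself is 3 ontologies, 8 concepts, 2 mappings — small
enough to verify by hand, which is the point of pinning it.

# Known limitations

* Matching is syntactic only: no stemming beyond plural folding, no
  word-order variation, no disambiguation of ambiguous strings, one
  language (English tokenization assumptions live in the plural rule
  and stopword list only).
* OBO support is the term/synonym/is_a subset; OWL and RRF sources must
  be converted upstream. Relationship types other than `is_a` are
  ignored.
* Whether per-annotation flooring or post-sum flooring of the ancestor
  decay matches the original service is unknowable from its outputs;
  per-annotation flooring is pinned here and documented above.
* The normalized score divides by concept count, so a one-concept
  ontology that happens to match once ranks at the top of the
  normalized ranking — by design, but worth knowing before trusting
  that value on tiny ontologies.
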