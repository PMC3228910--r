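---
title: "Methods: typed co-occurrence mining from abstracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: typed co-occurrence mining from abstracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litcooc)
```

## Model and assumptions

litcooc mines candidate gene/protein interactions from abstract text by
dictionary lookup and positional co-occurrence analysis. It makes no attempt
at parsing, anaphora resolution or semantic-role labelling; the working
assumption is that in abstracts — dense, declarative prose — two entity
names sharing a sentence with an interaction trigger word usually do
describe a relation, and that position of the trigger word is a usable proxy
for how directly the sentence asserts it.

The unit of evidence is a *co-occurrence instance*: one (abstract, entity
pair) observation with a confidence type.

### The four confidence types

Within a sentence containing entities $a$ and $b$ (mention spans known):

* **Type 1** — an interaction term lies strictly *between* the closest
  mentions of $a$ and $b$: the span of the term is contained in
  $[\min(\mathrm{end}_a,\mathrm{end}_b),\ \max(\mathrm{start}_a,\mathrm{start}_b))$.
* **Type 2** — an interaction term occurs in the sentence but not between
  the names.
* **Type 3** — the entities share the sentence; no interaction term in it.
* **Type 4** — the pair co-occurs in the abstract but in no single
  sentence. Type 4 is emitted *only* for pairs with no co-sentential
  instance anywhere in that abstract, so an abstract never reports the same
  pair at both a sentence level and the abstract level.

Types are ordered by evidence strength, and every downstream filter is a
*threshold*: "type ≤ t". This makes the prediction sets nested, which the
test suite checks as a monotonicity property on random corpora.

### Complexity exclusion

A sentence mentioning **4 or more distinct entities** (distinct dictionary
keys, not raw mention count — `tau … tau` is one entity) produces no
sentence-level pairs. Enumerating all pairs of an entity list sentence
("A, B, C and D were assayed") floods the output with type-3 noise; the
paper-scale default threshold of 4 is exposed as `max_entities` in
`extract_sentence_pairs()` / `extract_cooccurrences()`. Excluded sentences
still count toward abstract-level type 4, and the evaluation bench can
stratify recall by this exclusion.

### Negation blindness

"A does not interact with B" is reported as type 1. This is by design and
regression-tested: the tool proposes candidate statements about a pair for
a human to read, and a negated interaction claim is still a highly relevant
statement. Users needing assertion polarity must post-process.

## Tagging

* **Matching** is case-insensitive and token-bounded: a dictionary surface
  matches only where not flanked by `[A-Za-z0-9]`, so `APP` does not match
  inside `APPLE`, but matches in `APP/PS1`. Whitespace inside multi-word
  surfaces is tolerant (`\s+`).
* **Overlaps** are resolved leftmost-longest; where an entity mention and an
  interaction term overlap, the entity wins and the term occurrence is
  discarded.
* **Ambiguity**: a surface mapping to several gene ids is tagged once and
  flagged `ambiguous`; network labels fall back to the raw term for
  ambiguous nodes rather than guessing a symbol.
* **Concepts** additionally tolerate a plural suffix (`s`/`es`), so
  `deposit` matches `deposits`.
* **Offsets** are 0-based, half-open (`[start, end)`), the
  standoff-annotation convention — chosen so `substr`-style arithmetic and
  span containment tests need no ±1 adjustments, and verified by round-trip
  tests.
* Titles are prepended to the abstract body before segmentation so
  title-only mentions are taggable.
* Sentence segmentation is rule-based — split after `[.!?]+` followed by
  whitespace and an uppercase letter or digit — with an abbreviation guard
  list (`e.g.`, `Fig.`, `et al.`, …) shipped in `inst/extdata` and
  user-extensible.

## Parameters and defaults

| Parameter | Default | Rationale |
|---|---|---|
| `max_entities` | 4 | complexity-exclusion threshold (see above) |
| `min_length` (lexicon) | 2 | 1-character surfaces are almost always false positives; dropped count reported |
| interaction terms | shipped list of ~30 verb lemmas with `-s`/`-ed`/nominal variants | editable plain-text file; `load_interaction_terms(path)` |
| concept suffix tolerance | `s`/`es` | covers common English plurals without stemming machinery |
| `network_filter(max_type)` | 4 | keep everything; tighten for precision |

## Evaluation protocol

Gold standards for literature mining are incomplete: the tool routinely
finds true interactions absent from the reference set. The bench therefore
uses a **pooled truth**: the filtered gold set (self-interactions and
non-gene symbols removed, with a filtering report) unioned with
expert-confirmed novel predictions on `(pmid, term1, term2)` keys. Recall
is measured against the pool; precision over all predictions at each type
threshold. `stratify_recall()` recomputes recall on *nested* strata —
all truths ⊇ both entities in dictionary ⊇ both detected in text ⊇ evidence
sentence not complexity-excluded — so dictionary gaps, tagging misses and
the complexity exclusion can each be priced separately. Expert validations
persist in a timestamped table; later verdicts supersede earlier ones and
same-timestamp conflicts are an error.

## What the fixture generator emulates

`generate_corpus()` writes a MEDLINE tagged-field corpus, a matching gene
lexicon, the shipped interaction-term list, a concept list and a truthful
gold table. Each planted pair gets its own abstract whose key sentence is
built from a template guaranteed to classify as the target type (templates
for types 2 and 3 deliberately use verbs absent from the interaction
dictionary). Complex sentences (4 fresh entities) and negated interaction
sentences can be added; distractor sentences provide realistic surroundings.
The generator emulates *structure* — typed co-occurrences, hubs, complexity,
negation — not linguistic realism; it exists so the pipeline's claims are
testable offline with exact expected outcomes. All randomness flows through
a single seed with RNG state save/restore, and equal seeds give
byte-identical files. `two_hub_config()` plants a 48-partner and an
11-partner hub plus a type-2 bridge, giving a network of known topology.

Problem sizes exercised in the tests: corpora of 2–60 abstracts, lexicons
up to ~130 surfaces, 100 random corpora for the monotonicity property;
runtimes are seconds.

## Design decisions on open points

* **Type 4 non-duplication** (no abstract-level echo of sentence-level
  pairs) keeps instance counts interpretable as independent evidence.
* **Distinct keys, not mentions**, for the complexity rule: repetition of
  one name does not make a sentence complex.
* **Case-insensitive matching** trades some false positives (gene symbols
  that are common words) for recall; the evaluation bench exists to measure
  that trade.
* **Gold flags are three-state** (`TRUE`/`FALSE`/`NA`); unknown flags are
  excluded from strata and counted, never silently assumed.
* **Novel confirmed truths** count as detected by construction in the
  stratified recall.

## Limitations

No parsing: directionality ("A inhibits B" vs "B inhibits A") is not
captured; edges are undirected. No anaphora ("it binds B") and no
cross-sentence coreference. Dictionary-bound recall: unknown synonyms are
invisible, which is exactly what the recall strata quantify. Sentence
segmentation is heuristic; abbreviation lists never cover everything.
Negation, speculation and citation of prior negative results are all
reported as positive co-occurrence evidence.
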