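---
title: "Methods: the matching cascade, its parameters, and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the matching cascade, its parameters, and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entnorm)
```

## The problem

Integrating oncology knowledge bases requires mapping free-form entity
names — drug names such as "Gleevec" or "STI-571", cancer types such as
"NSCLC" — onto stable identifiers in a reference vocabulary (ChEMBL
accessions for drugs, Disease Ontology terms for cancer types). Unlike
text-mining entity linking, the inputs here come from database columns, not
sentences: there is no surrounding context to disambiguate with, but there
are very many names, so the normalizer must be both accurate and fast.
`entnorm` implements a dictionary-based approach: all reference names and
synonyms are preprocessed and indexed once, and each query passes through a
cascade of matchers of increasing cost, stopping at the first success.

## Preprocessing

A name is canonicalized by transliterating Latin diacritics to ASCII,
lowercasing, and treating every run of non-alphanumeric characters as a
single token boundary. The canonical form is the token sequence joined by
single spaces; it is idempotent under re-preprocessing and invariant to
casing and punctuation. Two design choices deserve mention:

* **Punctuation splits tokens rather than vanishing in place**:
  "beta-blocker" becomes `beta blocker`, not `betablocker`. Splitting
  preserves the token structure the order-invariant and n-gram matchers
  rely on; joining would conflate hyphenation styles with genuine
  single-token names. The cost is that a query written solid
  ("betablocker") reaches the edit-distance step instead, where one space
  insertion (normalized distance 1/12) still recovers it.
* **Digits are token characters** ("her2"), because suffix digits are
  semantically load-bearing in gene and drug names.

## The cascade

1. **Exact** — hash lookup of the canonical text. Resolves the clean
   majority of queries in O(1).
2. **Token** — lookup of the sorted-token key, matching names that are word
   permutations of a dictionary name ("cancer, lung" → "lung cancer").
3. **N-gram** — containment in both directions with word n-grams (default
   bigrams): a query n-gram equal to a reference name (or a permutation of
   it) catches over-specified queries ("invasive ductal carcinoma of
   breast" → "ductal carcinoma"); the full query equal to one of a
   reference name's n-grams catches under-specified ones.
4. **Partial** — normalized Levenshtein distance, `lev(a, b) / max(|a|,
   |b|)`, computed against every reference name on the space-joined
   canonical text; entries attaining the minimum distance are returned if
   that minimum is at or below the threshold.

Steps run strictly in this order; token precedes n-gram because it is the
stricter relation. A later step never runs once an earlier step has
matched, which is both the performance argument (the full-dictionary scan
of step 4 only pays for queries nothing cheaper could resolve) and a
semantic one: an exact hit should never be diluted with fuzzy candidates.
The per-step attempt counters exposed through `time_batch()` make the
short-circuiting observable.

## Parameters

* `partial_threshold` (default **0.2**): the maximum fraction of the longer
  name's characters that may differ. Moderate thresholds in the 0.2–0.3
  range add recall at little precision cost; beyond that, the number of
  candidate identifiers returned per query grows and inspection burden with
  it. The comparison is inclusive (`<= 0.2`); inclusivity is unobservable
  for generic inputs but fixed for determinism.
* `ngram_size` (default **2**): word bigrams. Unigrams over-match (any
  shared word), longer grams under-match for the 1–4-token names typical of
  drug and cancer vocabularies.
* Step switches `enable_token` / `enable_ngram` / `enable_partial` support
  ablation studies; exact matching always runs.

Two genuinely open design points were closed as follows. The partial step
returns **only the minimum-distance entries** rather than everything under
the threshold, minimizing the identifier set a curator must review; ties
return all co-minimal entries. And the normalization denominator is the
**longer** string's length, the standard choice that bounds the ratio to
[0, 1].

## Worked example

```{r example}
pairs <- parse_synonym_table(system.file("extdata", "drug_synonyms.tsv",
                                         package = "entnorm"))
dict <- build_dictionary(pairs)
normalize_name("GLEEVEC", dict)
normalize_name("imatinab", dict)   # one typo: recovered by the partial step
```

## The synthetic benchmark

Real gold standards for this task are curated lists of (query, identifier)
pairs; they are not redistributable here, so the package generates its own
with *known* ground truth. `make_dictionary()` draws names of 1–4 tokens
from a seeded artificial vocabulary, rejection-sampling until three
separation constraints hold: canonical texts pairwise distinct, sorted
token keys pairwise distinct (no entry is a word permutation of another),
and pairwise normalized edit distance above twice the partial threshold.
Separation makes every perturbed query's nearest entry unique, so each
gold record has a well-defined expected identifier *and* expected cascade
step.

`make_gold()` then perturbs dictionary names according to a mix of kinds,
each engineered to be recoverable at exactly one step: `identity` and
`case_punct` (case flips plus punctuation noise that preprocessing
removes) at step exact; `token_shuffle` (non-identity token permutation) at
step token; `embed_in_phrase` (the name embedded among out-of-vocabulary
context words; sources are restricted to names with exactly `ngram_size`
tokens so the n-gram window can contain them) at step ngram; `char_edit`
(character edits bounded by the threshold, rejection-sampled so no earlier
step can see them and no other entry is at least as close) at step partial;
and `unmatchable` (out-of-vocabulary strings beyond twice the threshold
from everything) at no step. Context and unmatchable tokens use a consonant
alphabet disjoint from the dictionary vocabulary, so accidental collisions
are impossible by construction, not by luck.

What a green benchmark does and does not establish: it shows the cascade
recovers each perturbation class at the intended step with perfect
precision/recall *under the separation assumption*. Real dictionaries
violate that assumption — near-duplicate names, shared synonyms across
identifiers, ambiguous abbreviations — which is precisely why published
F1 on real gold standards sits below 1 while this benchmark sits at 1. The
generator emulates the *mechanisms* of name variation (casing, punctuation,
word order, over-specification, typos), not the empirical frequency
distribution of any particular curated database.

Default generator settings: 1–4 tokens per name, vocabulary of 200 words,
one character edit per `char_edit` record, and a mix of 20% identity, 20%
case/punctuation, 20% token shuffle, 10% embedding, 20% character edits,
10% unmatchable — clean-majority with a substantial fuzzy tail, mirroring
the structure of curated-database gold standards where most names resolve
exactly and negatives are a minority whose ratio is acknowledged to be
somewhat arbitrary.

## Evaluation

`score()` uses strict counting: on a positive record a wrong non-empty
prediction counts as a false positive *and* a false negative (it both
pollutes the output and misses the truth); an empty prediction is a false
negative only. Negative records yield a true negative on empty output,
otherwise a false positive. Zero-denominator conventions define precision,
recall and F1 as 0. A multi-identifier prediction containing the expected
identifier is a true positive; `mean_prediction_size` reports the
inspection burden that tolerance hides. `bootstrap_metrics()` resamples
records with replacement (default 100 replicates) and reports means with
*population* standard deviations, matching the usual error-bar convention
for benchmark plots; it is seed-deterministic and restores the caller's RNG
state.

## Numerical choices and degenerate inputs

* Levenshtein is a two-row dynamic program in C++ (Rcpp); the test suite
  checks it exhaustively against `utils::adist` on all ~1.2M string pairs
  of length ≤ 6 over a three-letter alphabet and against a memoized
  recursive oracle on seeded random pairs.
* `normalized_edit_distance("", "")` is an error (undefined ratio); an
  empty canonical query is simply unmatched everywhere else.
* Names canonicalizing to the empty string are dropped at dictionary build
  with a counted warning; an all-empty dictionary is an error.
* Distance ties in the partial step return all co-minimal entries; no
  arbitrary first-wins tie-break.
* The subtree filter follows `is_a` edges only and drops obsolete terms,
  the conventional reading of "the cancer subtree under DOID:162";
  `relationship:` edges such as `part_of` are ignored.
* All synonym scopes (EXACT/RELATED/NARROW/BROAD) load by default, with an
  option to restrict, since reference sources differ in how they use
  scopes.

## Known limitations

* The partial step is a linear scan; no pruning index (BK-tree, length
  filtering) is implemented. For dictionaries of ChEMBL scale this is the
  dominant cost on unmatched queries.
* No abbreviation expansion, stemming, or semantic matching: "AML" matches
  only if the dictionary lists it as a synonym.
* Identifier ambiguity is surfaced, not resolved: a surface form mapping to
  several identifiers returns them all.
* The synthetic benchmark's separation guarantee is an idealization; it
  bounds what its perfect scores can claim about real data.
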