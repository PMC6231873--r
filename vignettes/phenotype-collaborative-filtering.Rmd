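---
title: "Collaborative filtering on heterogeneous phenotype profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collaborative filtering on heterogeneous phenotype profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarecf)
```

## The problem and the model

Rare-disease diagnosis is, at its core, a stratification problem: a new
patient should be grouped with previously diagnosed patients whose
phenotypes look alike. `rarecf` casts this as user-based collaborative
filtering over *binary* phenotype profiles. An entity — a patient from an
EMR cohort, or a merged per-disease literature document — is a set of
phenotype term ids plus exactly one disease label. The model makes no use
of phenotype frequency, severity or onset: presence/absence only. That is
an assumption, not an approximation — the upstream annotation processes
that produce such profiles (concept extraction from notes, predication
extraction from abstracts) emit mentions, and mention counts are too
biased across sources to be commensurable.

Two further assumptions matter. First, *single-label supervision*: every
profile carries one diagnosis, and multi-label patients are rejected at
ingest. Second, *exchangeability of sources downstream*: once a literature
document is merged and (optionally) pruned, the recommender treats it
exactly like a patient. The fusion strategies differ only in which
profiles exist, never in how they are weighted.

## Similarity measures

Four measures are implemented over the 2×2 contingency table of two sets
(`c` shared, `|P_m|`, `|P_n|` sizes, `N` phenotype universe):
Tanimoto `c/(|P_m|+|P_n|-c)`, overlap `c/min`, Fager–McGowan
`c/sqrt(|P_m||P_n|) - 1/(2 sqrt(max))`, and a log-likelihood-ratio
similarity `1 - 1/(1 + G²)` built on Dunning's G² statistic with
zero-count cells contributing nothing.

Design notes:

* **LL normalization.** G² is unbounded, so it is mapped to [0, 1) by
  `1 - 1/(1+G²)`. This keeps the TPN threshold grid meaningful for all
  four measures (thresholds for LL end up in the same 0–1 range as the
  bounded measures) and makes "exact independence" score exactly 0.
* **LL universe.** `N` is the number of distinct phenotypes in the
  training table, fixed when the model is built. A held-out query can
  legitimately carry phenotypes the training table has never seen; the
  scoring call enlarges `N` by the number of novel query phenotypes so
  the contingency table stays well-formed. The alternative — erroring on
  novel phenotypes — would make every prospective evaluation fragile.
* **Fager–McGowan penalty.** The chance-correction denominator uses the
  *larger* set (the classical form). The choice is isolated in one
  function should a variant be needed.
* **Empty sets.** Every measure returns 0 when an operand is empty.
  Ingest guarantees non-empty profiles, so this is a total-function
  convention that keeps `NaN` out of downstream arithmetic, not a
  modeling statement.

## Neighborhoods and aggregation

The score map for a query is sorted by descending similarity with ties
broken by ascending entity id (radix order, so the sort is
locale-independent and reproducible). KNN takes the first `min(k, n)`
entries — ties at the k-th position are resolved by that same id order and
never expand the neighborhood. TPN keeps scores *strictly* above `t`;
boundary equality excludes.

Neighbor labels become disease scores by a normalized
similarity-weighted vote: `score(d)` is the sum of similarities of
selected neighbors labeled `d`, divided by the sum over all selected
neighbors. Two conventions make this total:

* Negative similarities (possible only for Fager–McGowan) are clamped to
  zero as vote weights — a neighbor judged *less similar than chance*
  should not cast a negative vote for its own diagnosis.
* If every selected neighbor has weight 0 (e.g. a disjoint KNN
  neighborhood), the vote falls back to uniform over the selected
  neighbors, so KNN still returns `k` candidates instead of `0/0`.

An empty neighborhood (TPN threshold above all scores) yields an empty
recommendation, and `predict_top1()` returns `NA`.

## Parameter tuning by RMSE

Binary diagnosis data has no explicit zero-ratings, so RMSE needs a
convention for the "absent" cells. The protocol here: leave-one-out over
evaluation patients; the predicted rating of the true diagnosis (target 1)
is its recommendation score, and for each patient
`negatives_per_positive = 4` diseases other than the truth are sampled
(seeded) as target-0 cells. The tuner evaluates the whole grid — `k` in
1…15, `t` in 0.05…0.95 by 0.05 by default — against the *same* split and
the *same* sampled negatives, computing each query's score map once and
reusing it across the grid, and returns the first argmin. The sampling
seed is recorded in the tuning result's inputs, so any curve can be
regenerated exactly.

## Fusion

Predications are filtered to phenotype–disease pairs: a triple survives
iff exactly one side maps (by normalized name or synonym — lowercase,
trimmed, internal whitespace collapsed; no stemming) into the phenotype
vocabulary and the other into the disease vocabulary. Same-vocabulary
pairs (disease–disease, phenotype–phenotype) and unmapped terms are
dropped and counted. Surviving triples are merged into one profile per
disease (`LIT::<disease_id>`), since individual publications typically
assert a single pair and only the union carries evidence.

`EMR+L` concatenates and permutes storage order under a seed; the
permutation is cosmetic (every downstream computation is order-invariant,
and a property test holds this). `EMR+PL` first removes every literature
(phenotype, disease) pair absent from the EMR pair set and drops
literature profiles left empty — the fused pair set therefore *equals*
the EMR pair set, which is the defining invariant of pruned fusion:
literature may reinforce EMR-attested associations but can never
introduce new ones. Pruning at pair granularity (not whole profiles) is
what makes that invariant exact, and pruning is idempotent.

The minimum-support filter removes diseases with fewer than
`min_patients` EMR-source profiles (2 by default for recommendation
cohorts, 3 for per-disease prediction tables), taking literature profiles
of removed diseases with them.

## Disease matching and evaluation

Three relaxations of "predicted disease counts as correct": exact
normalized-name/synonym match (**string**), shared flat concept key
(**concept** — a deliberate stand-in for ontology-level equivalence,
expressing exactly the pairwise judgments a semantic hierarchy would
yield without shipping one), and intersecting category sets
(**category**; diseases may hold several categories, and matching is
reflexive and symmetric but intentionally not transitive).

Metrics:

* **Pooled PR curve / PRAUC**: all (query, candidate) pairs pooled,
  swept by descending score threshold; PRAUC is the trapezoid over the
  achieved recall points with a flat anchor at recall 0 carrying the
  first point's precision. The anchor makes a perfect ranking integrate
  to exactly 1 and keeps regression values stable; no other
  interpolation is applied.
* **MAP**: per query, the mean of precision-at-rank over ranks of
  retrieved relevant items, 0 when none is retrieved; averaged over all
  queries (queries with empty recommendations count as 0 via the
  `n_queries` argument).
* **Per-disease P/R/F and macro-F**: for disease `d`, TP are patients of
  `d` predicted correctly *under the criterion*, FN patients of `d`
  predicted wrongly, FP predictions *of `d` by id* that are wrong.
  Attributing FP by predicted id (rather than by criterion match) is
  deliberate: it is the standard confusion-matrix reading, and it makes
  every cell — hence macro-F — provably non-decreasing as the criterion
  relaxes on vocabularies whose match sets nest. Zero-denominator cells
  report 0.

One nuance worth stating: pooled PRAUC is *not* exactly monotone under
criterion relaxation, because relaxation also grows the recall
denominator; dips are vanishing (observed ~0.002 on fixtures where
string matching was already perfect) but real, so only MAP and macro-F
carry strict monotonicity guarantees in the test suite.

## The synthetic benchmark

The generator emulates the statistical skeleton the method assumes:

* Each disease gets a `signature_size`-phenotype signature laid out along
  a shared phenotype axis; `signature_overlap` slides consecutive
  signatures into each other (0 = disjoint partition), which is the
  difficulty dial — overlapping signatures emulate diseases lacking a
  unique phenotypic pattern.
* Patients draw their signature, lose each phenotype with probability
  `phenotype_dropout`, gain `noise_phenotypes_per_patient` off-signature
  terms, and are resampled if empty. Defaults (10 diseases × 20
  patients, 8-term signatures, dropout 0.1, 1 noise term) define the
  reference parameter-recovery benchmark.
* Literature documents each assert one predication — signature-true with
  probability `lit_fidelity`, random otherwise — plus a `decoy_fraction`
  of same-vocabulary predications to exercise the filter. One pair per
  document is the realistic regime: it is what makes per-disease merging
  do actual work.
* Vocabularies are wired for the matching criteria: a
  `concept_twin_fraction` of diseases form adjacent pairs sharing a
  concept key and a category, and categories are assigned in contiguous
  blocks along the signature axis so phenotypically similar diseases
  co-categorize — the structure real category systems (a few dozen
  categories over thousands of diseases) exhibit, and the precondition
  for the monotone-relaxation properties above.

All generation is integer-seeded and byte-identical across runs; the
generator restores the caller's RNG state.

What the generator does *not* emulate: clinical-language annotation noise
(synonymy failures, negation, section structure), visit timelines,
per-patient phenotype-count heterogeneity beyond binomial dropout,
citation-count structure in the literature, and multi-label patients.
Passing benchmarks here therefore demonstrate correctness and qualitative
behavior of the *model*, not expected performance on real EMR corpora.

## Problem sizes and numerical choices

The test suite and the acceptance script run on deliberately small
corpora — up to ~500 entities, 10–40 tuning queries, grids of 15 (`k`)
and 19 (`t`) points — sizes at which every similarity, neighborhood and
metric can also be recomputed by brute-force oracles for comparison at
`1e-9` tolerance. The 24-group sweep (4 measures × 2 neighborhoods × 3
strategies) on such a corpus completes in well under a minute and is
serialized deterministically (`write_report()`), so two runs with the
same seed produce identical bytes.

Degenerate inputs are handled explicitly rather than by accident: empty
tables read/write as empty; empty queries and empty tuning grids are
usage errors; `G²` is clamped at 0 against floating-point drift;
`min(k, n)` truncation and strict `>` thresholding are exact.

## Limitations

* The recommender is purely phenotypic; genotype evidence and
  disease–gene structure are out of scope.
* Concept matching is equivalence-only; ancestor/descendant relations of
  a real semantic hierarchy are not traversed.
* Scores are normalized vote shares, not calibrated probabilities.
* Exhaustive neighbor search is O(n) per query — appropriate for
  cohort-scale tables, not for millions of profiles without blocking.
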