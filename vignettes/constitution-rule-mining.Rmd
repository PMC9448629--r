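---
title: "Constitution rule mining: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constitution rule mining: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcmrules)
```

## The problem

Traditional Chinese medicine assigns each patient one of nine constitutions
(BC, YADC, YIDC, QDC, QSC, PDC, DHC, BSC, ISC) from their symptom pattern,
and each constitution carries its own health-conditioning regimen. Given a
corpus of tokenized clinical records — symptom phrases, a primary
constitution label, regimen/disease/drug tokens — `tcmrules` mines the
association rules behind that assignment and uses them as a transparent
multi-class classifier and regimen recommender. Every prediction decomposes
into named rules with support and confidence, which is the point: clinical
users can audit why a record was classified.

## Transactions and the mining model

A record projects onto transactions in two ways for training: *symptoms ∪
{primary constitution}* (the classification view) and *{primary
constitution} ∪ regimen* (the recommendation view). Within a record items
form a set; across records transactions form a multiset, so two identical
records count twice toward support — standard market-basket semantics.
Secondary constitution labels are excluded by default (their role in mining
is genuinely ambiguous in the field's record model) and can be switched on
with `include_secondary = TRUE`.

Support is an **absolute count**, not a fraction, with default minimum 20.
That default follows the clinical judging standards, under which each
constitution has at least 20 distinct symptom items: a pattern that cannot
accumulate 20 supporting records has no standing as a constitution rule.
Confidence defaults to 0.6 — a deliberately conservative, *declared* value
(the method itself fixes none), recorded in every trained rule base's
parameter block.

## The partitioned miner and its exactness argument

The scalable path mirrors map-reduce FP-growth without a cluster:

1. contiguous horizontal shards (sizes within one; order preserved);
2. one global F-list (item, count) — counts summed across shards,
   thresholded, ordered by count descending with ties broken by token order
   so every shard sorts transactions identically;
3. per-shard local FP-trees mined independently — *all* local itemsets are
   kept, at local support floor 1;
4. balanced grouping: frequent items are dealt round-robin by F-list rank
   into 9 groups; the task for group *g* mines only itemsets whose
   least-frequent (rightmost in F-list order) item lies in *g*, so the 9
   tasks partition the itemset space;
5. merge: local counts are summed per itemset and the global threshold is
   applied.

Exactness follows from step 3: because no local count is discarded, the
merged count of any itemset is exactly its corpus support, so the final
thresholding is exact and the result is independent of the shard count, the
group count and the executor. This is tested (a) against a brute-force
subset-enumeration oracle on hundreds of random databases and (b) as an
invariance property on a 5,000-record synthetic corpus. The memory price of
the support-1 floor is bounded at desk scale (~10^6 local itemsets on the
5,000-record corpus) and the local miner is compiled (C++), while the
single-machine `fp_growth()` stays in readable R as the reference
implementation of the F-list / FP-tree / conditional-pattern-base
operations.

Executors are a contract, not an infrastructure: tasks are pure functions
of (shard, F-list, group), run either serially (the reference) or in forked
worker processes (`parallel::mclapply`). Nothing in the result may depend
on the choice, and the tests enforce that.

## Preprocessing

Two noise mechanisms are handled before mining:

* **Stop words** (articles, pronouns, auxiliaries, conjunctions — a
  plain-text list shipped in `inst/extdata/stopwords.txt`) are removed from
  symptom tokens only; constitution and regimen labels are controlled
  vocabulary and never filtered.
* **Shared symptoms**: a symptom occurring at least `min_occurrences = 2`
  times whose discriminability `max(per-class counts) / total` falls below
  `min_discriminability = 0.8` is deleted from every record. The rationale:
  a symptom spread evenly across constitutions carries no signal for
  telling them apart, and even a small number of such occurrences distorts
  confidence estimates. The threshold form (rather than a clustering-based
  outlier detector, which the field literature gestures at without
  specifying algorithm, feature space or criterion) was chosen because it
  is deterministic, idempotent and directly testable; both parameters are
  exposed. Records themselves are never deleted.

## Classification scoring

The mined literature describes classifying by each constitution's
"representative frequent items" but fixes no formula, so the scoring rule
is a declared design choice: **confidence sum** over matching rules,
`score(c) = Σ conf(r)` over stage-1 rules `r` with consequent `c` and
antecedent ⊆ presented symptoms. It is simple, auditable and *monotone* —
adding symptoms can only add matching rules, never reduce a score — which
the test suite asserts as a property. `max_confidence` and
`support_weighted` variants are available for comparison. Ties break by
label order. The multi-label cutoff (every constitution scoring at least
half the top score) reflects that patients may genuinely hold several
constitutions; 0.5 is a declared default, not an estimated one.

Stage 2 links the two rule bases on the shared constitution; the chain
score is the product of the two confidences. The alternative route —
re-mining joint symptom-and-regimen transactions (`projection = "full"`) —
is supported by the miner but chaining is the default, because it reuses
audited stage-1 rules and keeps the constitution explicit in every
recommendation.

## The synthetic world

No deposited constitution corpus exists, so the generator is the test
substrate, and its defaults are fixed once:

| parameter | default | why |
|---|---|---|
| prevalence | uniform over 9 | no credible published vector exists (the literature's "top three" percentages sum to ~100% over three of nine classes and cannot be a probability vector); a `paper_like` preset renormalizing 42.3/31.3/26.2 onto BC/DHC/ISC is provided as an analogy only |
| symptoms per constitution | 20 | the judging-standard floor of distinct symptom items per class |
| symptoms per record | 3–8 uniform | records sample a subset of the class profile; a handful of phrases per consultation is clinically typical |
| shared-symptom rate | 0.1 | one record in ten carries a cross-class symptom from the designated pool (the four phrases the judging tables duplicate across classes, including "pale red tongue") |
| stop-word rate | 0.1 | mild free-text contamination |
| label-noise rate | 0.05 | plausible clinician disagreement; regimens follow the *recorded* label, since treatment follows the assessment actually made |
| regimen items per class | 3 | deterministic class → regimen map; PDC's first item is the classical "eliminate phlegm and remove dampness" principle |

The generator is seed-deterministic (bit-identical corpora from identical
configs). What it does **not** emulate: real Chinese clinical text and
segmentation, demographics-conditioned regimens, co-occurring diseases and
drug prescriptions with realistic marginals, or class-imbalanced clinics. A
green test therefore establishes algorithmic correctness (exact mining,
rule recovery, metric identities) — not clinical validity on real records.

## Numerical and degenerate-input choices

* F-list ties break by ascending token order in the C locale (`radix`
  sort), making every ordering decision reproducible across platforms.
* Itemset keys are items sorted in the C locale joined by `"|"`; tokens may
  not contain `"|"` or `":"` (enforced at record validation).
* Metrics with zero denominators report 0 with an explicit
  `*_defined = FALSE` flag instead of raising, so fold aggregation never
  aborts; F1 is 0 whenever P + R = 0.
* Empty corpora: mining an empty database yields an empty itemset table;
  training on an empty corpus is an error; thresholds that exclude
  everything produce an empty rule base with a warning, not an error.
* Cross-validation folds are stratified by constitution by default
  (disable with `stratify = FALSE`); fold sizes are balanced within one
  both overall and per class, and the assignment is a pure function of
  (labels, k, seed).
* Metric percentages are rounded to two decimals for display only; stored
  values are raw doubles.

## Known limitations

* The classifier only uses rules whose full antecedent is present; partial
  antecedent matches contribute nothing. Rare symptom combinations below
  the support floor are invisible, so records whose symptoms are all rare
  receive an empty prediction (reported as `NA`, counted as a negative
  decision in evaluation).
* Confidence-sum scoring favors constitutions with larger mined rule
  inventories; on strongly imbalanced corpora the `support_weighted`
  variant may be preferable. No calibration of scores to probabilities is
  attempted.
* The shared-symptom filter assumes shared symptoms are *uninformative*;
  a symptom genuinely indicative of two related constitutions is removed
  with the noise.
* Tongue-image and pulse-signal modalities, and per-patient demographic
  tailoring of regimens, are out of scope: the record model is symptom
  tokens only.
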