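---
title: "Methods: k-mer embedding features, mRMR and incremental selection for m5C site analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: k-mer embedding features, mRMR and incremental selection for m5C site analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m5Cselect)
```

## The analysis in one paragraph

Each candidate 5-methylcytosine site is represented by a 41-nt window with
the cytosine at position 21 (20 nt of flank on each side). Windows are
encoded through a 4-mer embedding table into 1020 features with full
positional provenance, features are ranked by
minimum-redundancy–maximum-relevance (mRMR), ranked prefixes are evaluated
by incremental feature selection (IFS) under cross-validation, and the
optimum model's features are mapped back onto window positions. The point
of the exercise is two-fold: a predictive model, and — more importantly for
the biology — a per-position profile of where the discriminative sequence
signal sits relative to the site.

## Window model and encoding

A window of length $L = 41$ contains $L - k + 1 = 38$ k-mers for $k = 4$.
The centre position is C in *every* window (negatives are also cytosine
sites), so the four 4-mers covering position 21 (starts 18–21) are
constant-context and are discarded; the remaining 34 starts — 1–17 and
22–38 — are the feature "slots". Each slot contributes the full
$d = 30$-dimensional embedding vector of its 4-mer, giving
$34 \times 30 = 1020$ features.

**Feature ordering is slot-major** (all 30 components of slot 1, then slot
2, …), with slots in ascending start order. Nothing in the analysis forces
this choice — mRMR is invariant to column order up to tie-breaking — but
reported feature *indices* depend on it, so it is fixed and declared: the
feature id `s18d7` is component 7 of the 4-mer starting at window position
22 (the 18th valid start). Every feature carries a descriptor with its
slot, start, embedding component and the set of 4 covered positions;
descriptors are the bridge from model space back to sequence space.

Input handling follows the conventions of site-benchmark datasets:
sequences are uppercased and T→U transliterated before validation (these
datasets usually ship in the DNA alphabet), coordinates are 1-based and
inclusive everywhere, and the centre-is-C check is applied to both labels
by default (disable `center_check` for exploratory inputs). Embedding
tables are whitespace-separated text, one token and $d$ values per line,
with an optional word2vec-style `count dim` header auto-detected; a k-mer
missing from the table is an error by default, or a zero vector under the
`"zero"` policy — both behaviours exist because real tables occasionally
omit tokens while curated ones are complete.

## mRMR: discretization, mutual information, greedy ranking

Continuous features are discretized once, up front, into three states
around their own mean: $-1$ below $\mu - \alpha\sigma$, $+1$ above
$\mu + \alpha\sigma$, else $0$, with $\sigma$ the population standard
deviation and boundary values mapped to state 0. The default
$\alpha = 1.0$ mirrors the long-standing default of discretized-MI feature
ranking tools; because published analyses rarely pin this value, $\alpha$
is an explicit parameter. Class labels enter as a two-state variable and
are never discretized.

Mutual information is the plug-in estimate over empirical distributions,

$$\mathrm{MI}(x, y) \;=\; \sum_{a,b} p(a,b)\,
  \log_2 \frac{p(a,b)}{p(a)\,p(b)},$$

in bits; cells with $p(a,b) = 0$ contribute zero. The base is a pure
rescaling and does not affect the ranking; bits are used for
interpretability (`MI(x, x)` is the entropy of $x$, 1 bit for a balanced
binary variable).

The ranking is the greedy **difference** (MID) criterion: the first
feature maximizes relevance $\mathrm{MI}(f, c)$; each later pick maximizes
$\mathrm{MI}(f, c) - \tfrac{1}{|S|}\sum_{g \in S}\mathrm{MI}(f, g)$ over
the already-ranked set $S$. Pairwise feature–feature MI values are
accumulated incrementally (each remaining candidate adds one MI term per
step), so ranking $m$ of $p$ features costs $O(p\,m)$ MI evaluations.
Score ties are broken to the lowest feature index; "tie" means within
$10^{-12}$ bits, which makes the tie-break robust to floating-point
summation order — genuinely distinct empirical MI values on realistic
sample sizes differ by far more than that. The quotient (MIQ) criterion
and continuous-density MI estimators are deliberately out of scope.

The test suite checks this implementation against a brute-force greedy
oracle (independent MI route via the entropy decomposition, no caching) on
200 random instances, exact permutation equality.

## IFS, classifiers, and cross-validation

For each prefix size $s = 1, 2, \ldots$ of the ranked list, the top-$s$
features are evaluated by stratified $k$-fold cross-validation (default
10-fold) and the six measures SN, SP, ACC, MCC, precision and F1 are
recorded; the optimum model is the prefix with the highest MCC, ties to
the smallest prefix. MCC is the selection measure because it is the most
balanced single number on a 2×2 confusion table; all measures with a zero
denominator are defined as 0 (unit-tested convention).

Cross-validation design choices, all pinned and echoed in results
metadata:

* **Pooled confusion counts** across folds, not per-fold metric averaging:
  per-fold MCC on ~20-sample test folds is unstable, and pooling matches a
  single confusion matrix over the dataset.
* **Stratified, seeded folds.** Each class's shuffled samples are dealt
  onto consecutive fold ids, so folds stay as balanced as the counts allow
  and the $n_{\text{folds}} = n$ case degenerates to leave-one-out-like
  size-1 folds; any class with $\ge 2$ samples spans $\ge 2$ folds, so
  every training fold contains both classes.
* **Classifier families** and defaults: CART decision tree with the Gini
  index (rpart defaults), kNN with 5 neighbours, random forest with 100
  trees, SVM with RBF kernel and cost 1. These are the conventional
  defaults of each family's reference implementation, pinned explicitly.
* **Standardization** (training-fold mean/variance, applied to the test
  fold) precedes kNN and SVM fits — both are scale-sensitive — and is
  fitted per fold so no test-fold information leaks. Tree-based families
  consume raw values.
* **Determinism:** fold construction and any classifier randomness
  (random-forest bootstrap, kNN distance-tie voting) are seeded from the
  single CV seed, so identical inputs and seed give identical results for
  all four families.

The pipeline default evaluates prefixes up to `max_size = 50` with the
mRMR ranking depth matched to it; both are parameters, and evaluating
every prefix of the full 1020-feature ranking is a flag away. Fifty covers
the optimum region in the synthetic studies below while keeping a full
four-family run interactive on a laptop.

## Position-frequency profiles

Given the optimum model's features, each feature adds 1 to the count of
each of the 4 window positions its 4-mer covers — features are counted,
not weighted by score, because the question is *where* selected features
look, not how strongly. Two invariants pin the bookkeeping: total count
mass is $4 \times$ the number of selected features, and the centre
position's count is identically 0 under the default encoding (the
discarded-slots rule, verified end to end). Profiles are written as TSV
and as a bar chart.

## The synthetic-data generator

The generator emulates the structure of curated site benchmarks: balanced
positive/negative 41-nt windows, centre fixed to C, i.i.d. background
bases from a configurable composition (uniform by default), and motifs
planted at fixed positions with class-dependent probability. The default
motif — UCCA at positions 22–25, present in every positive and 5% of
negatives — mirrors the downstream tetramer reported for one writer
enzyme's targets; G-rich runs further downstream are equally plantable.
Negatives are drawn from the *same* background as positives, so any class
signal is attributable to the planted motifs by construction. Sample-count
defaults (120/120) mirror the human benchmark; the recovery studies use
100/100.

Seeding expands a single master seed per record, so record $i$ is stable
when counts before it change. Embedding tables come in two schemes:
`gaussian` (i.i.d. normal components) and `near_orthogonal` (seeded
rejection sampling of unit vectors until every pairwise $|\cos|$ is below
0.5), the latter guaranteeing distinct 4-mers are geometrically separable.
Rejection sampling is feasible at the default geometry (256 vectors in 30
dimensions) and errors informatively when the dimension is far too low for
the bound rather than degrading silently.

What the generator does **not** model: realistic genomic base composition
and CpG structure, redundancy between windows (real benchmarks are
deduplicated upstream at 70% similarity), and embeddings that reflect
actual sequence co-occurrence statistics. Passing recovery tests therefore
demonstrates that the machinery — encoding, ranking, selection,
back-mapping — recovers planted signal faithfully; it does not certify
performance on real data, which depends on the external dataset and the
published embedding table.

## Numerical choices and degenerate inputs

* Constant features discretize to all-zero states (MI 0) and rank last in
  practice; a constant appended to a ranking never changes smaller
  prefixes.
* Metric denominators of 0 give metric 0 (including MCC); all-zero or
  negative confusion tables are errors.
* Confusion counts are reals, not integers, so rate-scaled counts from
  published SN/SP rows of balanced benchmarks can be fed through the same
  closed forms (every metric is scale-invariant); derived values agree
  with printed tables to one unit in the third decimal — the printed
  inputs are themselves rounded to three decimals, which propagates up to
  half a unit into derived measures.
* Empty FASTA files yield empty record sets; malformed embedding rows,
  duplicate tokens, non-ACGU characters, wrong window lengths and non-C
  centres are all named, early errors.

## Known limitations

* The recovery studies run at 200 samples × 1020 features with ranking
  depth 10–50 — the package's chosen study size; mRMR on the full ranking
  of much larger feature spaces is $O(p\,m)$ MI evaluations and is the
  slow path.
* With a 5% motif background rate, negatives carrying the motif are
  feature-space-identical to positives, which caps attainable specificity:
  the expected ~5 carriers per 100 negatives bound pooled MCC near 0.95
  even for an oracle classifier, and kNN on near-orthogonal embeddings
  (where all distinct 4-mers are roughly equidistant) typically lands at
  MCC 0.88–0.93. The null-motif control keeps optimum MCC well below 0.5,
  confirming that prefix selection over 50 candidates does not manufacture
  signal on this sample size.
* Absolute benchmark performance on the external human/mouse datasets is
  not reproduced here: it requires the original data and the published
  embedding file. The metric closed forms, the encoding arithmetic, and
  internal consistency of the published rows are verified instead.
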