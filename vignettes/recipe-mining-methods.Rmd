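---
title: "Methods: specialty scoring, cuisine classification and nutrient clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: specialty scoring, cuisine classification and nutrient clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recipemine)
```

This vignette is the package's own account of its methods: the models and
their assumptions, the tunable parameters and why their defaults are what
they are, what the synthetic generator does and does not emulate, and the
design decisions taken where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The preprocessing model

User-uploaded ingredient lines mix synonyms, symbols, vague quantities and
garnishes. Preprocessing makes three kinds of decision per line:

**Canonicalization.** A line's raw name is stripped of punctuation,
bracket symbols and emoji, whitespace-squashed, lower-cased and
NFC-normalized, then matched *exactly* against a synonym lexicon. There is
no word segmentation and no fuzzy matching: ingredient fields are short
noun phrases, and an explicit lexicon keeps recall auditable — adding a
synonym can only ever keep more recipes (a monotonicity property the test
suite checks). Stop terms (cooking techniques such as "julienne",
appliances) and lexicon misses yield `NA`; the line is dropped and logged.

**Gram imputation** follows three rules, in deliberate correspondence with
how composition databases are used in practice:

* *specified* quantities with mass/volume units convert directly
  (ml is treated as g — density 1, adequate for the watery liquids that
  dominate recipe liquids);
* *piece-like* units ("a piece of", "carton", "slice") are resolved
  through a replacement unit table, optionally specialized per ingredient
  (a "piece" of tofu is heavier than a generic piece);
* *vague* quantities ("few", "appropriate", "少許", "適量" — the
  vocabulary is configurable) take the mean of that ingredient's
  *specified* gram amounts in the current corpus. The mean is computed
  before any imputation, so imputed values never feed back into the means.
  When an ingredient has no specified occurrence anywhere, a configurable
  default of 5 g applies — a typical seasoning amount, which is what vague
  quantities overwhelmingly describe.

**Decorative garnishes** (membership in the lexicon's decorative list) get
0 g and are excluded from nutrient totals. Membership is used rather than
a mass-fraction heuristic so that behaviour is deterministic and a reviewer
can point at the single line in the lexicon that caused an exclusion.

A recipe is excluded as `unrecognizable` when no canonical ingredient with
positive grams remains, and as `single_ingredient` when exactly one does —
one-ingredient "recipes" carry no combinatorial information for either
specialty scoring or classification. Conversion rates are reported per
category as `100 · after/before`, rounded **half-up** to one decimal.
Half-up is a deliberate choice: base R's banker's rounding produces
surprising reported percentages, and the reference table this mirrors is
itself not consistent with any single rounding rule (the shipped
`icook_reference_counts()` documents the discrepancies; the acceptance
test asserts our recomputed rates against independently hand-derived
values rather than against the inconsistent cells).

## 2. Specialty score

For ingredient $i$ and category $j$: $p_{ij} = r_{ij}/s_j$ (importance),
$w_i = N/C_i$ (uniqueness), $S_{ij} = p_{ij} \cdot w_i$. Two reading
choices deserve a note:

* $r_{ij}$ counts **recipes**, not occurrences — a recipe listing
  scallions twice contributes 1. Duplicate lines are collapsed at counting
  time.
* The uniqueness weight is indexed $w_i$, not $w_{ij}$: it depends only on
  how many categories use the ingredient. (Source notations vary; the
  quantity itself is unambiguous.)

$S$ is bounded by $N$, attained exactly by a category-exclusive ingredient
used in every recipe of its category — the test suite verifies the bound
and its attainment. The featured threshold $\tau$ on $p$ defaults to 0.10:
it is described in the source analysis only as "empirically chosen", and
0.10 ("used in at least a tenth of the cuisine's recipes") is a defensible
floor that removes one-off exotic ingredients while keeping genuinely
characteristic ones; it is a plain argument everywhere it matters.
Rankings break ties deterministically (higher $S$, then higher $p$, then
lexicographic key) so reports are reproducible. Common ingredients are
those with $C_i = N$; no minimum-support option is applied by default
because the definition in the field is presence-based.

The implementation is matrix-based; its correctness is established against
a brute-force oracle that recomputes $S$ from raw membership sets with
plain loops, on random corpora, requiring exact equality (the arithmetic
path is identical: one division and one multiplication).

## 3. tf-idf representation and classifiers

Term frequency is **binary presence**: ingredient lists rarely repeat a
term, and the specialty counts are presence-based too, so a count-valued
tf would only inject noise. The idf is the smoothed variant
$\ln((1+D)/(1+\mathrm{df})) + 1$ (never zero, defined for unseen terms),
and every document vector is L2-normalized. These are fixed, not options:
reproducibility of the reports matters more than representation tuning.

Four classifier families are provided: linear SVM, multinomial naive
Bayes, a Gini decision tree and a bagged random forest. None of the usual
CRAN implementations are part of this package's dependency footprint, so
all four are implemented here:

* **SVM** — one-vs-rest, squared-hinge (L2) loss with $C = 1$, fitted by
  BFGS on the convex primal. With $p$ in the dozens-to-hundreds range and
  dense tf-idf rows this is fast and exactly reproducible; no kernel is
  offered because binary ingredient presence in an L2-normalized space is
  already near-linearly separable in practice.
* **Naive Bayes** — multinomial with Laplace $\alpha = 1$ on the
  (non-negative) tf-idf weights.
* **Decision tree** — CART-style binary splits by Gini impurity decrease,
  grown to purity (depth capped at 30 as a guard), deterministic
  tie-breaks (lowest feature index, lowest threshold).
* **Random forest** — 100 bagged trees, $\lfloor\sqrt{p}\rfloor$ features
  per node, majority vote.

Hyperparameters are defaults in a `control` list, not search targets: the
analysis this package supports compares model families, it does not tune
them.

**Evaluation protocol.** The evaluation of record is stratified 10-fold
cross-validation; the tf-idf vocabulary and idf weights are refit on each
training fold, and held-out recipes are transformed into the training
fold's space (unseen ingredients are dropped — no leakage). Metrics come
from the **pooled** out-of-fold confusion matrix rather than a per-fold
average: the source analysis does not say which aggregation it used and
its printed macro values are not exactly the column means of its per-class
values, so the package picks the aggregation that is reproducible without
per-fold variance bookkeeping and states it. An optional `holdout = TRUE`
gives the single stratified 80/20 split reading. Per-class metrics with a
zero denominator are reported as 0 with a warning, never silently.
Documents with no vocabulary ingredient at prediction time receive the
training majority class and are flagged.

## 4. Nutrient linkage

A recipe's per-100 g profile is the mass-weighted mean of its ingredients'
per-100 g nutrient densities — scale-free by construction (the test suite
checks invariance under uniform mass scaling, and that every profile lies
within the min/max envelope of its ingredients). Raw ingredient mass is
used: cooking losses are nowhere modeled, and inventing a yield factor
would add an unauditable parameter.

Unlinked ingredients are resolved in order: explicit substitute map (the
"most similar ingredient" path, kept as a human-curated file rather than
automatic similarity so outputs are auditable); below a 2% mass-fraction
threshold, silent exclusion with a log entry ("low usage" is unspecified
in the source; 2% is small enough that even a fat-dense ingredient moves
energy by under ~2%); above it, a hard error — silently guessing a heavy
ingredient's nutrients would corrupt every downstream cluster.

Energy is $4 \cdot \text{carb} + 4 \cdot \text{protein} + 9 \cdot
\text{fat}$ kcal per 100 g; fiber and sodium contribute none. Sodium stays
in mg/100 g (composition-table convention); Pearson correlations are
unit-invariant so no conversion is needed. Correlation matrices flag
zero-variance columns as undefined (`NA` plus an attribute) instead of
reporting a silent 0.

Composition-table rows violating the soft consistency checks
(sugar > carbohydrate, saturated fat > fat, macronutrients > 100 g) load
with a warning and a `valid = FALSE` flag rather than erroring: real
composition tables contain rounding violations, and refusing to load them
would make the reader useless in practice. Negative values remain hard
errors.

## 5. Nutrient clustering

Features are the seven nutrients, z-scored per column — in raw units,
sodium (hundreds of mg) would dominate Euclidean distance. Energy is
excluded from the features: it is an exact linear combination of three of
them and would double-weight the macronutrients. Initialization is
k-means++ from the stated seed, iterations are Lloyd's, an empty cluster
is reseeded from the point farthest from its own centroid, and the best of
`restarts` (default 10) runs by inertia is kept. `k = 20` is the
default analysis scale; the implementation is validated against
`stats::kmeans` (Lloyd, many random starts) as an independent oracle on
small separated data, and against planted archetypes via the adjusted Rand
index.

Representative ingredients per cluster treat each cluster as one pooled
document (tf = recipe count in the cluster, idf over the $k$
cluster-documents with the same smoothed formula). Characterization labels
a cluster `high_X` for every nutrient whose centroid z-score exceeds 1.0 —
"one standard deviation above the corpus mean" is the natural quantitative
reading of the qualitative "higher X" group descriptions this mirrors —
and `balanced` otherwise; raising the threshold can only remove labels
(tested monotonicity). Merging into groups is automatic for clusters with
identical label sets, or verbatim via an explicit `merge_map` (the
manual-curation path). Group annotations are a **static text table**
(`group_annotations()`) mapping labels to dietary-risk interpretations
with citation keys; the package computes no health inference.

## 6. The synthetic world

`generate_corpus()` emulates the structural features that the pipeline's
correctness depends on: 8 cuisines × 100 recipes by default (the scale of
a mid-sized single-site corpus, kept small enough for fast tests);
4–10 ingredients per recipe plus a staple, matching the ~8.6-ingredient
mean reported for comparable recipe sites; per-slot featured-pool draws
with probability `p_featured = 0.6` (strong but not caricatural cuisine
signal); lognormal(ln 30 g, 0.5) quantities with 15% replaced by vague
terms and 10% piece units, so all three imputation rules are exercised;
synonym variants at rate 0.3 resolved by the emitted lexicon; a 5%
decorative-garnish rate; and a toy composition table built from six fixed
nutrient archetype templates (high-carbohydrate, high-sugar, high-sodium,
high-fiber, high-fat, balanced) with 10% relative Gaussian noise, adjusted
to satisfy the consistency constraints. Templates are constants in code,
not sampled, so acceptance margins are stable.

What it does **not** emulate: real orthographic variation beyond the
listed variants, food-group-specific quantity distributions, class
imbalance, cooking transformations, or the long tail of rare ingredients.
A green test therefore establishes that the pipeline recovers structure
that is present and recoverable by construction — not that any real corpus
has that structure. The published per-category counts of the reference
corpus ship as data (`icook_reference_counts()`,
`icook_predicted_distribution()`) for arithmetic checks and realistic
scaling, including their documented internal inconsistencies (conversion
rates that do not match their own printed counts; a predicted-distribution
row whose eight counts sum to 5613 against a printed total of 5349 that
matches the first seven).

## 7. Numerical choices and degenerate inputs

* Half-up rounding for reported percentages; full-precision values
  everywhere internally. Reports round-trip through CSV/JSON to at least
  6 significant digits.
* Specialty and tf-idf arithmetic involve no tolerance at all; tests
  require exact equality with oracles where the arithmetic path is
  identical.
* Empty corpus, unknown-only corpus, empty vocabulary, zero recipe mass,
  $k > n$, non-square confusion matrices, out-of-range $\tau$, unresolved
  units and unmapped heavy ingredients are all hard, classed errors —
  each has a test.
* All randomness (fold assignment, forest bootstraps, k-means++
  initialization, the generator) derives from explicit integer seeds;
  derived child seeds stay below $2^{31}$.

## 8. Known limitations

Exact-match canonicalization bounds recall by lexicon coverage; the
corpus-mean imputation ignores ingredient co-usage context; linear SVM is
the only SVM; k-means assumes roughly isotropic clusters in z-space, which
real dietary data may violate; and the characterization threshold (z > 1)
is a single global constant, not adapted per nutrient. These are the
points where a follow-up analysis would most plausibly diverge.
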