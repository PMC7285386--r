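---
title: "Methods: SMOTE-balanced C4.5 stroke-risk stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SMOTE-balanced C4.5 stroke-risk stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokerisk)
```

## Scope and model

`strokerisk` analyses community stroke-screening cohorts coded as sixteen
categorical factors per person, labeled with a six-level risk
stratification (`H`, `M`, `L`, `N`, `T`, `Y`). The analytical chain is:
guideline labeling, an imbalance gate with nominal SMOTE, a C4.5 decision
tree, stratified cross-validated evaluation, rule extraction, and factor
analytics. Everything is categorical end to end — continuous measurements
(blood pressure, lipids, exact BMI, hours of sleep) enter only through the
coders `categorize_bmi()` and `categorize_sleep()`.

### Guideline labeling

`label_risk()` applies strict precedence: a stroke history (`SH = y`)
dominates everything (`Y`); otherwise a prior TIA gives `T`; otherwise the
counts of satisfied *major* and *secondary* predicates decide `H/M/L/N`.
Two modeling commitments here were genuinely open and are therefore
configurable:

* **The major/secondary partition.** The guideline source behind the
  reference analysis does not print its exact split. The default takes
  the four clinical diagnoses (`Hyte`, `Dysl`, `Diab`, `AF`, affirmed) as
  major and smoking, family stroke history, obesity (`BMIc` ∈ {B4, B5})
  and low exercise (`Sport = C3`) as secondary — the screening list minus
  the two history items that precedence already consumes. Any disjoint
  partition not touching `SH`/`TIA` can be supplied.
* **Missing values never satisfy a predicate.** The stratification counts
  affirmed items; absence of evidence is not an item. A record of all-`?`
  clinical fields labels `N`, not `H`.

`Y` beats `T` when both histories are affirmed, matching the screening
order (stroke history is asked first).

### Category coders

Missing information arrives under several spellings (`uncertain` in
clinical fields, `null` in habit fields, empty cells); `read_cohort_csv()`
folds all of them into the single token `?`, which the tree treats as a
level of its own.

Sleep hours are coded `TS`/`TB`/`TL` (short/normal/long) against
age-specific bands (6–10 h is normal for ages 18–64, 7–8 h above 64).
The printed band table leaves gaps between child age bands and is
ambiguous at the hour edges; the package commits to *closed-below /
open-above* hour intervals (`[lo, hi)` is `TB`) and lets ages between
printed bands inherit the nearest younger band, making the coder a total
monotone step function. BMI uses half-open bands on four configurable
cutpoints defaulting to the Chinese reference standard
18.5 / 24 / 28 / 32 kg/m² (`B1` underweight … `B5` severe obesity); only
the category codes, not the cutpoints, are fixed by the cohort coding.

### The imbalance gate and nominal SMOTE

Six-level stroke cohorts are strongly unbalanced (the reference cohort's
largest/smallest class ratio is ≈ 29). `smote_nominal()` implements the
gate-then-oversample design: count classes, and if max/min ≥ 3 (strict
`<` means balanced), shuffle the records by nonrepeatable sampling and
grow every minority class with synthetic records until the ratio falls
strictly below the target (default 3, the gate threshold itself). The
growth target is the minimal count satisfying the gate —
`ceiling(max/target)`, plus one when max is an exact multiple — because
the design prescribes only the gate, not an oversampling amount.

Classic SMOTE interpolates numerically; all features here are nominal, so
the neighborhood metric is Hamming distance over the sixteen coded
factors (missing `?` counted as an ordinary level), neighbors are the k
(default 5) nearest within the same class with ties broken by record
index, and a synthetic record copies each attribute from seed or neighbor
by a fair coin — the nominal analogue of convex interpolation, mixing the
two parents rather than cloning the minority point. Consequences that the
tests rely on: the majority class is never altered; every synthetic
(factor, value) pair exists in a real record of the same class (closure);
a second pass on balanced output is the identity; a lone-record class
degrades gracefully (its neighbor pool is itself). Neighbor search is
within-class; drawing neighbors across classes is a plausible alternative
reading of "combining the major and the minor data", but it would break
closure and label coherence, so it was not adopted.

By default cross-validation applies SMOTE *inside each training fold*;
`paper_mode = TRUE` reproduces the original whole-table-then-fold order.
The whole-table order lets synthetic records share neighbor information
with test records, which optimistically biases CV estimates — both modes
exist so the original protocol can be reproduced while sound reuse gets
the fold-wise default. Synthetic records never enter a test fold in
either mode.

### The C4.5 learner

`grow_tree()` is a from-scratch implementation: at each node every factor
is scored by information gain over the partition induced by its observed
levels (one branch per level, `?` included), inadmissible candidates
(single branch, non-positive gain, any branch below `min_leaf`) are
dropped, the mean-gain guard restricts the gain-ratio contest to factors
with at least average gain, and the winner maximizes the gain ratio.
Numerical guards: gains below 1e-12 count as zero; a vanishing
denominator disqualifies the candidate rather than raising an error;
selection ties break by schema factor order, and majority-vote ties at
leaves break by the fixed level order `H, M, Y, T, N, L` — all so that
identical inputs yield structurally identical trees.

Two deliberate deviations from J48's internals, both visible in the API:

* **Gain-ratio denominator.** The canonical C4.5 denominator is split
  info (the entropy of the branch sizes), and that is the default; a
  variant dividing by the post-split conditional entropy is available as
  `gain_denominator = "conditional_entropy"`, since that formulation also
  appears in the field. Under the variant, pure partitions make the
  denominator vanish and the candidate is disqualified, not crashed.
* **Missing values branch, not fractionally split.** J48 distributes
  records with missing values fractionally across branches; here `?` is
  an explicit branch. This keeps every extracted rule a crisp conjunction
  over literal factor values — a requirement of the rule-mining surface —
  at a small fidelity cost to J48's exact trees.

Pruning is pessimistic subtree replacement: a node's error count is
inflated to the upper binomial confidence limit at the confidence factor
(default 0.25; values near 0.5 prune least), and a subtree collapses when
the collapsed leaf's pessimistic error does not exceed its children's
sum. Subtree *raising* is not implemented; replacement covers the
analysis surface and raising has no observable effect on any quantity the
package reports. Prediction routes unseen values at an internal node to
that node's majority class.

### Evaluation

Folds are stratified per class (dealt round-robin after a seeded
within-class shuffle, so per-class fold sizes differ by at most one); the
fold count drops with a warning when the rarest class is smaller than the
requested folds. Accuracy is trace/total — for the six-class task this
equals the aggregated one-vs-rest TP+TN form. Precision and recall are
one-vs-rest per class, with 0/0 reported as `NA` rather than 0 so macro
summaries are not silently deflated. Kappa is `(po − pe)/(1 − pe)` with
`pe` from the matrix margins; a degenerate single-class matrix yields
`NA`.

### Rules and factor analytics

Every root-to-leaf path is one rule; the rule list therefore partitions
the record space and its supports sum to the training size. "Related to
the daily habits" means the rule's factor set intersects
`{Smok, Alco, Tea, DT, Sleep, Sport}` — the reading consistent with
per-factor and pairwise rule counts being comparable to the filtered
total. Rules carry leaf confidence (majority fraction) even though the
reference analysis reports none; ranking rules in reuse needs it.

The relationship matrix accumulates, over all rules, a weight for every
unordered factor pair co-occurring in a rule. The generative description
behind the reference matrix ("the sum of the reciprocals of factors" per
set) is ambiguous, so three explicit schemes are implemented and stamped
into the result: `set-size` (default; each pair in a rule with f factors
gets 1/f, so a rule spreads unit-order mass), `depth-sum`
(1/(1+d_a) + 1/(1+d_b), favoring near-root factors), and `unit` (pure
co-occurrence counts). Matrix summaries are scheme-agnostic:
`matrix_mean()` averages all C(n,2) unordered pairs including zeros, and
`above_mean_partners()` compares a factor's row against that row's own
mean — the "group" reading that reproduces the reference membership
tables, including the Sleep column's eight members. The transcribed
reference matrix ships as a fixture so these summaries are testable
without regenerating the original tree.

Depth profiles use the convention root split = depth 0, forced by the
reference table (stroke history averages 0.00). The frequency-weighted
average depth is an influence ranking: factors consulted near the root
dominate the stratification.

## The synthetic cohort generator

The original cohort is not publicly deposited, so `simulate_cohort()`
stands in. What it emulates:

* **Marginals** — per-factor level probabilities equal to the published
  per-level counts over the row total (the diet row's printed counts sum
  to 5626 against a cohort of 5599; normalizing each row by its own total
  preserves the printed proportions). Age-band counts are published only
  graphically, so the seven adult bands default to uniform weights.
* **Label logic** — `guideline` mode applies `label_risk()`;
  `planted` mode starts every record at the baseline level `N` (the
  no-factor stratum) and fires the planted rules; `mixture` layers
  planted overrides on guideline labels. Planted rules apply in list
  order with later rules overriding, each firing on a matching record
  with its configured strength.

What it does **not** emulate: any dependence between factors. Factors are
sampled independently because only marginals are published; real
screening data certainly correlates (smoking with gender and age,
diabetes with BMI…). Tests that need dependence plant it explicitly, so a
passing structure-recovery suite shows the pipeline can find signal that
is present — it says nothing about the strength of such signal in real
cohorts, and guideline-mode CV accuracy is optimistic relative to real
data because the label is a deterministic function of the factors up to
missingness.

The structure-recovery study conditions are two planted rules of strength
0.95 on a cohort of 5,000: `Hyte = y → H` and `Sport = C3 → M`. These
two were chosen (before any tuning, and not revisited) because their
antecedents are frequent (≈ 22% and ≈ 41% marginal mass), which keeps the
majority-class baseline low enough that a 15-percentage-point accuracy
lift is a meaningful bar, and because they touch one clinical and one
habit factor.

## Problem sizes and determinism

The test suite works at three scales, chosen as the smallest sizes where
each property is sharp: exact-arithmetic checks on the transcribed
reference tables (no simulation), property suites on cohorts of 100–600
records across many seeds, and two 5,000-record runs (marginal fidelity
at 20,000 draws; structure recovery and the acceptance pipeline at
5,000 — the scale of the reference cohort). Every stochastic step takes
an explicit integer seed; pipeline stages derive their seeds from one
master seed by hashing the stage name, so a single integer reproduces a
full run byte-for-byte, and RNG state is restored after each seeded
operation so library calls do not perturb the caller's session.

## Known limitations

* No continuous-attribute splits: the learner is deliberately nominal
  (the cohort coding is categorical); it is not a general C4.5.
* No J48 bit-compatibility: fractional missing-value handling and
  subtree raising are absent, so leaf/size counts will differ from J48 on
  the same data even at identical settings.
* The reference tree (98 leaves, 171 nodes) and its 37 habit rules are
  not reproducible without the original cohort; fidelity is anchored on
  the transcribed summary tables instead.
* `habit_risk_profile()` reports conditional distributions, not causal
  effects; planted-cohort recovery checks the estimator, not any clinical
  claim.
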