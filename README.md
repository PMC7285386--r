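# strokerisk

Stroke-risk stratification over categorical screening data with an
imbalance-gated SMOTE + C4.5 pipeline, knowledge-rule extraction, and
factor-relationship analytics.

## The problem

Community stroke screening produces large tables of coded categorical
factors — clinical diagnoses (hypertension `Hyte`, dyslipidemia `Dysl`,
diabetes `Diab`, atrial fibrillation `AF`), histories (own stroke `SH`,
family stroke `FSH`, transient ischemic attack `TIA`), demographics,
BMI class, and six daily-life habits (smoking, alcohol, tea, diet, sleep,
exercise). Each person is assigned one of six risk levels:

| Level | Meaning |
|---|---|
| `Y` | history of stroke |
| `T` | prior TIA |
| `H` | ≥ 2 major factors, or 1 major + ≥ 2 secondary |
| `M` | 1 major factor, < 2 secondary |
| `L` | 0 major, ≥ 2 secondary |
| `N` | 0 major, < 2 secondary |

The interesting questions are interpretive: which factors drive the
stratification, how strongly are the daily habits tied to the clinical
risk factors, and what crisp IF–THEN rules can screening staff act on?

This package answers them with:

1. **Guideline labeling** (`label_risk`) — the precedence/counting logic
   above, with a configurable major/secondary factor partition.
2. **Imbalance gate + nominal SMOTE** (`is_balanced`, `smote_nominal`) —
   rare levels like `T` are heavily outnumbered; when the max/min class
   ratio reaches 3, minority classes are grown with synthetic records built
   from within-class nearest neighbors under Hamming distance, each
   attribute drawn from seed or neighbor by a fair coin.
3. **A from-scratch C4.5 learner** (`grow_tree`, `prune_tree`) — multiway
   nominal splits chosen by gain ratio

   Info(D) = −Σᵢ pᵢ log₂ pᵢ,  Info_A(D) = Σⱼ (|Dⱼ|/|D|) Info(Dⱼ),
   Gain(A) = Info(D) − Info_A(D),  GainRatio(A) = Gain(A) / SplitInfo(A),

   with a mean-gain guard, explicit `?` branches for missing values,
   `minNumObj`-style leaf control and confidence-factor (default 0.25)
   pessimistic pruning.
4. **Evaluation** (`cross_validate`, `accuracy`, `cohen_kappa`) —
   stratified 10-fold CV, per-class precision/recall, accuracy, and
   Cohen's kappa (p₀ − pₑ)/(1 − pₑ) over six-class confusion matrices.
5. **Rule mining** (`extract_rules`, `filter_rules`) — each root-to-leaf
   path becomes a conjunctive rule with support and confidence; habit
   filtering selects the rules touching the six daily-life factors.
6. **Factor analytics** (`depth_profiles`, `relationship_matrix`,
   `above_mean_partners`, `habit_risk_profile`) — average split depth per
   factor (lower = more influential), a symmetric factor-pair weight
   matrix accumulated over rules, above-row-mean partner tables, and
   per-habit risk profiles.
7. **A synthetic cohort generator** (`simulate_cohort`) — the original
   5,599-person cohort is not publicly deposited, so the generator
   reproduces its published per-factor marginals and lets tests plant
   known factor→risk rules to verify structure recovery end to end.

Transcriptions of the published summary tables (confusion matrices for the
C4.5, random-forest and logistic models; split-depth counts; the 16-factor
relationship matrix) ship in `inst/extdata/` and load through
`reference_confusion()`, `reference_depth_counts()` and
`reference_relationship_matrix()`.

## Worked example

```r
library(strokerisk)

co <- simulate_cohort(sim_config(n = 3000, seed = 7))
class_counts(co)
#>    H    M    Y    T    N    L
#>  270  749  102   40 1525  314

bal <- smote_nominal(co, balance_config(seed = 7))
bal$report
#> balance report (triggered: TRUE )
#>             H   M   Y   T    N   L
#> before    270 749 102  40 1525 314
#> synthetic 239   0 407 469    0 195
#> after     509 749 509 509 1525 509

cv <- cross_validate(co, folds = 10, seed = 7)
sprintf("accuracy %.4f  kappa %.4f", cv$report$accuracy, cv$report$kappa)
#> "accuracy 0.9150  kappa 0.8699"

tree  <- grow_tree(bal$table, tree_config(), prune = TRUE)
rules <- extract_rules(tree)
head(render_rules(filter_rules(rules, habit_factors())), 1)
#> IF SH = n AND TIA = n AND Hyte = y AND Dysl = n AND Diab = n AND
#>    Smok = y AND Sport = C1 THEN risk = M [support=16, confidence=0.8125]

head(depth_profiles(tree), 3)
#>   factor frequency average_depth
#> 1     SH         1             0
#> 2    TIA         2             1
#> 3   Hyte         4             2
```

The depth profile reads as an influence ranking: stroke history splits at
the root (average depth 0), TIA right below it, then the clinical
diagnoses — habits appear deeper, i.e. they modulate rather than determine
the risk level. On the published reference tables:

```r
accuracy(reference_confusion("c45")) * 100     # 87.5281
cohen_kappa(reference_confusion("c45"))        # 0.8344
matrix_mean(reference_relationship_matrix())   # 1.95
above_mean_partners(reference_relationship_matrix(), "Sleep")$factor
#> "SH" "Hyte" "Dysl" "Diab" "Smok" "Age" "FSH" "Sport"
```

A thin command-line wrapper lives at `inst/scripts/stroke_pipeline.R`
(`simulate` and `run` subcommands over YAML configs); `run_pipeline()` is
the same entry point from R and writes every artifact (cohort, balanced
cohort, tree JSON, metrics, rules, factor report) plus a seed/hash
manifest into an output directory.

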