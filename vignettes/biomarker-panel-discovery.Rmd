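---
title: "Multiclass biomarker panel discovery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiclass biomarker panel discovery: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

panelIFS implements a feature-selection-and-classification chain that is
widely used for transcriptome-based tumor typing: screen tens of thousands
of genes down to the relevant ones, rank the survivors, find how many of
the top-ranked genes a classifier actually needs, and then distill the
compact panel into human-readable decision rules. This vignette explains
each stage's model and assumptions, the tunable parameters, and the design
choices made where the methods literature leaves the details open.

## The pipeline at a glance

Input is a samples × genes expression matrix (TPM-like non-negative
values, or already log2-transformed) with a class label per sample —
typically tumor type, with many classes of very different sizes. The
stages run in a fixed order:

1. **Class-size filter.** Classes with fewer than `min_class_size`
   (default 10) samples are dropped with their samples: smaller classes
   cannot support stratified 10-fold cross-validation.
2. **Boruta screening** (`run_boruta`) removes genes whose importance is
   indistinguishable from permuted noise.
3. **mRMR ranking** (`rank_mrmr`) orders the retained genes by mutual
   information with the label, penalized by redundancy with already-ranked
   genes.
4. **Incremental feature selection** (`run_ifs`) evaluates nested top-k
   prefixes of the ranking with a classifier under stratified
   cross-validation, optionally SMOTE-balancing each training fold, and
   records per-class accuracy, overall accuracy and multiclass MCC per k.
5. **Optimal/compact selection** (`select_optimal`, `select_compact`)
   reads the curve: the optimal k maximizes MCC; the compact k is the
   smallest one within a tolerance of the optimum.
6. **Rule extraction** (`train_tree`, `extract_rules`) trains a CART tree
   on *all* samples restricted to the compact panel and emits one IF–THEN
   rule per leaf, summarized per class as rule/criterion/distinct-gene
   counts.

`run_pipeline()` orchestrates the chain from one config with resumable
on-disk artifacts; the numbered scripts under `analysis/` run the same
stages interactively on the package's synthetic study.

## Shadow-feature screening (Boruta)

Each iteration copies the whole expression matrix, permutes every copied
column independently ("shadow" features), fits a random forest on the
original-plus-shadow matrix, and counts a *hit* for every still-undecided
gene whose importance exceeds the maximum shadow importance. After `t`
iterations a gene with `h` hits faces an exact binomial test against the
coin-flip null: the upper tail confirms, the lower tail rejects, both
Bonferroni-corrected across all `m` input genes, at `alpha = 0.05`.

Three details matter and were settled empirically:

* **Importance statistic.** We use the Z-score of permutation importance
  (mean decrease in out-of-bag accuracy scaled by its standard error, the
  classic Boruta statistic) rather than mean-decrease-impurity. With
  hundreds of genes and moderate sample sizes, a handful of genes are
  strongly correlated with any labeling — including a permuted one —
  purely by chance; impurity importance rewards those in-sample
  correlations so persistently that they beat the shadow maximum in well
  over half of iterations and are eventually "confirmed" on data with no
  signal at all. Permutation Z-scores suppress this failure mode almost
  entirely while leaving the recovery of genuine effects untouched.
* **Shadow pool.** Shadows are rebuilt for *all* genes every iteration,
  not only for the undecided ones. If the shadow pool shrank with the
  undecided set, the max-shadow threshold would weaken over time and
  late-surviving chance correlations would start beating it.
* **Tentative genes.** Genes still undecided at `max_iter = 100` stay
  tentative and are *not* retained. The median "rough fix" (confirm a
  tentative gene if its median importance history exceeds the median of
  the per-iteration shadow maxima) is available via `rough_fix = TRUE`,
  but on permutation-null data it flips lingering chance-correlated genes
  to confirmed about half the time, so it is off by default.

The forest has `num_trees = 500` trees and the run is fully deterministic
given `seed`.

## mRMR ranking

Expression values are discretized into three bins at `mean ± sigma·sd`
(population sd, `sigma = 1`) — the convention of the widely used mRMR
program for continuous inputs; a constant gene collapses into the middle
bin. Relevance and redundancy are empirical mutual information in bits
(`0·log 0 = 0`). The greedy selection takes the most relevant gene first
and thereafter maximizes

* `MID` (default): relevance − mean MI with the already-selected genes, or
* `MIQ`: relevance / mean MI with the already-selected genes.

Ties break by candidate order, so the ranking is deterministic. Note a
consequence of the *mean* in the redundancy term: an exact duplicate of an
already-selected gene has its relevance fully cancelled at the step right
after its twin is taken, but at later steps the penalty is averaged with
near-zero terms and the duplicate can legitimately overtake weakly
relevant genes. The test suite checks every greedy step against a
brute-force evaluation of the criterion.

## Cross-validated evaluation and SMOTE

`stratified_folds` assigns each class's samples to K folds (default 10) as
evenly as possible (per-class fold counts differ by at most one). One fold
assignment is reused across all subset sizes, so the IFS curve is a paired
comparison.

Tumor-type data sets are heavily unbalanced, so each training fold can be
SMOTE-balanced before fitting: every minority class is raised to the
majority count by synthesizing points `x + u·(z − x)` with
`u ~ Uniform(0,1)`, `x` a random minority sample and `z` one of its
`k_neighbors = 5` nearest same-class neighbors, with distances measured in
the feature subspace under evaluation (oversampling must live in the
classifier's input space). Original rows are never altered. By default
SMOTE runs inside each training fold (`scope = "fold"`), which keeps the
held-out fold untouched and avoids information leakage;
`scope = "global"` balances once before cross-validation to mimic
preprocessing-style workflows, and `scope = "none"` disables balancing.
The methods literature is genuinely ambiguous about which arrangement the
classic tumor-typing studies used, so both are provided and the
leakage-free one is the default.

Raw-scale expression is transformed by `log2(x + 1)` before any
classifier, neighbor search or importance computation; already-log2 data
is used as is.

## Performance measures

Pooled held-out predictions are scored by per-class accuracy
(`n_correct_i / N_i`), overall accuracy (`Σ n_i / Σ N_i`) and the
multiclass Matthews correlation coefficient in covariance form: with X and
Y the one-hot predicted and actual label matrices,

$$\mathrm{MCC} = \frac{\sum_{ij}(x_{ij}-\bar x_j)(y_{ij}-\bar y_j)}
 {\sqrt{\sum_{ij}(x_{ij}-\bar x_j)^2\;\sum_{ij}(y_{ij}-\bar y_j)^2}},$$

with column means over all n rows. For two classes this is algebraically
the classical binary MCC (fuzz-tested against an independent
implementation of that formula). When either variance term is zero — e.g.
a constant prediction — the value is defined as 0 with a warning, so IFS
curves remain well defined.

## Classifiers

Two classifiers sit behind the `classifier_spec` contract:

* **tree** — the in-package CART (Gini impurity, exhaustive search over
  midpoint thresholds, grown to pure leaves by default). IFS evaluation
  and rule extraction share this one implementation, so the rules exactly
  describe the classifier that was evaluated. Ties in impurity gain break
  toward the lowest feature index, then the lowest threshold; training is
  deterministic. CART is implemented in-package rather than wrapped from
  an existing tree library because rule extraction needs full control over
  thresholds, tie-breaks and leaf bookkeeping, and the guarantees are
  asserted by tests (rules reproduce the tree on 100% of training samples
  and random query points).
* **margin** — a one-vs-rest maximum-margin model with a polynomial
  kernel: one binary SVM per class (degree 1, cost 1, mirroring the
  common SMO defaults), prediction by the largest decision value. The
  binary subproblems are solved by `e1071::svm`; the IFS engine only sees
  the contract.

## Selection tolerance

`select_compact`'s default tolerance of 0.025 MCC is the size of
performance drop that tumor-typing studies typically accept in exchange
for an order-of-magnitude smaller panel. It is exposed as a parameter
because "slightly lower" is a judgment call, not a constant.

## The synthetic study

Real pan-cancer inputs (e.g. ~1,000 cell lines × ~58,000 genes over 20
tumor types) require external downloads, so the package carries a
generator (`synthetic_spec`/`generate_dataset`) whose defaults define a
desk-scale study with the same structure:

* 5 classes with unbalanced sizes 60/45/40/30/25 (200 samples);
* 500 genes: 25 informative, 15 redundant (noisy copies of informative
  parents, `redundancy_sd = 0.25`), 460 class-independent;
* log2-normal expression: per-gene baseline Uniform(1, 8), within-class
  sd `noise_sd = 0.5`, class shift `effect_size = 2` — a strong,
  cleanly recoverable effect (4 within-class sds);
* each informative gene is "on" in a random 1..C−1 class subset, so no
  single gene separates all classes and multi-gene panels are required.

Heavier test settings use 2 classes × 100 samples with 20 informative /
180 noise genes (screening recovery) and 5 × 40 samples with 20
informative / 480 noise genes (IFS recovery); these sizes keep the full
suite and the acceptance script in the minutes range while leaving each
stage's statistics meaningful.

What the generator does *not* emulate: library-size and batch effects,
count noise, gene-gene correlation beyond the explicit redundant copies,
and realistic class-conditional covariance. Passing recovery tests
therefore show that the pipeline's logic is sound, not that it will
resolve any particular real data set.

One behavior of the synthetic study is worth flagging. Because mRMR
explicitly minimizes redundancy, its top-10 genes already cover the five
classes, and with a strong effect size the IFS curve is essentially flat
from the first grid point: the compact selection lands at k = 10 (the
smallest evaluated subset), not near the number of informative genes. A
smaller panel with equal cross-validated MCC is the method working as
intended, but it means the compact k should not be read as an estimate of
how many genes carry signal.

## Numerical conventions

* All text writers print doubles with 17 significant digits, so
  writer/reader pairs round-trip exactly and identical runs produce
  byte-identical artifacts (asserted by tests).
* One global seed derives per-stage seeds by hashing the stage name
  (`stage_seed`), so a single integer reproduces a whole run and stages
  stay decoupled.
* Class names map to factor levels in lexicographic order everywhere.
* Degenerate inputs are defined, not special-cased away: constant genes
  discretize to the middle bin (MI 0), single-class training sets give
  single-leaf trees, an empty rule set summarizes to zeros.

## Known limitations

* Boruta screening and IFS assume a moderate sample-to-gene ratio within
  the retained set; with very few samples per class the binomial test
  needs many iterations and the cross-validated MCC becomes noisy.
* SMOTE interpolates linearly, which can place synthetic points in
  implausible regions when a minority class is multimodal.
* The CART implementation is exact but pure R; for panels beyond a few
  hundred genes and thousands of samples a compiled tree learner would be
  faster. At the package's problem sizes a full IFS curve takes seconds.
* No nested hyperparameter tuning: classifier defaults are fixed inside
  the IFS loop by design, so curves across k are comparable.
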