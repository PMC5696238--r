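---
title: "Decision Forest modelling of ERbeta binding: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision Forest modelling of ERbeta binding: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erbforest)
```

## The modelling problem

Estrogen receptor beta (ERbeta) binding is a classification endpoint of
practical interest in drug discovery and toxicology: compounds that bind one
estrogen-receptor isoform selectively are candidate selective estrogen
receptor modulators, and high-throughput screens produce far more candidate
chemicals than binding assays can absorb. `erbforest` implements a complete
QSAR (quantitative structure-activity relationship) classification protocol
for this endpoint: compounds are described by precomputed numeric molecular
descriptors (e.g. Mold2-style 1D/2D descriptors), labelled binder or
non-binder from log relative binding affinity (logRBA), and classified by a
Decision Forest.

Two structural features of the motivating data drive every design choice in
the package:

* **Extreme class imbalance.** The training structure emulated here has
  ~98.8% binders and ~1.2% non-binders. Plain accuracy is therefore nearly
  meaningless (the majority-class predictor scores ~99%), which is why the
  protocol reports sensitivity, specificity, MCC and balanced accuracy
  alongside accuracy, and why balanced accuracy drives the forest's
  stopping rule.
* **No missing values, descriptors on arbitrary scales.** Descriptor
  generators emit complete tables of typed/discretised values. The package
  refuses missing cells rather than imputing, and nothing is normalised:
  trees are invariant to monotone rescaling of individual descriptors.

## The Decision Forest

A Decision Forest (DF) combines a *small* number of *deep* decision trees.
Trees are trained sequentially on all compounds; after a tree is accepted,
the descriptors it used are removed from the descriptor pool before the next
tree is grown. The per-tree descriptor sets are therefore pairwise disjoint;
tree diversity comes from feature exclusion, not from bootstrapping or
random feature subsets as in Random Forests. The consensus binder
probability of a compound is the unweighted arithmetic mean of the leaf
binder fractions the trees route it to, the class call is binder iff
P >= 0.5 (boundary inclusive), and the prediction confidence is
|P - 0.5| / 0.5.

### Tree growth

Individual trees are grown greedily: at each node every pool descriptor is
scanned for the binary threshold maximising information gain (Shannon
entropy reduction, in bits), thresholds being midpoints between adjacent
distinct sorted values with at least `min_leaf` compounds on each side.
Ties in gain are broken by descriptor column order and, within a descriptor,
by the smaller threshold, so training is deterministic and seed-free.

A split is only *accepted* if it passes a significance gate: the
G-statistic of the best split (`2 n ln2 * gain`) is referred to its
chi-squared(1) null with a Bonferroni correction for every candidate
threshold scanned at the node (`pool size * (n - 1)`, a deliberately
conservative count), and the node becomes a leaf when the adjusted p-value
exceeds `split_alpha` (default 0.05). This pre-pruning, in the spirit of
conditional-inference trees, is what makes "deep" trees safe: without it a
deep tree always reaches training purity, so a tree grown on a pool with no
remaining class signal memorises noise, and — because consensus averaging
is unweighted — a single such tree dilutes the specificity of the whole
forest. With the gate, a signal-free pool produces a degenerate single-leaf
tree and forest growth stops. During development we verified this
behaviour directly: on synthetic data the package's out-of-fold balanced
accuracy matches a deep CART reference when one genuine tree is kept,
whereas ungated extra trees collapsed specificity toward zero.

### Forest growth and stopping

Trees are added until one of:

1. `max_trees` (default 10) is reached;
2. the descriptor pool is exhausted, or the next tree is degenerate
   (a single leaf — the usual outcome once the pool's signal is consumed);
3. the candidate tree *degrades* consensus training balanced accuracy by
   more than `improvement_epsilon` (default 0), in which case it is
   discarded and growth stops.

Rule 3 keeps ties: a weak-but-genuine tree whose root association passed
the significance gate usually leaves consensus training balanced accuracy
unchanged (the confident first tree dominates the mean), and discarding it
would defeat both the multi-tree character of the method and the coverage
of substitutable informative descriptors that frequency-based importance
ranking relies on. The consensus training balanced accuracy of the returned
forest is by construction never below that of its first tree.

No class weighting or resampling is applied to counter the imbalance. The
motivating protocol left the bias in — visible as high sensitivity and low
specificity — and reproducing that behaviour is part of the point.

### Defaults and their rationale

| parameter | default | rationale |
|---|---|---|
| `min_leaf` | 5 | prevents singleton leaves from dominating the consensus mean |
| `max_depth` | unlimited | DF trees are deep by design; depth is controlled by the significance gate instead |
| `split_alpha` | 0.05 | conventional family-wise level; conservative Bonferroni count |
| `improvement_epsilon` | 0 | any strict degradation of consensus training balanced accuracy stops growth |
| `max_trees` | 10 | safety cap; growth almost always stops earlier via rule 2 or 3 |

## Labelling and preprocessing

* A compound is a **binder iff logRBA >= -5** (inclusive). Compounds with
  several measurements are labelled by strict majority; an exact tie is
  *excluded* from training (and logged), since an ambiguous consensus label
  would corrupt training. The threshold comparison and the tie rule are
  exact, not fuzzy.
* **Low-information descriptors** are removed before training: a descriptor
  is dropped when its most frequent value (exact floating-point equality)
  covers more than `dominance_threshold` (default 0.95) of the compounds;
  constant descriptors are always dropped. The filter is computed on the
  training table only and its kept-column list is applied verbatim to
  application tables (`apply_filter()`), preventing leakage and column
  mismatches. The 0.95 default is a package choice: the exact cutoff behind
  the motivating study's 777-to-447 reduction is not recoverable without
  its original table, so the parameter is exposed.

## The validation protocol

* **Repeated k-fold cross-validation** (`cross_validate()`): each iteration
  draws a fresh *unstratified* uniform random partition into k folds
  (default 5), trains one forest per fold on the other folds, and evaluates
  the pooled out-of-fold predictions of the iteration. Pooling, rather than
  averaging fold-level metrics, keeps specificity defined even when an
  unstratified fold happens to contain no non-binders — a real possibility
  with ~1-5% negatives. Stratified folds are available behind a non-default
  flag. A training fold that is entirely single-class is skipped and the
  iteration flagged.
* **Permutation testing** (`permutation_test()`): each replicate scrambles
  the labels (class counts preserved) and runs one full k-fold CV. Because
  of the significance gate, permuted replicates almost always produce
  prior-rate single-leaf models, so every compound is called binder and the
  replicate lands exactly at the random-classifier null: sensitivity 1,
  specificity 0, balanced accuracy 0.5, and MCC 0 (its denominator is
  degenerate; the package reports 0 with an `mcc_undefined` flag, the
  convention a permutation null converges to).
* **Seed ladder.** Iteration i of a CV draws folds with
  `base_seed + i`; permutation replicate r scrambles with `base_seed + r`
  and runs its CV with `base_seed + replicates + r`, so the permutation
  draw and the fold draw never share a generator stream start and every
  replicate is independently reproducible.
* **Confidence analysis** (`bin_predictions()`): out-of-fold predictions
  are placed into 10 *equal-width* bins over confidence in [0, 1]
  (left-closed, the final bin closed at 1) and each bin is scored
  separately. Equal width was chosen over equal frequency because the
  protocol's "10 even bins" most naturally reads as even width; the
  observed near-even occupancy in the motivating study describes its data,
  not the binning rule.
* **Descriptor importance** (`descriptor_frequencies()`): a descriptor
  counts as used in a model iff it appears in at least one split node of
  any of the model's trees — pool membership alone is an artefact of
  ordering. Descriptors used in strictly more than 90% of CV models are
  selected as informative.

## The synthetic-data generator

`generate_dataset()` emulates the statistical structure the protocol
assumes, so that every stage is testable without database access:

* exact class counts (default 2462 binders / 30 non-binders);
* a small planted set of informative descriptors (default 18 of 447):
  non-binders drawn from N(0, `noise_sd`), binders from a normal with 1.5x
  the dispersion whose mean shift delivers a *standardised* class
  separation of exactly `effect_size` (default 1.5) against the pooled SD.
  The heavier binder dispersion mirrors the observation that binders
  occupy a larger chemical space than non-binders;
* the remaining descriptors are class-independent noise, and a
  `fraction_constant` share (default 0.1) is emitted constant to exercise
  the preprocessing filter;
* `generate_logrba_records()` emits replicate logRBA measurements whose
  ground-truth consensus labels are fixed *before* the values are drawn
  (offsets of known sign from the threshold), so the emitted truth is an
  independent oracle for the labelling rule, including exact-tie records.

What the generator does **not** emulate: real Mold2 marginal distributions
(discreteness, skew, heavy correlation between descriptors), structured
redundancy among informative descriptors, and any relation between
descriptors and actual chemistry. Passing tests therefore demonstrate that
the machinery is correct and that the protocol behaves as designed under
its stated statistical assumptions — not that the package reproduces the
motivating study's headline cross-validation numbers, which depend on a
proprietary descriptor table.

## Problem sizes used by the test-suite and acceptance script

Desk-scale configurations keep the full suite within half a minute while
preserving the study's structure:

* validation-protocol checks: 500 compounds (4% non-binders), 50
  descriptors with 5 planted informative at the default effect size;
  20 CV iterations and 100 permutation replicates. Five planted of fifty
  was chosen over scaling the default 18/447 ratio because frequency-based
  recovery requires each planted descriptor to be individually detectable;
  with 18 equal-effect planted descriptors each model needs only a few of
  them, and usage fractions collapse.
* importance recovery: 800 compounds (5% non-binders), 40 descriptors with
  4 planted informative. This configuration was set by a power
  calculation: at fold size 640, a planted descriptor's best root split
  (G about 30) clears the Bonferroni-corrected acceptance bar (about 22),
  so every planted descriptor is root-detectable and the disjoint-pool
  mechanism forces models to cover substitutable descriptors. Under the
  500-compound configuration a single planted descriptor's marginal split
  (G about 14) sits *below* the multiplicity bar — frequency-based
  recovery there is statistically ill-posed, which is itself an
  instructive property of the method.
* the acceptance script runs the 100-replicate permutation experiment on
  the 500-compound configuration and reports mean out-of-fold MCC and
  balanced accuracy in percent.

## Numerical choices and degenerate inputs

* Entropy is computed in bits; `0 log 0 = 0`.
* A best split whose gain is not strictly positive (tolerance `1e-12`) is
  treated as no-split.
* Thresholds are midpoints of adjacent distinct values, so predictions are
  invariant to which side of a tie a training value sat on.
* Metrics with zero denominators are `NA` ("undefined"); MCC with any zero
  denominator factor is 0 with a flag. Reported percentages round half
  away from zero to one decimal.
* Model JSON stores doubles as 17-significant-digit strings so that a
  saved and reloaded forest predicts bit-identically.
* A dataset whose every compound is excluded by tied labels, an empty
  descriptor pool, a single-class training set, and application compounds
  missing descriptor columns are all hard errors naming the offender.

## Known limitations

* Specificity estimates ride on very few non-binders; their CV standard
  deviation is intrinsically large (the protocol's unstratified folds make
  this visible rather than hiding it).
* The significance gate is Bonferroni-conservative; genuinely weak signal
  near the detection boundary may be pruned. This is a deliberate
  trade-off against noise trees whose cost, under unweighted consensus
  averaging, is severe.
* Concordance tables with an empty class row yield degenerate metrics
  (specificity 0 or undefined, MCC flagged); the package reports the
  flags rather than guessing.
* Descriptor computation from structures (SDF/SMILES) is out of scope;
  tables arrive precomputed.
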