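---
title: "Predicting GC/LC amenability: models, selection pipeline and statistical comparisons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting GC/LC amenability: models, selection pipeline and statistical comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amenability)
```

## The problem

Archived GC-HRMS and LC-HRMS chromatograms can be searched retrospectively
for chemicals that were never targeted when the samples were run. Before
searching, one must decide which archive a compound can plausibly appear in
at all. `amenability` treats that decision as a multi-label classification
task: every compound carries two independent binary labels, GC and LC, and
a compound may be amenable to both platforms, to one, or to neither. The
inputs are wide numeric descriptor tables (typically >1000 descriptors per
compound) with the two label columns.

## The rule baseline

The baseline encodes textbook chromatographic practice. A compound is
GC-amenable when it is volatile (boiling point between 100 and 350 °C,
inclusive at both ends), light (molecular weight strictly below 700 Da) and
apolar (logP strictly above 2); it is LC-amenable (reversed phase) when it
is polar enough (logP strictly below 5.91). The boundary semantics —
inclusive boiling-point window, strict MW and logP comparisons — are a
deliberate fixed convention, centralized in `classify_rule()` and pinned by
boundary tests, because "from 100 to 350" is otherwise ambiguous. Rows with
a missing mapped descriptor are classified (0, 0) with a warning rather
than aborting a batch: in screening practice a compound with no boiling
point estimate simply cannot be routed by the rule.

## Label-based accuracy

Multi-label predictions can be partially correct. The exact match ratio
ignores this; the package's primary score is the label-based (Hamming)
accuracy, the per-compound Jaccard overlap between true and predicted label
sets averaged over compounds:

$$A = \frac{1}{n}\sum_{i=1}^{n}\frac{|y_i \cap \hat y_i|}{|y_i \cup \hat y_i|}.$$

A row with both sets empty contributes 1 (there is nothing to get wrong);
this cannot occur with the rule baseline (logP is always on one side of
5.91) but is defined for generality and flagged when it happens. The
classification report follows the common convention of reporting
zero-denominator precision/recall as 0 with a flag, and its "samples"
average scores a row with an empty predicted (or true) label set as
precision (recall) 0. All report entries are rendered as percentages with
two decimals by `tidy()`.

## The feature-selection pipeline

Six stages, each consuming the previous stage's retained set:

1. **Quasi-constant filter** (`quasi_constant_threshold = 0.99`): a feature
   is dropped when its modal value covers more than 99% of rows. Missing
   values count as a value of their own, so an almost-all-`NA` column is
   also dropped.
2. **Spearman correlation filter** (`correlation_threshold = 0.9`): rank
   correlations catch monotone (not merely linear) redundancy, which is the
   right notion for descriptor tables full of monotone transforms of the
   same physical quantity. Pairs are scanned in column order; by default
   the later member of a redundant pair is dropped (`keep_rule =
   "column_order"`). An alternative rule keeps the member more
   rank-correlated with the labels (`"label_relevance"`), since relevance
   to the outputs is worth preserving; the default is the simpler,
   order-reproducible convention. |r_s| is compared by default so
   anti-correlated duplicates are caught too; a signed option exists.
3. **Random-forest importance filter** (`importance_scale = 1.5`): a forest
   is fitted jointly on both labels — encoded as the 4-class product label
   (GC, LC) ∈ {00, 01, 10, 11} — and features with importance at least 1.5
   times the mean importance are kept (inclusive comparison). The default
   importance measure is **out-of-bag permutation importance**. This is a
   deliberate design choice: with many irrelevant columns and noisy labels,
   fully grown forests distribute substantial impurity credit over noise
   features (every deep spurious split counts), which inflates the mean and
   can push a genuinely predictive but weak descriptor below the 1.5×-mean
   cutoff. Permutation importance scores noise features near zero because
   shuffling them leaves out-of-bag accuracy unchanged. Impurity importance
   is available via `importance_type = "impurity"`. If the cutoff would
   empty the set, the single best feature is kept with a warning.
4. **Recursive feature elimination with CV** (`cv_folds = 10`): features
   are removed one per step (the least important under a refitted forest),
   and every intermediate set is scored by k-fold cross-validated
   label-based accuracy under one shared fold assignment. The full score
   curve is returned — the plateau is the useful diagnostic — and the
   best-scoring count wins, ties preferring fewer features.
5. **Sequential forward selection** (`sfs_keep = 10`, `sfs_repetitions =
   5`): greedy addition of the feature that maximizes mean CV label-based
   accuracy, repeated five times with re-shuffled folds and re-seeded
   ensembles.
6. **Overlap consensus** (`overlap_min_count = 3`, `overlap_cap = 10`):
   features appearing in at least 3 of the 5 repetition lists survive; if
   more than 10 do, the best by (count, then earlier mean selection
   position, then column order) are kept. When fewer repetitions than the
   configured count are run, a majority of the available lists is required
   instead.

The SFS stage draws its candidates from the importance-filter set (stage 4
is recorded in the trace but does not constrain stage 5 by default;
`sfs_input = "rfecv"` switches this). The ensembles use 50 trees by
default — importance rankings on descriptor tables of this size are stable
well below that, and the repeated cross-validated stages dominate the
pipeline's cost, so larger ensembles buy accuracy nowhere it matters.
Model-based stages require complete columns and fail with a diagnostic
naming the offending columns; the rank-correlation stages use
pairwise-complete observations.

The whole pipeline is a pure function of (data, labels, configuration):
stage seeds are fixed offsets of the configuration seed, ranger is run
single-threaded with pinned seeds, and prediction tie-breaks are pinned
(ranger breaks classification vote ties from the global RNG; the package
wraps predictions in a fixed-seed context).

## The multi-output decision tree

The final classifier is a single CART grown jointly on both labels: the
impurity of a node is the mean of the two per-label binary Gini (or
entropy) impurities, so a split must pay off on average across outputs.
This matches the usual multi-output tree construction and keeps one
interpretable model rather than two. Leaves store per-label class-1
proportions; prediction thresholds them at 0.5, with a tie at exactly 0.5
classified positive (a fixed, testable convention). `max_features = "auto"`
is interpreted as `sqrt` — the historical meaning of that token in the
stack this grid imitates — and is documented because the token alone is
ambiguous. Splits stop on purity, `max_depth`, `min_samples_split`,
`min_samples_leaf`, or when no split achieves a positive impurity decrease
(tolerance 1e-12; split thresholds are midpoints between adjacent sorted
values; ties prefer the earlier feature and the smaller threshold).

Grid search evaluates the conventional CART grid (criterion × max_features
× min_samples_split ∈ {2,3,5,8,10,20,40} × max_depth ∈ 3..29 ×
min_samples_leaf ∈ {1..5,10,20,40}) by mean k-fold CV label-based accuracy
under one shared fold assignment, breaking ties toward smaller depth and
then grid order. The depth validation curve reports train/validation means
± SD per depth and recommends the smallest depth within `tolerance`
(default 1 percentage point) of the best validation score — the
interpretability trade-off read directly off the curve.

### How deep must the tree be?

The expert rule itself is an instructive test case. Classifying a compound
GC-amenable requires four comparisons (boiling point twice, MW, logP), and
settling its LC label requires a fifth (logP against 5.91). A single tree
must settle *both* labels on every root-to-leaf path, so representing the
rule exactly needs depth-5 paths. On noiseless synthetic data a depth-5
tree reaches ≈99.8% held-out label-based accuracy, while the best possible
depth-4 tree is structurally capped near 98.9% (one leaf must mix either
the MW cap or the LC threshold). The package's tests assert these
attainable properties; with 5% label noise the validation curve flattens
much earlier, and a depth of 4 is the parsimonious recommendation.

## The synthetic generator

`generate_descriptors()` emulates the statistical structure of a labeled
descriptor table without any chemistry: three informative latent
descriptors — boiling point uniform on 0–600 °C, molecular weight
log-uniform on 50–1500 Da, logP uniform on −5 to 12, fixed constants chosen
to straddle every rule threshold so all four label combinations occur —
generate labels through the expert rule, then each label bit is flipped
independently with probability `label_noise`. Around them: redundant
columns (a strictly monotone transform — scale/shift, exponential, or cube
— of a jittered copy of a random informative column; the jitter is applied
on the parent scale *before* the transform so the rank correlation with the
parent stays above 0.95 by construction), quasi-constant columns (one value
planted in >99% of rows), and independent Gaussian noise columns. The
default configuration (2000 compounds, 5% label noise, 10 redundant, 5
quasi-constant, 50 noise columns) is the study condition used by the
package's recovery simulations.

What the generator does *not* emulate: correlated noise blocks, heavy-tailed
descriptor distributions, systematic missingness, or the fact that real
descriptors are deterministic functions of structure (so "label noise" in
real data comes from curation and platform limits, not random flips).
Passing recovery tests therefore demonstrate that the pipeline's logic is
sound under planted structure, not that eight specific descriptors would be
selected from any particular real table.

## The comparison protocol

Classifier/feature-set comparisons run under repeated k-fold
cross-validation (by default 10 × 10): repetition r shuffles folds with
seed + r, and all methods share each repetition's fold assignment, so the
resulting accuracies are paired block by block. On such blocks:

* **Friedman test** with within-block average ranks and the standard tie
  correction; Kendall's coefficient of concordance is derived as
  W = Q / (n(k−1)).
* **Nemenyi post hoc**: mean-rank differences against the studentized range
  distribution (SE = √(k(k+1)/12n)); the p-value matrix is symmetric and
  reported uncapped, with an optional conventional 0.900 display cap in the
  print method.
* **Wilcoxon signed-rank** (one- or two-sided): zeros dropped (the classic
  treatment), average ranks for ties, exact p by enumeration of the sign
  patterns up to 20 nonzero pairs (a convolution over doubled ranks, so
  ties are exact too), normal approximation with continuity correction and
  tie-adjusted variance beyond. Effect sizes: matched-pairs rank-biserial
  correlation (W⁺−W⁻)/(W⁺+W⁻) and the all-pairs common-language effect
  size.
* **McNemar test** on the discordant counts of two classifiers per label,
  continuity-corrected by default (both variants exposed and named in the
  output); the odds ratio b/c is the effect size, with the Haldane +0.5
  correction when a discordant count is zero.

## Problem sizes used by the tests and acceptance script

The recovery simulations run the full pipeline on the study conditions
(n = 2000, 3 + 10 + 5 + 50 columns, 5% label noise) over 25 master seeds
and require all three informative features in the final set in at least 90%
of them; the type-I calibration uses 2000 null Wilcoxon comparisons of 30
paired scores; metric-vs-oracle checks use 1000 random instances each; the
noiseless tree-recovery check uses 4000 compounds with a 25% holdout; and
the end-to-end study uses 3 repetitions of 10-fold CV. These sizes are the
package's chosen defaults for a single-CPU run and are stated here so the
reported rates can be read with their resolution in mind.

## Known limitations

* Descriptor computation from structures (SMILES → descriptors) is out of
  scope; the package consumes precomputed tables.
* The correlation filter's retained set depends on column order by design
  (both documented keep rules are deterministic, but neither claims to
  reproduce any particular historical ordering).
* The final tree is a single axis-aligned CART by choice — the point is an
  interpretable router, not maximal accuracy; the ensembles are used only
  inside feature selection.
* ROC analysis for a hard-threshold rule classifier degenerates to a
  one-point curve; the package computes it from binary predictions (AUC =
  balanced accuracy) but makes no claim of comparability with score-based
  ROC curves.
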