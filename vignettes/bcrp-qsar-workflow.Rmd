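---
title: "Building and validating BCRP inhibition classifiers with bcrpqsar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and validating BCRP inhibition classifiers with bcrpqsar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcrpqsar)
```

## The modeling problem

BCRP (ABCG2) is an efflux transporter whose inhibition matters both for
multi-drug resistance in chemotherapy and for drug–drug interactions.
Experimental inhibition data are heterogeneous: concentration–response
indices (IC50/EC50 in µM), single-concentration %inhibition readings, and
qualitative activity calls from different assays and sources. `bcrpqsar`
turns such records into a binary classification dataset and carries it
through feature computation, feature selection, model building, validation,
domain-of-applicability assessment and structural interpretation.

## Curation rules

Records are converted to labels by fixed decision rules:

* IC50/EC50 `< 10` µM → inhibitor (1); `> 50` µM → non-inhibitor (0);
  values in `[10, 50]` µM are excluded as assay-condition sensitive.
* %inhibition is used only at 10 µM: `> 50%` → 1, `< 25%` → 0, `[25, 50]%`
  excluded, any other concentration excluded.
* Qualitative outcomes: Active → 1, Inactive → 0,
  Inconclusive/Unspecified → removed.

Reading the strict inequalities literally, boundary values (exactly 10 or
50 µM, exactly 25 or 50%) fall into the exclusion windows. Replicated
IC50/EC50 measurements are averaged arithmetically before labeling; a
replicate set whose max/min ratio exceeds 10 (configurable) is treated as
discrepant and the compound excluded — the underlying notion of
"significant discrepancy" is not quantified anywhere authoritative, so we
fixed an order-of-magnitude rule. When a compound carries both quantitative
and qualitative evidence, quantitative wins (IC50/EC50 first, then
%inhibition, then outcome calls): thresholds on measured values are the
most objective rule available. Structure washing strips counter-ion
components without carbon, keeps a single organic component, and rejects
multi-organic mixtures and metal-organics; organic means built from
H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I. Duplicated canonical structures
with conflicting labels are removed entirely.

## Features and pre-filters

Descriptors and fingerprints are computed with OpenBabel (via
ChemmineR/ChemmineOB): continuous descriptors (`desc:` namespace — MW,
logP, an ESOL-style logS estimate, TPSA, molar refractivity, H-bond
counts, graph counts, Kier flexibility, aromatic atom/bond counts) and the
1024-bit FP2 path fingerprint (`fp:` namespace). The namespacing keeps the
pipeline feature-set agnostic: any continuous/binary feature table works.
The logS value is an estimate from a Delaney-type linear model on logP,
MW, rotatable bonds and aromatic proportion, chosen because no
experimental-solubility descriptor is available in the open toolchain.

Three pre-filters run in a fixed order, and each is idempotent:

1. columns with missing values are dropped at computation time;
2. near-zero-variance: a feature is removed if it has a single unique
   value, or if its most-common/second-most-common frequency ratio
   exceeds 95/5 *and* its percent-unique-values falls below 10 (the
   documented defaults of the classical filter);
3. correlation: greedy elimination of pairs with |Pearson r| > 0.90,
   dropping the pair member with the larger mean absolute correlation
   (ties keep the earlier column).

The stratified 4:1 split draws `floor(class_size / 5)` test compounds per
class; this floor rule is what makes a 1098/1701 dataset split exactly into
879/1361 training and 219/340 test compounds. Continuous features are then
z-scored with training-set statistics only (binary bits untouched);
z-scoring was chosen over range scaling because it keeps Euclidean
distances meaningful for the k-NN and SVM models, and the choice is
configurable.

## rfSA feature selection

The wrapper search couples simulated annealing with a random-forest
scorer. For each resample of a 5×5-fold scheme, a chain starts from a
random subset (each feature included with probability 0.2) and proposes
neighbors by toggling 1–3 features. A candidate is accepted whenever its
internal accuracy — the out-of-bag accuracy of a 100-tree forest fit on
the internal 4/5 — does not decrease, and otherwise with probability
`exp(−Δacc / T_i)` under geometric cooling `T_i = T0 α^i` (defaults
`T0 = 0.10`, `α = 0.99`). The exponential-with-geometric-cooling form is
the canonical acceptance schedule consistent with "probability depends on
the accuracy difference and the iteration"; both knobs are configurable,
and the limits are useful diagnostics: `T0 = 0` is greedy hill-climbing
(internal accuracy provably non-decreasing), `T0 = ∞` a pure random walk.
OOB accuracy was preferred over a further internal split because it uses
all internal rows and adds no variance from an extra partition.

External accuracy — prediction of the held-out fold — is tracked at every
iteration; the best iteration maximizes the mean external accuracy across
resamples (earliest on ties), and the final subset is re-derived by one
deterministic chain on the full training set up to that iteration. This
consolidation step is required because a resampled search produces one
subset per chain but the pipeline needs a single subset.

The reference chain length is 1000 iterations; the test suite runs scaled
searches (tens to hundreds of iterations, 3–6 chains) so the whole suite
stays desk-scale. The planted-subset benchmark in the acceptance tests
uses 5 informative features at Cohen's d = 1 among 45 unit-variance noise
features, 150 compounds per class, and 6 chains of 250 iterations — a
scale at which the search reliably recovers the informative subset while
running in about a minute per repetition.

## Models, tuning and consensus

Seven methods sit behind `classifier_spec()` / `train_classifier()` /
`predict_prob()`: Gaussian naive Bayes and RBF-kernel SVM (e1071),
distance-weighted k-NN (inverse-distance voting, implemented here because
no installed package provides weighted k-NN with class probabilities),
regularized logistic regression (glmnet), stochastic gradient boosting and
XGBoost (both via the xgboost library — SGB is gradient boosting with row
subsampling < 1, no column subsampling and no regularization penalty, the
classic SGB recipe), and a small feed-forward network. The network honors
fixed settings: ReLU hidden layers, an Adam-type adaptive-learning-rate
optimizer, and a hard epoch cap of 300; it is implemented in plain matrix
arithmetic so the pipeline has no deep-learning backend dependency, and
the other six methods never require it.

Hyper-parameters are tuned in two stages on the training set: a coarse
grid scored by mean five-fold CV MCC under fixed folds, then random
sampling inside the hyper-box spanned by the top quartile of grid points
(sequential zoom-in with a random surrogate — the guaranteed fallback when
no model-based optimizer is available). Class probabilities convert to
labels at the fixed threshold 0.5, with ties classified as inhibitor.

Two consensus rules combine aligned prediction sets with equal weights:
majority vote of labels (odd member count enforced to avoid ties) and
unweighted mean probability.

## Validation machinery

Random five-fold CV is stratified by class. Cluster CV builds
complete-linkage Tanimoto clusters on fingerprint bits, cuts the
dendrogram at distance 0.7 (we read "maximum distance between identified
clusters 0.7" as the cut height — complete linkage makes the cut height
exactly the maximal intra-cluster distance bound), and distributes whole
clusters across folds by randomized greedy size balancing (each shuffled
cluster joins the currently smallest fold), which yields near-equal fold
sizes without splitting any cluster. Cross-entropy residuals use the
natural logarithm with probabilities clipped at `1e-15`; the exceedance
curve (fraction of compounds with residual above a threshold) separates
models that share a confusion matrix but differ in confidence. MCC returns
0 when its denominator vanishes — the standard continuity convention for
an undefined correlation.

## Applicability domain

The domain model projects normalized training features onto the principal
components retaining ≥ 95% variance, fits a Gaussian product-kernel
density with Scott's bandwidth per component, and thresholds at the
minimum training density (quantile 0) so the training set is covered
completely by construction. Density estimation was chosen over
range/distance/leverage domains because it can flag internal empty regions
of feature space. All three knobs — retained variance, bandwidth rule via
the component standard deviations, threshold quantile — are arguments, as
the reference implementation of this idea lives in closed software and any
single choice is a modeling decision, not a ground truth.

## Interpretation

Permutation importance shuffles one feature column at a time (preserving
its marginal distribution), recomputes the mean cross-entropy loss, and
reports the difference to the baseline loss, averaged over 10 repetitions.
The difference (not the ratio) is reported so importances are comparable
across models with different baseline losses. An all-constant column is
unchanged by permutation, so its importance is exactly zero; no
conservation property is claimed for the sum of importances.

## Fragment enrichment

Each molecule is decomposed into ring assemblies (connected components of
the ring-bond subgraph, keeping atoms attached by double/triple bonds,
stripping single-bond substituents), bridge assemblies (ring systems in
which two smallest rings share ≥ 2 bonds), and Bemis–Murcko assemblies
(the leaf-pruned scaffold, emitted when it links ≥ 2 ring systems).
Presence is binary per compound, fragments are canonicalized, and
statistics are computed over the whole labeled dataset — per-class counts
only make sense against full class sizes. Fragments are ranked by
information gain within the strictly-more-frequent class (`F1 > F2` for
the inhibitor list, `F2 > F1` for the non-inhibitor list; ties belong to
neither). The misclassification analysis pools all three fragment kinds,
keeps fragments seen in ≥ 2 misclassified compounds and reports occurrence
ratios (percent of set) in training, test and misclassified sets.

## What the synthetic generators emulate — and what they do not

`gen_feature_table()` draws informative continuous features as
unit-variance normals with a class-mean shift equal to `effect_size`
(i.e., Cohen's d), noise features identically in both classes, and
fingerprint bits as Bernoulli draws with class-dependent rates. The
unit-variance choice makes separability analytic: a single feature at
d = 3 supports a univariate threshold with accuracy Φ(1.5) ≈ 0.933.
`gen_compound_library()` assembles real, parseable molecules from planted
ring-system scaffolds (default vocabulary: quinazoline, morpholine,
thiophene, piperazine, pyridine) at class-dependent inclusion rates, with
a fixed substituent vocabulary (methyl, chloro, methoxy) so decomposition
outcomes stay predictable; ground-truth membership columns ride alongside.
`gen_activity_records()` emits one fixture per curation branch together
with expected dispositions that curation itself never sees.

These generators exercise every code path and make planted signals
recoverable, but they do not mimic real chemical space: features are
independent given the class (no descriptor correlation structure),
molecules are small and regular, and class-conditional distributions are
clean. Passing tests therefore demonstrate correctness of the machinery,
not expected predictive performance on real BCRP data; absolute
performance on the original curated dataset additionally depends on
commercial descriptor sets not reproducible with open tools.

## Numerical and degenerate-input choices

* MCC zero-denominator → 0; cross-entropy clipping `1e-15`; natural log.
* Correlation filter errors on zero-variance columns (run the NZV filter
  first); normalization errors on zero-variance continuous features.
* Tanimoto of two empty fingerprints is 1 (identical objects).
* The AD fit errors when retaining the requested variance would need more
  components than compounds minus two.
* SA neighbor moves that would empty the subset are rejected; acceptance
  at `Δacc = 0` is certain (`exp(0) = 1`).
* Per-class test counts use `floor`; earliest-iteration tie-break in SA;
  earlier-column tie-break in the correlation filter.

## Problem sizes in the test suite

Unit tests run at 30–200 compounds per class with feature counts in the
tens; the acceptance suite uses 150/class for the SA benchmark, 400/class
for the high-separation classifier check, and 879/1361-sized feature sets
for the applicability-domain coverage computation. These sizes were chosen
so that planted effects are detectable at 3-sigma while the full suite
runs on a single CPU in well under half an hour.

## Known limitations

* Descriptors/fingerprints are OpenBabel's, not MOE's or PaDEL's; absolute
  metric values on the original dataset are not reproducible here, and the
  property comparison (`compare_property_distributions`) reproduces the
  methodology, not specific means.
* The bridged-ring detector uses a greedy smallest-ring basis; exotic cage
  systems may be classified differently than by commercial ring-perception
  tools.
* The probability-density domain is exact in the projected space only;
  directions discarded by the projection do not influence coverage.
* Qualitative-outcome curation cannot encode per-source author judgment
  beyond the Active/Inactive/Inconclusive/Unspecified vocabulary.
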