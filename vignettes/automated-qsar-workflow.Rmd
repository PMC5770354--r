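---
title: "The automated QSAR modeling workflow: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The automated QSAR modeling workflow: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autoqsar)
```

## The modeling problem

Quantitative structure–activity relationship (QSAR) modeling predicts a
compound's bioactivity against a protein target from numeric features of
its structure. `autoqsar` automates the full regression modeling cycle:
curation of compound–activity records, featurization, a modelability gate,
feature ranking and selection, model fitting, and externally validated
reporting with an applicability-domain check. The package is aimed at
modelers who want a reproducible, scriptable pipeline rather than a
point-and-click workflow: every stage is an exported function, every run is
reproducible from one integer seed, and every stage persists its artifact
to the working directory.

## Data curation

Input records carry an identifier, a SMILES string, an activity type (Ki,
Kd, IC50, EC50, AC50, ...), an activity value assumed to be a
concentration in nM, and optionally a publication year. Curation applies,
in order:

1. **Activity-type filter.** Mixing measurement types (e.g. Ki with IC50)
   in one regression response is not meaningful; only the requested type is
   retained.
2. **Missing and non-positive values.** The activity scaling below takes a
   logarithm, so values that are absent or \(\le 0\) are dropped.
3. **Canonicalization and desalting.** Each structure is replaced by the
   canonical SMILES of its largest organic fragment (most heavy atoms among
   fragments containing carbon), followed by charge neutralization, so salt
   forms and free bases collapse onto one parent structure. Unparsable
   SMILES and purely inorganic entries are rejected with a reason code.
4. **Deduplication.** Among records sharing a canonical structure, the one
   with the most recent year is kept — the most recent measurement is
   taken as the best available. When years tie or are absent, the record
   whose activity is the median of the group is kept (on even-sized groups
   both middle records are eligible and the lower original index wins).
   This keeps exactly one deterministic measurement per structure without
   inventing an averaged value that was never measured.

The curation log counts every dropped record per rule; the input size
always equals kept plus dropped, which the test suite asserts.

All structure handling runs through a single cheminformatics backend (an
RDKit bridge shipped with the package and invoked once per batch), so the
canonical-SMILES dialect is identical across curation, featurization and
later external prediction.

## Featurization

Two feature families are computed per compound: the backend's full
standard physicochemical descriptor set (about 210 descriptors), and any of
nine binary fingerprint families — `morgan` (circular, ECFP-like),
`feat_morgan` (FCFP-like), `atom_pair`, `torsion`, `path`, `avalon`,
`layered`, `maccs` (166 fixed keys) and `pattern`. The default is Morgan,
radius 2, folded to 1024 bits — the conventional ECFP4-style setting.
Blocks are concatenated into one matrix; constant columns are removed at
merge time (and logged) because the min–max scaling below is undefined for
them.

## Scaling and partitioning

Raw activities in nM are mapped to \([0, 1]\) by a piecewise logarithmic
transform: values at or above 10,000 nM (10 µM, essentially inactive)
score 0, values at or below 1 nM (maximally potent) score 1, and values
in between score \((4 - \log_{10} v)/4\). The transform is continuous at
both cut-offs and monotone, so a higher score always means a stronger
binder. Users with pre-normalized activities can skip it
(`activity_prescaled = TRUE`).

Compounds are split 75/25 into a training set and an Independent
Validation Set (IVS) by uniform random sampling. The IVS is never touched
by modelability estimation, ranking, selection or training.

Features are min–max scaled to \([0, 1]\), **fitted on the training
partition only** and applied unchanged to the IVS without clipping.
Fitting on the full dataset would leak the IVS geometry into training;
out-of-range IVS values are legitimate applicability-domain signal, not an
error. Columns that happen to be constant within the training partition
are removed from the run (and logged).

## Modelability gate (MODI)

Before any expensive modeling, the pipeline estimates whether the dataset
is modelable at all. The modelability index is the leave-one-out
coefficient of determination of a plain k-nearest-neighbour regressor on
the scaled training set: each compound's activity is predicted as the
unweighted mean of its k nearest neighbours (Euclidean distance over all
scaled columns, ties broken by lower row index), and the score is
\(1 - \sum_i (y_i - \hat y_i)^2 / \sum_i (y_i - \bar y)^2\). Both k = 3
and k = 5 are reported; the gate uses k = 5 and passes only when the score
strictly exceeds 0.45. Datasets dominated by activity cliffs — near
identical structures with divergent activities — score near or below zero
and are flagged before any model is built. In `halt` mode the pipeline
aborts with curation advice; in `warn` mode it proceeds with a logged
warning.

## Feature ranking by random-forest permutation importance

A regression random forest provides, per feature, the mean increase in
out-of-bag MSE when that feature is permuted (the raw, "unscaled"
importance \(VI(X_j)\)) and its standard error across trees (per-tree
standard deviation divided by \(\sqrt{ntree}\)). The "scaled" importance
is the z-score, raw importance over standard error. Because a single
forest is stochastic, the fit is repeated over the training portions of an
n-fold split of the training set (defaults: 10 folds, 500 trees,
\(p/3\) variables per split; run *t* uses seed *base + t*), and each
feature's scores are averaged over runs. For the scaled method the per-run
z-scores are averaged (a run with zero standard error contributes z = 0).
Ranking sorts descending by the active score, ties broken alphabetically,
and never eliminates features — selection is the next stage's job. Columns
are put in canonical (sorted) order before each forest fit, so rankings
are invariant to the input column order.

## Stepwise selection and model building

The training partition is split once more, 75/25, into an internal
sub-train/test pair, held fixed across all steps. Features are added to
the learner in ranked order (step size 1 by default; coarser steps always
still evaluate the final full prefix), and the internal-test RMSE is
recorded at each step. The selected feature set (SF) is the ranked prefix
at minimum RMSE, ties resolved toward fewer features; an optional
tolerance picks the smallest prefix within τ of the optimum (off by
default). The learner is ε-SVM regression with an RBF kernel by default
(cost 1, ε 0.1, kernel width 1/(current feature count) — the common
library conventions, all configurable), with a random-forest learner as an
alternative.

The final models — the full-feature model and one SF model per ranking
method — are refit on the whole training partition and scored on the IVS
with the proportion of variance explained,
\(PVE = 1 - \sum_i (y_i - \hat y_i)^2 / \sum_i (y_i - \bar y)^2\), and
\(RMSE = \sqrt{\tfrac1N \sum_i (y_i - \hat y_i)^2}\). Internal-test scores
are reported from a fit on the internal sub-train (replaying the stepwise
split), so internal and external numbers are directly comparable.

## Applicability domain

External predictions are only trustworthy near the training data. The
domain threshold is the mean plus \(Z\) standard deviations (default
\(Z = 0.5\)) of each training compound's Euclidean distance to its nearest
training neighbour, computed in the scaled feature space restricted to the
model's own features — the domain should be judged in the model's input
space. An external compound is flagged outside the domain when its
nearest-training distance strictly exceeds the threshold; a compound
exactly on the boundary is inside. Flagged compounds are reported, never
removed — the decision is the user's. The exact threshold form is a
design choice; mean + Z·sd of nearest-neighbour distances is the common
distance-based convention and Z is exposed in the configuration.

## The synthetic benchmark generator

Testing a pipeline like this against live ChEMBL retrievals would be
neither reproducible nor offline-safe, so the package ships a generator
whose ground truth is known by construction.

Real descriptor+fingerprint tables are strongly collinear: descriptor
families (size, lipophilicity, polarity...) move together and compounds
occupy a low-dimensional manifold inside a wide table. A k-nearest-
neighbour modelability estimate is only meaningful in such a geometry — in
a table of independent features, distances concentrate and no dataset
would ever look modelable. The generator therefore draws a few latent
"chemical" factors (default 4) and gives every feature a Gaussian-copula
loading on one factor, with uniform \([0,1]\) marginals. Collinearity is
heterogeneous, as in real tables: background features draw their squared
loading uniformly from 0.3–0.9, while the informative features use a
moderate 0.5 — activity depends on specific structural content, not only
on the global factors every feature shares. Half of the columns are
binarized at 0.5 to mimic fingerprint bits. The response is a weighted sum
of the informative features (plus an interaction and a quadratic term in
the nonlinear default), squashed to \([0,1]\), with Gaussian noise
(default sd 0.05) added and clipped. The activity-cliff variant arranges
compounds in near-duplicate feature pairs assigned activities near 0 and
near 1 — the canonical unmodelable geometry.

What the generator does **not** emulate: discrete chemical scaffolds,
heavy-tailed descriptor distributions, assay noise structure, or the
extreme sparsity of real fingerprint bits. Passing tests on it demonstrate
that the pipeline's machinery behaves as specified under a realistic
correlation geometry, not that any particular real target will reach a
given PVE.

A hand-curated list of ~40 drug-like SMILES with planted curation traps
(a salt form, duplicate structures with and without years, one invalid
SMILES, one missing value, records of a second activity type) exercises
every curation branch with exactly known outcomes.

## Numerical choices and degenerate inputs

* Distance ties in kNN resolve to the lower row index; ranking ties to the
  alphabetically first feature; RMSE ties in selection to the smaller
  subset. All outputs are deterministic given the base seed.
* The modelability gate uses a strict inequality (a score exactly at the
  threshold fails).
* Zero-variance columns are removed before scaling; a constant column
  reaching the scaler is an internal-consistency error, not a silent fix.
* Constant observed activities make PVE/MODI undefined and raise a domain
  error rather than returning NaN.
* Partitions clamp so both sides are non-empty and refuse datasets with
  fewer than 4 compounds; importance estimation refuses fewer than 10
  training rows.
* Every stochastic stage derives its seed from the base seed plus a fixed
  stage offset, so stages can be re-run in isolation and reproduce.

## Problem sizes used by the test suite

The bundled checks run the full machinery at deliberately compact sizes:
the reference benchmark is n = 300 compounds × p = 200 features with 10
informative features (ranking and selection checks use 5-fold importance
estimation with 500 trees; the selection-benefit check repeats the
modeling path over 10 generator seeds), pipeline orchestration checks use
n = 120 × p = 60, and formula oracles run on vectors up to n = 1000.
These sizes were chosen so the whole suite exercises every stage in a few
minutes while keeping the estimates' behaviour representative; nothing in
the implementation is specific to them.

## Known limitations

* Featurization requires the RDKit backend available as `python` on the
  PATH; purely feature-table workflows (`customized_features` mode) run
  without it.
* Only nM concentration units are accepted from activity payloads; other
  units are skipped with a log entry rather than converted.
* No stereochemistry standardization or tautomer canonicalization is
  attempted during curation.
* The stepwise wrapper is forward-only; backward elimination and per-step
  hyperparameter retuning are out of scope.
* MODI variants for classification problems are not implemented; the
  pipeline is regression-only.
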