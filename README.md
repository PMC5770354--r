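# autoqsar

An automated, reproducible pipeline for building and validating QSAR
(quantitative structure–activity relationship) regression models from
compound bioactivity data, for computational chemists and modelers who
want the full modeling cycle — curation, featurization, modelability
gating, feature selection, external validation — as scriptable R
functions rather than a point-and-click workflow.

## What it does

Given compound–activity records (a ChEMBL-style activity listing, a
CSV/SMILES/SDF file of structures, or a precomputed feature table), the
pipeline:

1. **Curates** the records: keeps one activity type, drops missing and
   non-positive values, canonicalizes and desalts structures (largest
   organic fragment + neutralization), and deduplicates by canonical
   structure (most recent year wins; median-activity representative on
   ties), with a log that accounts for every dropped record.
2. **Featurizes** structures through an RDKit backend: ~210
   physicochemical descriptors plus any of nine fingerprint families
   (Morgan, FeatMorgan, AtomPair, Torsion, path-based, Avalon, Layered,
   MACCS, Pattern; default Morgan radius 2, 1024 bits).
3. **Scales and partitions**: activities map to [0, 1] by the piecewise
   log transform *sp(v)* = 0 for v ≥ 10,000 nM, 1 for v ≤ 1 nM, else
   (4 − log₁₀ v)/4; compounds split 75/25 into training set and
   Independent Validation Set (IVS); features are min–max scaled with
   parameters fitted on the training partition only.
4. **Gates on modelability (MODI)**: the leave-one-out k-nearest-neighbour
   coefficient of determination on the scaled training set
   (k = 3 and 5 reported). A dataset passes only if MODI(k=5) > 0.45;
   activity-cliff-dominated datasets fail here before any model is built.
5. **Ranks features** by random-forest permutation importance — raw
   out-of-bag MSE increase VI(Xⱼ) ("unscaled") and its z-score
   Zⱼ = VI(Xⱼ)/(σ̂/√ntree) ("scaled") — averaged over n-fold repeated
   fits.
6. **Selects features stepwise**: ranked features are added one at a time
   to an RBF-SVM regressor and the internal-test RMSE curve is traced; the
   selected set (SF) is the prefix at minimum RMSE.
7. **Validates externally**: the full-feature model and the SF models are
   refit on the whole training partition and scored on the IVS with
   PVE = 1 − Σ(yᵢ−ŷᵢ)²/Σ(yᵢ−ȳ)² and RMSE = √(Σ(yᵢ−ŷᵢ)²/N), and every
   IVS compound gets an applicability-domain flag from its Euclidean
   nearest-training-neighbour distance (threshold: mean + Z·sd of training
   NN distances).

Every stage persists its artifact (CSV/JSON/PNG) into the working
directory, every stochastic step derives its seed from one base seed, and
persisted model bundles re-predict bit-identically.

## Worked example

```r
library(autoqsar)

# a synthetic benchmark with 10 known informative features out of 100
d <- make_regression_dataset(n = 200, p = 100, n_informative = 10, seed = 42)
write.csv(data.frame(compound_id = names(d$activity),
                     activity_value = unname(d$activity),
                     as.matrix(d$features), check.names = FALSE),
          "benchmark.csv", row.names = FALSE)

cfg <- qsar_config("customized_features", workdir = "run",
                   input_path = "benchmark.csv", nfold = 5, ntree = 500,
                   activity_prescaled = TRUE, seed = 42)
run <- run_pipeline(cfg)
print(run)
```

```
[partition] 150 training / 50 IVS compounds
[modelability] MODI(k=3)=0.473 MODI(k=5)=0.534 gate=pass
[stepwise_scaled] selected 10 features (internal RMSE 0.0752)
[stepwise_unscaled] selected 16 features (internal RMSE 0.0785)
qsar_run in run
MODI(k=5) = 0.534 (passed)
       model           set  n n_features       pve       rmse
        full internal_test 38        100 0.6773051 0.10976706
        full           ivs 50        100 0.6798795 0.10867924
   sf_scaled internal_test 38         10 0.8486358 0.07517746
   sf_scaled           ivs 50         10 0.8616960 0.07143437
 sf_unscaled internal_test 38         16 0.8350792 0.07847182
 sf_unscaled           ivs 50         16 0.8492434 0.07458096
```

MODI(k=5) = 0.53 clears the 0.45 gate, so the dataset is worth modeling.
The stepwise wrapper reduces 100 features to 10 (scaled ranking) and 16
(unscaled), and both selected-feature models beat the full model on the
never-touched IVS (PVE 0.86 vs 0.68, RMSE 0.071 vs 0.109) — the expected
signature of successful feature selection. `run/` now holds the MODI
report, importance table, stepwise traces and plots, validation and AD
reports, and three reusable model bundles; `predict_external()` scores new
compounds against any of them with an in/out-of-domain flag per
prediction.

A command-line interface wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/autoqsar.R", package="autoqsar"))')" \
    simulate --type regression --out benchmark.csv
```

with `run` (YAML config) and `predict` subcommands; exit code 3 signals a
modelability-gate halt.

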