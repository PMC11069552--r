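# dacl

Binary disease prognosis on mixed-type clinical record tables, as one
seed-reproducible pipeline: auto-encoder imputation of missing cells,
wrapper feature selection by a golden flower search, classification by a
collaborative bias-integrated conditional GAN whose coupling weight is
tuned by an intelligent-water-drops graph search, and a full
confusion-matrix metric suite. The package is aimed at methodologists who
want each of these components as a tested, composable R function — and a
synthetic stroke-style cohort generator with a planted signal that makes
every claim checkable against ground truth.

## The methods in brief

**Imputation.** A single-hidden-layer auto-encoder over the encoded table:
encoder `b = σ(ωᵀa + β)`, decoder `ω′ᵀb + β′` with identity outputs on
continuous coordinates and sigmoids on binary/one-hot ones. Training
minimizes the masked reconstruction loss over observed cells only —
squared error on continuous, cross-entropy on discrete coordinates — with
iterative re-feeding of the current reconstruction into the missing
inputs. A held-out set of observed source cells selects the best epoch and
calibrates a per-column shrinkage toward the column mean, so columns
without predictive structure are not polluted by fitting noise.

**Feature selection.** Flower-pollination search in `[0,1]^d`: global
moves are tangent flights `G′ = G + s·S·tan(θ)·(G − τ*)` with a
Pareto-drawn step magnitude `S` and `θ ~ U(−π/2, π/2)` (heavy-tailed, sign
alternating); local moves are golden-section line searches (probes at
0.618/0.382 of the bracket) along the segment to another pollen. Subsets
are scored by `w_a · CV-accuracy + (1 − w_a)(1 − |S|/d)` with a
deterministic ridge classifier under stratified k-fold CV.

**Classification.** A conditional generator (noise embedding + label
embedding, summed), a discriminator, and an auxiliary classifier trained
in two adversarial pairings per batch; the generator loss
`CE(D(fake), 1) + δ·CE(clf(fake), label)` couples generation to the
classifier. Minority classes are rebalanced with generated samples and the
classifier head is fine-tuned on the balanced data.

**Tuning.** δ is chosen by an intelligent-water-drops search over a
layered candidate graph: drops prefer low-soil edges
(`p ∝ 1/(ε + soil)`), erode soil as they pass
(`soil ← (1−g_y)·soil − g_y·Δ`), and the iteration-best path is
reinforced; path quality is the held-out log-likelihood of a short
training run, cached per configuration.

**Evaluation.** Accuracy, precision, recall/sensitivity, specificity, F1,
NPV, MCC, fall-out and miss rate from the confusion counts, plus
trapezoidal ROC/AUC (equal to the pairwise concordance probability,
ties rank-averaged).

## A worked example

```r
library(dacl)

cfg <- pipeline_config(cohort = high_signal_config(seed = 11),
                       global_seed = 42)
report <- run_pipeline(cfg)
report
```

```
DACL pipeline report
  train/test: 900 / 300 rows
  selected features: age, hypertension, heart_disease, avg_glucose, bmi 
  tuned delta: 0.01 
  accuracy 0.9167 | sensitivity 0.8868 | specificity 0.9330 | F1 0.8826 | AUC 0.9773
  cohort Bayes accuracy estimate: 0.9303 (prevalence 0.354)
```

The generated cohort plants a five-factor logistic signal (age,
hypertension, heart disease, glucose, BMI) in a stroke-style record table
with 10% missing cells. The pipeline imputed the gaps, recovered all five
planted risk factors and nothing else, tuned the generator-classifier
coupling to δ = 0.01, and reached held-out accuracy 0.917 against the
cohort's Bayes ceiling of 0.930 — the residual gap is the honest price of
finite data, imputation and selection. `predict(report, new_table)`
classifies further tables from the same schema.

Each stage is equally usable on its own — `generate_cohort()`,
`train_daem()`/`impute()`, `select_features()`, `train_colbgan()`/
`augment_minority()`, `tune_loss_parameter()`, `confusion()`/
`classification_metrics()`/`roc_auc()` — and a thin command-line wrapper
(`inst/cli/dacl.R`, subcommands `generate | impute | select | tune |
train | evaluate | run`, YAML config) drives the same functions from a
shell.

See `vignettes/dacl-methods.Rmd` for the models, their assumptions, the
defaults and their rationale, and known limitations.

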