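---
title: "Self-stacking ensembles for imbalanced clinical cohorts: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-stacking ensembles for imbalanced clinical cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selfstack)
```

## The problem

Thyroid screening cohorts are a canonical case of extreme class imbalance:
in the panel this package is modelled on, healthy ("no condition") records
outnumber the largest disease class by more than 15:1 and the smallest
usable disease class by almost 30:1. A classifier fit to such data can score
high accuracy while missing most disease records, because accuracy is
dominated by the majority class. The package implements a protocol that
confronts this twice over: by *balancing* the data (down-sampling) before
training, and by *scoring* with macro-averaged one-vs-rest metrics that give
every class equal weight.

## The self-stacking model

Stacked generalization trains base learners, collects their predictions as
features, and trains a meta-learner on those features. Classical stacking
uses heterogeneous base learners; the self-stacking classifier (SSC) here
uses *homogeneous* ones — `m = 4` random forests that differ only in their
derived random seeds — and a fifth forest as meta-learner. The rationale is
pragmatic: on mixed binary/continuous clinical tables, tree ensembles are
reliably the strongest single family, and stacking several randomizations of
the same strong family lets the meta-learner arbitrate the cases where the
randomizations disagree.

The critical construction is the meta-feature matrix. For `k` folds
(default 5), each base learner is refit `k` times on a fold's complement
and predicts the held-out fold; row *i*'s meta-feature from learner *j* is
therefore always produced by a model that never saw row *i*. Without this,
the meta-learner would be trained on base-learner *fits* rather than
base-learner *generalization*, and would inherit their overfitting — the
package's test suite demonstrates the failure mode with a "memorizing"
stub learner whose out-of-fold meta-features collapse to chance accuracy
while its in-sample predictions are perfect.

Two encodings of the meta-features are supported. In `label` mode (the
default, matching the construction above) each base learner contributes its
predicted class, which is one-hot encoded before reaching the meta-learner
so that no artificial ordering of the diagnosis codes is introduced. In
`proba` mode each learner contributes its full class-probability vector
(`m * C` columns). After the meta-learner is fit, the base learners are
refit on the full training set for inference — the standard resolution of
the fact that fold-wise models exist only to produce unbiased meta-features.

Self-voting ensembles (SVEC) are the simpler cousins: `n_base = 3` forests
with distinct derived seeds, combined either by majority vote on labels
(hard) or by argmax of the summed probability vectors (soft). All ties —
hard-vote ties, soft-vote ties, and probability-argmax ties inside any
learner wrapper — break to the lowest class index, deterministically.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `m` (stack) | 4 | base learners; the pseudocode convention for the stack |
| `k` (stack) | 5 | folds for out-of-fold meta-features; any value ≥ 2 works, 5 is standard stacking practice |
| `n_base` (vote) | 3 | voting members |
| `min_class_size` | 200 | class-selection support threshold |
| `per_class_n` | 230 | records kept per selected class (keep-first-N, file order) |
| split `ratio` | 0.2 | held-out test fraction (80:20) |
| CV `k` | 10 | cross-validation folds |
| `alpha` | 0.05 | t-test significance level |

Base-learner defaults are the tuned settings of the evaluation protocol:
random forest with 200 trees and depth cap 50; gradient boosting with 50
rounds, learning rate 0.2, depth cap 200; SAMME boosting of stumps with 300
estimators and learning rate 0.8; multinomial logistic regression with
inverse regularization C = 3 (mapped to weight decay 1/C); linear SVC with
C = 1. The number of folds inside the stack is deliberately configurable
because only "k-fold" is conventionally specified; 5 was fixed once as the
default and not revisited.

## Design choices that were genuinely open

* **"First N" means file order.** The down-sampler keeps each selected
  class's first `per_class_n` records in the order they appear in the
  source table, with no shuffling or deduplication beforehand. This is the
  only reading that is deterministic and reproducible; a prepended record
  of class *c* changes the kept window for *c* and for no other class
  (tested as a property).
* **Shortfall is an error.** Asking for 230 records from a class with 150
  errors rather than silently truncating; an explicit `allow_short` flag
  downgrades this to a logged warning.
* **Preprocessing.** The raw dialect leaves preprocessing unspecified, so
  the encoder does the minimal deterministic thing: t/f (and F/M) → 1/0,
  first-appearance integer codes for the referral source, median imputation
  for continuous columns, mode imputation for binary/categorical, identifier
  columns dropped, constant columns dropped (they carry no signal; the
  mostly-missing TBG column is instead retained and imputed unless
  explicitly placed on the policy's drop list). A completely missing column
  is an error — there is no statistic to impute from.
* **Multi-label records.** Compound diagnosis codes (e.g. `AK`) are
  decomposed per character by the parser, and such records are excluded
  from modelling cohorts with a message — the task is single-label
  multi-class, and silently keeping or dropping them would both be wrong.
* **Splits are not stratified.** The 80:20 split permutes rows with a
  seeded generator and cuts the tail, so per-class test counts vary around
  their expectation; without shuffling the tail is taken as-is. Both are
  deterministic given the seed.
* **The t-test convention.** Model comparisons use a paired t-test over
  each model's eight evaluation scores: accuracy and the three macro
  metrics, under the original and the down-sampled setting — the pairing
  that yields df = 7. An unpaired Welch alternative is provided
  (`unpaired_ttest()`) for score vectors that are not naturally paired.
  Degenerate cases are reported, not errored: identical vectors give t = 0
  (p = 1); zero-variance non-zero differences give an infinite t (p = 0).
  No statistical-power calculation is provided.
* **Seed discipline.** Every stochastic component takes an explicit seed;
  ensemble member *j* derives `master_seed + j`, the meta-learner uses
  `master_seed`, and fold assignment is drawn once under `master_seed`.
  Identical seeds yield bit-identical meta-features, predictions, fold
  assignments and generated cohorts (RNG kind pinned to Mersenne-Twister
  with rejection sampling).

## Numerical conventions

Zero-denominator metrics are defined as 0: a class never predicted has
precision 0, a class with no true instances has recall 0, and F1 is 0 when
both are 0. This matters under severe imbalance, where linear baselines can
miss whole classes. Report tables round half *away from zero* at two
decimals (three where needed), because base R's round-half-even would make
printed-table comparisons ambiguous — `round_half_up(0.995, 2)` is 1.00.
Cross-validation reports the sample (n−1) standard deviation. Wall time is
recorded in CV results but deliberately excluded from written report files
so reruns with one configuration are byte-identical.

## What the synthetic generator does and does not emulate

The generator reproduces the *structure* that the pipeline must survive:
the printed class skew (6771/436/359/346/233 for the five modelling
classes), a mix of strictly positive hormone-like continuous features
(log-normal, so the encoder sees realistic skewed marginals), t/f flag
features, `?` missing tokens in continuous columns, and the raw file
dialect itself, so reading, encoding, balancing and splitting are exercised
end-to-end. Class separation is synthetic: each class carries a distinct
bit pattern shifting continuous means (in SD units on the log scale, via
`effect_size`) and skewing flag probabilities (via `flip_rate`). Defaults
were fixed once at `effect_size = 1`, `flip_rate = 0.3`,
`missing_rate = 0.03` — overlapping classes, so that ensemble improvements
have room to show, with missingness frequent enough to exercise imputation.

What it does **not** emulate: the real panel's covariance between hormones
(TSH–TT4 coupling and the like), the measured/value indicator pairing, the
concentration of missingness in specific assays (real TBG is missing almost
everywhere), or any label noise. Consequently, passing tests show that the
*machinery* is correct — balancing arithmetic, leakage-free stacking,
metric identities, protocol determinism — and that the ensembles behave
sensibly at both ends of a separability dial (chance at zero effect, ≥ 0.95
on the separable preset). They do not certify the headline accuracy
achievable on the real clinical panel; with the real file ingested via
`read_thyroid_table()`, the identical pipeline applies and the balanced
counts (5 × 230) reproduce exactly.

Problem sizes used throughout the tests and the acceptance script were
chosen as the smallest that make each property visible: the full 8145-row
skewed cohort wherever the balancing arithmetic itself is under test, the
balanced 1150-row working size for model evaluation and 10-fold CV, and a
few hundred rows for stub-based properties.

## Known limitations

* Homogeneous stacking only; mixing families across base learners is
  expressible through the spec mechanism but untested and unsupported.
* No probability calibration; soft voting consumes raw model probabilities.
* No SMOTE/over-sampling/class-weighting alternatives — down-sampling is
  the protocol's chosen balancing method.
* `kfold_cv` stratifies nothing; with very small minority classes a fold's
  training complement can miss a class entirely (the stack warns and pads
  probabilities with zero).
* The AdaBoost implementation is SAMME on stumps; SAMME.R (probability
  boosting) is not provided.
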