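---
title: "Consensus machine learning for multigeneration reproductive toxicity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus machine learning for multigeneration reproductive toxicity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgrtox)
```

## The problem

Guideline rat multigeneration reproductive (MGR) toxicity studies dose two
or more generations of animals and score reproductive endpoints; they are
slow, expensive, and ethically costly. `mgrtox` implements an in-silico
screening pipeline for this endpoint: chemicals are represented by numeric
molecular-descriptor tables (Mold2-style, 777 columns nominally), a binary
label marks whether a reproductive lowest-observed-adverse-effect level
(LOAEL, mg/kg/day) was recorded, and seven classification algorithms plus a
majority-vote consensus predict that label from structure-derived
descriptors alone. Descriptor computation itself (Mold2) is an upstream
black box: this package consumes its output as delimited tables.

The package is organized the way the analysis proceeds: synthetic data
generation (`generate_study()`), I/O and dataset assembly (`join_dataset()`),
three-stage descriptor selection (`filter_descriptors()`), base learners
(`fit_learner()`), consensus (`consensus_vote()`), tuning (`tune_learners()`),
repeated cross-validation (`run_repeated_cv()`), confidence profiling
(`bin_by_confidence()`), LOAEL stratification
(`loael_stratified_sensitivity()`), and applicability-domain analysis
(`applicability_domain()`). `run_pipeline()` orchestrates all stages and
writes machine-readable reports; each stage is equally usable on its own,
which is why no shell wrapper is shipped — the exported functions are the
command surface.

## Descriptor selection

Three stages, applied in order to the training table only:

1. **Sparse filter.** A descriptor that is exactly zero for *more than* 90%
   of training chemicals is removed (strictly greater: zero in 90 of 100 is
   kept). Mold2-style tables contain many count-type columns that are zero
   for almost every chemical and carry no signal.
2. **Shannon entropy.** Each remaining descriptor's range (training minimum
   to maximum) is divided into 20 even bins; with bin occupancies
   $p_1,\dots,p_{20}$ the entropy is $H = -\sum_i p_i \log_2 p_i$ (with
   $0\log_2 0 = 0$). Descriptors with $H < 2.5$ bits are removed. The top
   bin is right-closed so the maximum value lands in bin 20 rather than in
   a phantom 21st bin. Equality at 2.5 is kept: the verbal rule pair
   ("greater than 2.5 kept", "less than 2.5 removed") leaves the boundary
   undefined, so we chose the inclusive side and record the convention in
   every `filter_report`.
3. **Tree-frequency importance.** Repeated 5-fold cross-validation fits a
   decision tree (DT), a decision forest (DF) and a random forest (RF) on
   each leave-one-fold-out part and records which descriptors each fitted
   model actually splits on. Frequency = number of fitted model instances
   using the descriptor, per algorithm; importance = frequency divided by
   the maximum frequency of that algorithm; overall importance = mean over
   the three algorithms. Descriptors with overall importance strictly
   above 0.2 are kept.

Stages 1–2 never see the labels, so any label permutation leaves their
output bit-identical — an information-leak guard that the test suite
asserts. Stage 3 legitimately uses labels, which is why it sits inside the
training side of every evaluation split.

**A counting subtlety.** Because stage 3 counts usage once per fitted
*model*, an unconstrained random forest would touch nearly every descriptor
in at least one of its trees and the RF column would carry no contrast.
The stage-3 RF therefore defaults to a deliberately shallow forest
(`ntree = 10`, `maxnodes = 4`); the DT uses standard `rpart` pruning and the
DF is naturally selective because its trees must use disjoint descriptors.
These parameters are exposed (`dt_params`, `df_params`, `rf_params`) and
recorded in the report. At realistic table widths (hundreds of descriptors)
the contrast is robust to these choices; at a few dozen descriptors a deep
forest would flatten it.

## The seven learners and their probability contracts

Every learner returns the probability that a chemical is positive
(reproductive-toxic), with fixed semantics:

| algorithm | probability of the positive class |
|---|---|
| DT | positive proportion in the terminal node |
| DF | mean of per-tree terminal-node proportions |
| RF | fraction of trees voting positive |
| kNN | fraction of positives among the $k$ nearest neighbors |
| SVM | Platt sigmoid $1/(1+e^{Af+B})$ of the margin $f$ |
| LDA | two-class posterior (sigmoid of the discriminant) |
| LR | $1/(1+e^{-(a\cdot x+b)})$ |

Decisions worth flagging:

* **LDA.** An unnormalized exponential $e^{a\cdot x+b}$ is unbounded and
  cannot be a probability; the standard two-class posterior is the only
  probability-valued reading, and the deviation is noted in the run
  manifest.
* **SVM.** The kernel is RBF and Platt's $A,B$ are fitted by maximum
  likelihood (BFGS on the regularized-target log-loss) on decision values
  obtained from an internal 5-fold cross-validation — calibrating on
  resubstitution margins would be optimistically biased. The calibration
  folds are seeded from the learner seed, so fits are deterministic.
* **LR.** Fitted as ridge-penalized logistic regression (`glmnet`,
  $\alpha=0$) with a small default penalty (`lambda = 0.01`); the penalty
  strength is a tuning-grid dimension.
* **Scaling.** kNN, SVM, LDA and LR consume descriptors standardized by
  training mean/sd (distance- and margin-based methods are scale-sensitive
  and Mold2-style columns span orders of magnitude); tree-based learners
  consume raw values, to which they are invariant.
* **Decision Forest.** Trees are grown sequentially with `rpart`; after
  each tree the descriptors it used are withheld from all later trees, so
  tree descriptor sets are pairwise disjoint and each signal axis is spent
  exactly once. If descriptors run out before the requested number of
  trees, the forest stops early with a warning; fewer than two growable
  trees is an error.

Classification thresholds at 0.5, with 0.5 itself called positive (0.5 is
the minimum probability at which a chemical is called toxic).

## Consensus

With $N^+$ of the 7 base votes positive, the consensus label is positive
iff $N^+ > 3$, and the consensus probability is

$$P = \begin{cases} 1 - (7-N^+)/8 & N^+ > 3\\ N^+/6 & N^+ \le 3\end{cases}$$

This is implemented exactly as designed, including its one wrinkle: at
$N^+ = 3$ the probability is 0.5 while the label is negative, which
conflicts with the "probability ≥ 0.5 ⇒ positive" convention used for base
models. We preserve the published behavior (label negative, probability
0.5, confidence 0) rather than smooth it over; the run manifest flags it.
Consensus over any other number of models is refused — the probability
formulas hard-code seven voters — and with seven voters no tie is possible.

## Tuning and evaluation

Hyperparameters are selected on a class-stratified 80% subset drawn once
from the master seed: for each candidate setting, five repeats of 5-fold
cross-validation are run, the Matthews correlation coefficient (MCC) is
computed on the pooled held-out predictions of each repeat, and the setting
with the highest mean MCC wins (ties broken by grid order, recorded). MCC
is the tuning criterion because the class balance (roughly 1:2) biases
accuracy toward negatives while balanced accuracy overcorrects. The MCC is
computed per repeat on pooled predictions rather than per fold then
averaged; with 5 folds of ~44 chemicals, per-fold MCCs are noisy and
occasionally undefined.

Model evaluation is repeated $k$-fold cross-validation: per iteration a
fresh unstratified random fold plan (iteration-indexed seed), all seven
models fitted per leave-one-fold-out part, consensus votes combined per
chemical *within* the iteration, and the seven metrics computed on the
iteration's pooled predictions. Aggregates are means and standard
deviations over iterations. The seven metrics are accuracy, sensitivity,
specificity, balanced accuracy, positive/negative predictive rates, and
MCC with the standard denominator
$\sqrt{(TP\!+\!FP)(TP\!+\!FN)(TN\!+\!FP)(TN\!+\!FN)}$ (a printed variant
that repeats two factors is not the Matthews coefficient and can exceed 1,
so the standard form is used and the deviation recorded). Conventions for
degenerate denominators: MCC is 0; ratio metrics are undefined (`NA`) and
excluded from aggregation, never reported as 0.

External validation refits all seven models on the full training set and
predicts the external cohort once; overlapping chemical IDs are refused
because an external set sharing chemicals with training is not external.

**LOAEL stratification.** Positives are split at 100 mg/kg/day into strong
(≤ 100) and weak (> 100) toxicants and sensitivity is recomputed per model
within each stratum from the same prediction log. Empty strata are
undefined, not zero.

## Prediction confidence

Confidence is $|p - 0.5|/0.5 \in [0,1]$. The printed signed form
$(p-0.5)/0.5$ is negative for predicted negatives while the quantity is
stated to range over $[0,1]$; the absolute value (equivalently, the
predicted class's probability rescaled) is the only reading satisfying
both, and it makes confidence class-symmetric. Predictions are pooled
across CV iterations and partitioned into ten bins of width 0.1 (top bin
right-closed); per-bin accuracy plus an optional full metric set are
reported, and `confidence_accuracy_trend()` summarizes the
confidence–accuracy relationship as a count-weighted rank correlation,
flagging bins holding under 1% of predictions (or fewer than 5) where
accuracies are statistically fragile.

## Applicability domain

Training descriptors (post-filter, by default) are standardized by
training mean/sd and rotated by PCA; the smallest number of leading
components covering 95% of variance is retained (a fixed component count
can be forced instead — for the emulated study that count was 20). Every
chemical is projected and its Euclidean distance to the training-score
centroid computed, together with the training-distance quantile ("farther
than 95% of training chemicals"). Training and external distance
distributions are compared by a two-sided Mann–Whitney test — rank-based
because descriptor-space distances are strongly right-skewed; no normality
is assumed and none holds.

## The synthetic study generator

Because the curated training data (ToxRefDB-derived tables) and the closed
descriptor software are not redistributable, the generator is the package's
test bed, and its defaults *are* the emulated study conditions: 275
training chemicals with 94 positives (exact stratified assignment), 29
external chemicals, 777 descriptors, positive LOAELs spanning
$10^0$–$10^4$ mg/kg/day. Structure:

* **Marginals** mix continuous columns (normal, with log-normal scale
  heterogeneity across descriptors) and non-negative count-like columns
  (Poisson), because real 2D descriptors include many atom/bond/fragment
  counts; 270 columns are sparse (zero with probability 0.95) to exercise
  the sparse filter; scales vary over orders of magnitude to exercise
  standardization and entropy binning.
* **Signal.** A configurable set of informative descriptors is shifted by
  `effect_size` (in units of each descriptor's own scale) in positives.
  The default effect size of 1 produces the moderate separability regime
  (cross-validated balanced accuracy well below 1); tests of signal
  recovery use 3.
* **Latent toxicity score** = mean standardized informative-descriptor
  value per chemical, i.e. the realized signal. LOAELs are assigned to
  positives rank-anti-correlated with this score (target Spearman −0.7 by
  default, exactly reversed order at −1), then mapped linearly onto the
  configured log10 range — so strong (low-LOAEL) positives are genuinely
  more separable, the mechanism behind the stratified-sensitivity
  analyses.
* **Covariate shift.** The external cohort draws from the same family with
  informative-descriptor means shifted by `shift_magnitude` (default 2)
  standard units, reproducing the "external set far from the training
  centroid" geometry.
* **Determinism.** One master seed; every sub-stream (scheme, cohorts,
  LOAELs) derives from it by fixed offsets, and generation restores the
  caller's RNG state. Identical configs are byte-identical.

What the generator does *not* emulate: real descriptor covariance
(block-correlation among 2D descriptors), multimodal chemical-class
structure, or any actual chemistry. Passing tests therefore demonstrate
that the machinery is correct and that qualitative phenomena (consensus
advantage, LOAEL gradient, domain-shift degradation) emerge when their
generating mechanisms are present — not that real-data performance levels
are reproduced.

## Numerical and degenerate-input choices

* Entropy bins: `findInterval` on equal-width breaks, top bin closed;
  constant descriptors have entropy 0 by definition.
* Threshold equalities follow each verbal rule literally: sparse filter
  removes strictly above 0.90; entropy filter keeps exactly 2.5;
  importance filter keeps strictly above 0.2.
* kNN neighbor ties are broken by training-row order (deterministic);
  $k$ is capped at the training size.
* Standardization of a zero-variance column divides by 1, not 0.
* Fold sizes differ by at most one (`rep_len` then shuffle); single-class
  training parts raise warnings, and in tuning contribute chance-level
  predictions rather than aborting the repeat.
* Platt fitting starts from Platt's recommended initial point and clips
  probabilities at $10^{-12}$ inside the log-likelihood.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full-width generator
(275 × 777) for composition and filtering checks, and reduced descriptor
tables (20–50 columns) with 5–20 CV iterations for the model-level
simulations; these sizes give stable qualitative outcomes (checked across
seeds) while keeping a full run in the minutes range. The full-scale
design — 500 CV iterations, 500 importance iterations — is available by
argument (`iterations`, `cv_iterations`) and changes estimates' precision,
not their meaning.

## Known limitations

* Real-data performance for this endpoint is modest (balanced accuracy in
  the 0.6 range in the motivating study); nothing here claims otherwise —
  synthetic separability is a dial, not a forecast.
* The consensus probability is a vote-count step function with eight
  levels; it is not a calibrated probability, and the package deliberately
  does not recalibrate it.
* Subset consensus (< 7 models) is refused rather than generalized.
* Imputation is out of scope: missing descriptor values are rejected
  unless a missing-value token is configured at read time, and models
  require complete matrices.
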