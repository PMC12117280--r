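---
title: "Prescriptive predictor modelling for two-arm trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prescriptive predictor modelling for two-arm trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A two-arm randomized trial tells us whether a treatment works on average;
it does not tell us *for whom* it works better than the comparator.
`prescriptr` implements a counterfactual machine-learning workflow for
answering that second question with a binary endpoint, motivated by a
14-day smartphone-delivered mindfulness ecological momentary intervention
(MEMI, five brief prompts per day) evaluated against an active
self-monitoring control (SM) in 191 adults with probable social anxiety
disorder. Remission is defined by a severity score strictly below the
SPDQ cut-off 12.13 at posttreatment and at one-month follow-up, and the
quantity of interest is each participant's *individual treatment effect*
(ITE): the difference between their remission probability under MEMI and
under SM.

The workflow has five stages, each a module of the package:

1. **T-learner counterfactual estimation** (`fit_arm_models()`): separate
   random-forest remission models per arm impute both potential outcomes
   for every participant; the binary *optimization label* is 1 exactly
   when the imputed remission probability is strictly higher under the
   treatment arm.
2. **Leakage-controlled preprocessing** (`preprocess_fit()`,
   `standardize_and_encode()`, `smote_rebalance()`): chained
   random-forest imputation, standardization to mean 0 / SD 1, full
   one-hot encoding, and SMOTE rebalancing, all fitted strictly inside
   training partitions.
3. **Elastic-net screening** (`elastic_net_screen()`): reduces the 17
   baseline predictors to the top 10 by penalized-logistic importance.
4. **Nested repeated cross-validation** (`run_nested_cv()`): unbiased
   evaluation of random-forest, RBF-kernel SVM, and logistic-reference
   classifiers of the optimization label, with inner-fold grid search and
   DeLong comparisons of correlated AUCs.
5. **Kernel SHAP attribution** (`kernel_shap()`, `rank_and_sign()`):
   model-agnostic Shapley attributions ranking the prescriptive
   predictors with signed directions.

Because the motivating trial's data are not publicly deposited, the
package ships a calibrated synthetic generator (`generate_trial()`) whose
defaults emulate the trial's design, and every stage is validated by
recovery against the generator's latent ground truth.

## The synthetic trial generator

`generator_config()` fixes the study conditions:

- **Sample**: N = 191 by default, allocated by permuted-block
  randomization with block sizes 2, 4, and 6 drawn uniformly with
  replacement; complete blocks are exactly balanced, so the worst-case
  arm imbalance is 3 and the observed 96/95 split is attainable.
- **Predictors**: the 17 baseline variables (age; gender; ethnicity;
  university education; treatment credibility and expectancy; SAD,
  depression and GAD severities; clinician-diagnosed disorder; current
  psychotherapy; psychotropic medication; trait attentional control,
  emotion dysregulation, mindfulness, perseverative cognition,
  self-compassion) with marginals matching the trial sample where
  reported (age 21.84, SD 3.37; 78% female; 86% Chinese; 5.24% on
  medication; 15.71% prior psychotherapy; 17.8% university-educated).
  Scales whose summaries are not reported use plausible values on the
  instrument's raw metric; since the outcome model consumes standardized
  values, only location/scale enter downstream behaviour.
- **Outcome model**: remission at each wave is Bernoulli with logit
  `a_t + arm * (tau_t + delta_t) + X beta + arm * X gamma` on
  standardized predictors. Two constants are calibrated by Monte Carlo
  (200,000 draws, fixed internal stream): the intercept `a_t` pins the
  control arm's marginal remission rate to its target -- 18% at
  posttreatment and 26% at follow-up, the midpoints of the arm-specific
  rates reported for the motivating trial (15.6-21.1% and 26.0-26.3%) --
  and the offset `tau_t` pins the treated arm to the *same* marginal
  rate. The second calibration is not cosmetic: the sigmoid is convex
  below its midpoint, so a wide interaction spread `G` alone would
  inflate the treated arm's marginal rate
  (`E[plogis(a + G)] > plogis(a)` for symmetric `G`), contradicting the
  null between-group contrasts the generator emulates. The configurable
  `arm_effect` (`delta_t`, default 0) adds a genuine average effect on
  top. A by-product of equal marginal rates under strong moderation is
  that the latent ITE is positive for a *minority* (~27%) of
  participants -- the benefiting subgroup the pipeline is meant to find
  -- so the optimization label is naturally imbalanced, which is what
  the SMOTE stage is for.
- **Planted moderators**: default interaction weights of +1.5 SD (trait
  mindfulness), -1.5 (SAD severity), and +1.0 (GAD severity) log-odds,
  consistent with capitalization (leverage strengths: high mindfulness)
  and compensation (remediate deficits: high worry) accounts of who
  gains more from a mindfulness EMI. `default_outcome_model(moderation
  = 0, signal = 0)` yields a null trial with an identically zero latent
  ITE.
- **Severity scores**: the analysis treats remission as binary, so
  severity values only need to respect the cut-off: remitters receive
  `12.13 - |N(0, 4)|` (truncated into `(0, 12.13)`), non-remitters
  `12.13 + |N(0, 15)|`.
- **Missingness**: exactly `round(rate * n_cells)` cells of the
  18-column analysis matrix (17 predictors + posttreatment outcome) are
  masked, MCAR by default; 10% of a 191-row table is exactly 344 cells.
  A MAR mode (masking probability increasing with observed GAD severity,
  which is then exempt from masking) supports robustness checks. The
  follow-up outcome is left observed: dropout processes are out of
  scope.
- **Engagement**: completed prompts out of 70 are drawn around 60
  (SD 12), i.e. ~85% engagement.

The generator does *not* emulate momentary (prompt-level) time series,
dropout, item-level psychometrics, or predictor intercorrelations
(predictors are drawn independently). Passing recovery tests therefore
demonstrates that the pipeline's machinery works under clean, favourable
conditions; it does not certify performance on real trial data, where
correlated predictors and informative missingness can only weaken the
stages that assume neither.

## T-learner design

Arm-specific probability forests (500 trees) are trained on participants
with an observed outcome. Two choices matter:

- **Cross-fitting**: a participant's *same-arm* probability comes from
  the model whose training fold excluded them (stratified within-arm
  10-fold cross-fit, preprocessing refit inside every split), removing
  self-prediction optimism. The *counterfactual* probability comes from
  the full model of the opposite arm, which never saw the participant.
- **Strict labelling**: `optimized = 1` exactly when
  `p_memi > p_sm`; ties are labelled 0.

`recovery_report()` scores estimates against the generator's latent
truth. Under the default strong moderation the estimated ITE's sign
agreement with truth is well above the binomial chance band and the
Spearman correlation is high; both are recomputed by the test suite and
the acceptance script rather than quoted here.

## Leakage control

Every statistic that could carry outcome or test-fold information is
fitted on a training partition and applied frozen:

- Imputation forests, standardization constants, and one-hot level
  registries are fitted per outer-training partition
  (`PreprocessorState` records the partition it was fitted on, and the
  test suite asserts bitwise state stability under held-out transforms).
- SMOTE runs independently inside every inner and outer training fold;
  synthetic rows carry provenance flags and can never reach an
  evaluation partition.
- Screening and the hyperparameter grid search see only the
  outer-training partition.
- A leakage sentinel test permutes outer-test labels and asserts that
  every fitted model and score is unchanged.

One deliberate economy: imputation and standardization are fitted once
per *outer*-training partition and reused across that partition's inner
folds (SMOTE is still refit per inner fold). The imputer uses predictors
only -- never outcome or label -- so the reuse cannot move label
information into model selection; it cuts the imputation cost of a full
nested run by an order of magnitude.

Chained random-forest imputation initializes missing cells at the
training mean/mode, then iteratively re-imputes each incomplete variable
from all others (regression forests for continuous variables,
classification forests for nominal ones, 100 trees by default), stopping
when the mean out-of-bag error of the chained models stops improving or
after `max_iter = 10` sweeps. Observed cells are never altered, and a
constant column imputes to its constant without a forest.

## SMOTE scheme

Class rebalancing is two-sided: the majority class is first randomly
undersampled to the midpoint between the class counts, then the minority
class is augmented to exact parity (configurable ratio) with synthetic
points, each a uniform convex combination of a minority point and one of
its `k = 5` nearest minority neighbours (Euclidean distance on the
standardized features). `k` is reduced with a warning when the minority
class is smaller than `k + 1`; a singleton minority is an error.

## Screening and the final predictor set

The elastic-net screen fixes the mixing parameter at 0.5 and tunes the
penalty strength by inner cross-validated deviance (`glmnet`). A
predictor's importance is the maximum absolute coefficient across its
one-hot block, so a nominal predictor enters or leaves the top-k as a
unit. Because screening must stay fold-internal, the selected set may
differ across outer folds; the reported final set is the modal selection
across folds, ties broken by mean importance and then canonical name
order. A fully shrunk fit (all coefficients zero) falls back to the
canonical predictor order -- a deterministic, documented degenerate case.

## Evaluation

- **AUC** is the Mann-Whitney rank form (ties count half), verified
  against brute-force pair counting.
- **AUPRC** is step-integrated average precision (no trapezoids).
- Confusion metrics use a 0.5 probability threshold (the threshold is a
  reported parameter, not tuned).
- **Calibration** is summarized as the point-biserial correlation `r`
  between predicted probability and outcome, converted to
  `d = 2r / sqrt(1 - r^2)`; the report carries `|d|` with the sign on
  `r`, and zero-variance predictions raise a degeneracy flag.
- **Aggregation**: metrics are means over all repeat-by-fold
  evaluations; the AUC interval is the percentile interval of
  repeat-level means. Per-participant scores averaged over repeats feed
  the paired **DeLong** test (placement-value covariance form, verified
  against both `pROC` and a paired-permutation oracle).
- **Grids**: RF tunes variables-per-split over
  `{floor(sqrt(p)/2), floor(sqrt(p)), 2 floor(sqrt(p))}` at 500 trees;
  the SVM tunes cost over `{0.25, 1, 4, 16}` and kernel width over
  `{1/(2p), 1/p, 2/p}`; the logistic reference has no grid. SVM
  probabilities come from a deterministic Platt-style logistic mapping
  of decision values fitted on the training partition (the SVM's
  internal probability machinery is randomized; a monotone mapping
  preserves AUC and gives reproducible thresholds).

## Kernel SHAP

Attributions solve a constrained least-squares system over coalitions
sampled from the Shapley kernel (sizes drawn with mass proportional to
`(p-1)/(s(p-s))`, each coalition paired with its complement; default
`8p` coalitions). Masked features are integrated over a background
sample; additivity (base value + attributions = prediction) is enforced
exactly per instance via the constraint. One-hot blocks are re-aggregated
to their source predictor by summation, which is invariant to indicator
order. Direction is the sign of the Spearman correlation between a
predictor's value and its attribution (for nominal blocks, the indicator
with the largest mean absolute attribution represents the block); rank
ties break by canonical name order. The linear-model closed form
(`phi_j = w_j (x_j - mean background_j)`) and the duplicated-feature
symmetry axiom serve as oracles in the test suite.

## Numerical and reproducibility choices

- Every stochastic stage receives a seed derived deterministically from
  one master seed (`derive_seed()`); a repeated run is bit-identical,
  including report-bundle content hashes.
- `ranger` prediction draws an internal tie-break seed from the session
  RNG unless one is supplied; the package pins it everywhere, otherwise
  classification imputation would depend on ambient RNG state.
- Stratified folds guarantee fold sizes and per-class counts within one
  of each other; a class smaller than the fold count is an error that
  suggests fewer folds.
- Degenerate cases are explicit: zero-marginal chi-square tables return
  0 with a warning; single-class partitions fall back to constant
  probability models; unseen test levels encode as all-zero indicators
  with a warning.

## Known limitations

- **Derived-label circularity.** The optimization label is a function of
  the baseline predictors *by construction* (through the fitted arm
  models). A classifier of that label therefore has signal even in a
  null trial with zero planted moderation: the test suite and
  `scripts/acceptance.R` compute this null-trial AUC, and it sits far
  above 0.5 even though the leakage sentinel passes and a permuted-label
  run is correctly at chance. Discrimination of the optimization label
  should accordingly be read as fidelity to the T-learner's decision
  surface, not as evidence of true treatment-effect heterogeneity;
  only recovery against ground truth (or external validation) supports
  the stronger claim.
- The generator's independent predictors and MCAR default are favourable
  conditions; real data will be harder.
- ITE sign recovery close to the decision boundary is intrinsically
  noisy: participants with small true effects are the ones the T-learner
  misclassifies, so sign agreement plateaus well below 1 even at large
  n.
- No S-, X-, or R-learner and no doubly robust estimator is provided;
  the learner behind the T-learner is pluggable but random forest is the
  committed default.

## Problem sizes used by the tests

The test suite exercises the full pipeline at n = 400 (10 outer folds, 3
repeats) for the discrimination study, n = 191 for the null-calibration
study, n = 1000-2000 for recovery studies, and 20 seeds for the SHAP
recovery rate; generator-moment checks use n = 10,000-20,000. These
sizes were chosen so each property is measured with useful precision
while the whole suite stays comfortably runnable on a laptop.
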