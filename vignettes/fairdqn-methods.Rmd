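---
title: "Fairness-aware classification by reinforcement learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fairness-aware classification by reinforcement learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Clinical risk models are routinely trained on cohorts in which both the
outcome and the sensitive attribute are badly imbalanced: a screening task
may have ~11% positives, while 85–90% of presentations come from one ethnic
group or one hospital site. Cross-entropy training aggregates errors over a
batch, so the learning signal is dominated by the majority outcome and the
majority group; the resulting classifier can satisfy headline metrics while
its true-positive and false-positive rates differ appreciably between
groups. The *equalized-odds* criterion asks that TPR and FPR be equal across
all classes of the sensitive attribute `Z`.

`fairdqn` trains a classifier whose learning signal is a *reward*, not an
aggregated loss, and shapes that reward so rarer sensitive groups matter
more. The package contains the full study apparatus around that idea:
preprocessing, a biased-cohort simulator, the RL trainer, supervised
baselines, fairness metrics, threshold calibration, and an orchestrated
experiment runner.

## Classification as a Markov decision process

Each training row's feature vector is a state `s`; the action `a` is the
predicted class among `K`; the transition to the next state is simply the
next row of a freshly shuffled pass over the training data (the transition
kernel is deterministic and independent of the action). Because actions do
not influence transitions, a dependency is created through *termination*:
an episode ends when the agent misclassifies a sample of the minority
outcome class (or exhausts the pass), forfeiting all future reward. With
minority positives this makes false negatives doubly costly: the immediate
penalty plus the lost continuation value.

### The debiasing reward

Let `N_k` be the training count of outcome class `k` and `N_m` of sensitive
group `m`. Define per-class weights as the *vector-normalized reciprocals*

    lambda_c = (1 / N_c) / || (1/N_0, ..., 1/N_{C-1}) ||_2 ,

so `lambda` is a unit vector and rarer classes receive strictly larger
weights; the weights are invariant to rescaling all counts. The reward for
acting on a sample with outcome label `l`, group `z` is

    R = + lambda_sensitive[z]   if the prediction is correct  (debias mode)
    R = - lambda_outcome[l]     if the prediction is wrong

Correct predictions are worth more for rare groups; wrong predictions cost
more for rare outcome classes. The `outcome_only` mode (the "RL,
unweighted" comparator) replaces the positive branch with
`+lambda_outcome[l]`, removing the debiasing component while keeping the
imbalance-aware penalty. The printed normalization of the weight vector is
typographically ambiguous between the Euclidean norm and its square; we use
the Euclidean norm — the reading under which "vector-normalized" is literal
and `lambda` is a unit vector — and expose the squared-norm variant as
`compute_lambda(..., norm = "squared")` for sensitivity checks.

A discount factor `gamma = 0.1` weights the continuation value of an
episode; classification quality is almost entirely an immediate-reward
matter, and the small positive `gamma` only has to transmit the termination
penalty.

### Dueling architecture

The Q-network is a single-hidden-layer fully connected network (ReLU,
dropout) whose trunk feeds two streams: a scalar state value `V(s)` and a
per-action advantage vector `A(s, ·)`. They recombine as

    Q_a = V + A_a - softmax(A)_a .

Subtracting the softmax of the advantage vector makes the decomposition
identifiable (up to the scalar shift gauge `(V, A) -> (V - c, A + c)`,
which leaves Q unchanged) and — because `m - tanh(m/2)` is strictly
increasing — never reorders the actions, so the greedy policy is untouched.
The subtraction is applied elementwise using the advantage vector of the
*same* state; softmaxes are computed with max-subtraction for overflow
safety. Head weights start at zero so an untrained network is exactly
indifferent between actions.

### Double-DQN training

Transitions `(s, a, r, s', term)` accumulate in a bounded FIFO replay
memory. Each gradient step regresses the online network's `Q(s, a)` onto

    y = r + (1 - term) * gamma * Q_target(s', argmax_a Q_online(s', a)) ,

the double-DQN target: the online network selects the next action, the
periodically synchronized target copy evaluates it, reducing the
overestimation bias of vanilla Q-learning. The loss is the *summed* squared
error over the batch (a mean-reduction switch exists but defaults off, to
match the stated objective). Behaviour is epsilon-greedy with epsilon
annealed linearly from 1 to 0.01 over the whole run; the reference schedule
is 120,000 steps, and shorter runs anneal over their own length.

Unstated engineering constants are exposed in `training_config()` with
these defaults: replay capacity 10,000, batch size 64, target
synchronization every 1,000 steps, one Adam step (learning rate 1e-3) per
environment step once the memory holds a full batch, hidden width 128,
dropout 0.2. Dropout is active only in the gradient-step forward pass;
action selection, target computation and all scoring are deterministic.
Episodes span a full shuffled pass by default (`episode_cap` restricts
them). The terminal sample of an episode stores no successor state; its
target is exactly `r`.

## Supervised baselines

`train_baseline_nn()` is the same trunk with a softmax head and weighted
cross-entropy. `weight_mode = "sensitive_frequency"` multiplies each
sample's loss by `compute_lambda(sensitive counts)[z]` — the cost-adjusted
comparator. Reusing the unit-norm construction (rather than raw inverse
frequencies) puts the baseline's weights and the RL reward on a single
scale; under Adam, which is nearly invariant to a uniform gradient
rescaling, the distinction from raw reciprocals is immaterial.

## Evaluation protocol

Scores are `softmax(Q)` for the positive class — a strictly monotone
transform of the Q-margin, so ranking metrics agree with the raw network
output. For each model the decision threshold is calibrated on the
*validation* split: the largest threshold whose validation sensitivity
reaches the target (0.9 by default, chosen in the screening context to
exceed the sensitivity of lateral-flow and PCR testing; 0.85 as a secondary
operating point). Test-set reporting: sensitivity, specificity, PPV, NPV
(the screening use-case prizes NPV), F1, normal-approximation 95% CIs,
AUROC with the Hanley–McNeil interval, and the equalized-odds summaries

    sd_TP = population s.d. over groups of TP_g / (TP_g + FN_g)
    sd_FP = population s.d. over groups of FP_g / (FP_g + TN_g) .

Two conventions deserve note. First, the population (divide-by-M) standard
deviation is used because the groups observed are the complete set of
groups, not a sample from a larger population. Second, the printed source
formula for the false-positive dispersion carries a positive-count
denominator (`TP + FN`); we use the standard false positive rate
`FP / (FP + TN)`, which is the quantity the equalized-odds definition
actually constrains. A group with no positives (or negatives) has an
undefined rate and is excluded from the corresponding dispersion with a
warning rather than crashing the report. Model pairs are compared by the
Wilcoxon signed-rank test on paired per-sample correctness indicators
(zero differences dropped; identical models give p = 1); the pairing unit
is the test-set presentation.

## The synthetic cohort generator

Real multi-site clinical extracts are governed; the generator reproduces
the statistical hazards that make them hard, without any resemblance to
actual marginal distributions:

* **Rare outcome** — latent outcome Bernoulli(`outcome_prevalence`),
  default 0.111, the training prevalence of the motivating screening task.
* **Skewed sensitive attribute** — categorical `group_proportions`,
  default (0.85, 0.10, 0.05).
* **Outcome signal** — `n_informative` of the `n_features` Gaussian
  features shift their class-conditional mean; `signal_effect` (default 2)
  is the Euclidean distance between class means, giving a Bayes AUROC near
  0.92, inside the range typical of blood-test screening models.
* **Site/measurement shift** — each group adds a fixed offset: a unit
  direction drawn once per group from the seed, scaled by `bias_shift`.
  Groups therefore form separable clusters when `bias_shift` is large,
  mimicking the site-specific clustering seen in low-dimensional embeddings
  of real multi-hospital data. The magnitude is a calibration choice, not a
  measured quantity.
* **Group-dependent label noise** — with probability
  `bias_label_noise[g]` a *truly positive* case is observed as negative.
  The noise is deliberately one-sided: reference-standard labels in
  screening data err almost exclusively as missed diagnoses (imperfect
  assay sensitivity, incomplete testing penetrance), and differential
  under-ascertainment across groups is precisely the label-bias mechanism
  of concern. One-sided noise also keeps the observed positives truly
  positive, so a group's observed TPR measures real detection rather than
  an artifact of contaminated positives — under symmetric flipping at
  these rates, most "observed positives" in a noisy group would be latent
  negatives and sensitivity-calibrated evaluation would reward
  indiscriminate flooding of that group. Evaluation everywhere uses the
  observed labels, as real studies must (their reference labels are
  themselves proxies).
* **Missingness** — cells masked completely at random
  (`missing_rate`, default 0.05), handled downstream by training-median
  imputation.

All randomness flows from the single config seed through an RNG scope that
is restored on exit, so generation never perturbs the caller's RNG stream.
What passing tests on these cohorts do *not* show: robustness to real
feature distributions (heavy tails, discreteness, informative missingness),
to label noise correlated with features, or to covariate shift between
sites beyond a mean offset.

## Study design at package scale

The headline experiment asks whether the debiasing reward narrows
equalized-odds TPR dispersion relative to the unweighted network at a small
AUROC cost. Conditions: ten seeded cohorts, N = 4,000, two groups with
proportions 0.8/0.2, missed-diagnosis noise (0.05, 0.30), `bias_shift` 1,
latent prevalence 0.2 (raised from 0.111 for test power at this N); both
models use one hidden layer of width 128; the RL agent trains for 10,000
steps (a reduced budget that this problem size saturates — the toy
convergence study uses 20,000) and the baseline for 30 epochs; thresholds
are calibrated per model to 0.9 validation sensitivity; the summary is the
median over seeds. The same conditions are recomputed from scratch by
`scripts/acceptance.R`.

A caveat this design cannot escape: with a 20% test split of N = 4,000 and
a 0.2-proportion rare group under 30% missed-diagnosis noise, each
replicate's rare-group TPR is estimated from roughly two dozen observed
positives, carrying a binomial standard error near 0.09 — comparable to or
larger than the dispersion differences under study. Medians over ten seeds
tame but do not eliminate this, so the ordering of the two models' TPR
dispersions is reliable only at the study's fixed seed set, and different
seed draws can invert it. The FPR dispersions, estimated from hundreds of
negatives per group, are far more stable. Detecting the TPR effect with
seed-independent confidence would need several-fold larger cohorts or
several times more replicates than this package's runtime envelope admits;
conclusions at this scale are demonstrations of the apparatus, not
evidence about the method's behaviour on real data.

## Numerical choices and degenerate inputs

* Greedy action ties break toward the lowest class index, deterministically.
* Constant training features standardize to 0 (flagged), so synthetic edge
  cases cannot abort a run.
* Median imputation uses the midpoint convention for even counts.
* Stratified splitting apportions each stratum by largest remainder, so
  every stratum lands within one sample of its target fraction; strata
  smaller than the number of parts raise an error naming the stratum.
* Zero-denominator metrics report `NA` ("undefined") rather than erroring.
* Label vocabularies map to dense integers in first-appearance order, and
  the mapping is carried in every report.
* `adjust_threshold` scans only observed unique scores; with a vacuous
  target it returns the highest score, which maximizes specificity.
* All stage seeds in `run_experiment()` derive deterministically from the
  one global seed, and reruns are bit-identical.

## Known limitations

* The reward acts on decision events, not on calibrated probabilities; the
  per-group scaling of Q-values means a single pooled threshold can sit at
  different points of each group's score distribution. Calibration-aware
  debiasing is out of scope.
* Only single-hidden-layer trunks are provided; no convolutional or
  recurrent variants, no prioritized replay, no multi-step returns.
* Gradient-boosted and adversarial comparators are not implemented; the
  weighted/unweighted network baselines exercise every comparison
  mechanic.
* The simulator's bias channels (mean shift, one-sided label noise, MCAR
  missingness) are the simplest members of their families; conclusions at
  this scale are qualitative, not numeric reproductions of any real-data
  result.
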