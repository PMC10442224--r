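# fairdqn

Fairness-aware classification of tabular clinical cohorts with a dueling
double deep Q-network and a debiasing reward.

## What problem this solves

Risk models trained on routine clinical data inherit the imbalances of the
data: rare positive outcomes (a screening task with ~11% prevalence), a
sensitive attribute — ethnicity, hospital site — dominated by one group,
site-specific measurement shift, and labels that miss true positives at
group-dependent rates. A conventionally trained classifier can post a good
AUROC while its true-positive and false-positive rates differ materially
between groups, violating *equalized odds*:
`P(Ŷ=1 | Y=y, Z=z)` equal across all groups `z`, for y = 0 and 1.

`fairdqn` frames classification as a sequential decision process and trains
a Q-network with a reward built from **vector-normalized reciprocal class
frequencies**. With `N_c` the training count of class `c`,

```
λ_c = (1/N_c) / ‖(1/N_0, …, 1/N_{C−1})‖₂
R(s, a) =  +λ_sensitive[z]   if a equals the outcome label (debias mode)
           −λ_outcome[l]     otherwise
```

so correct predictions are worth more for rare sensitive groups and errors
cost more for rare outcome classes. Training episodes terminate when the
agent misclassifies a minority-outcome sample, cutting off future reward.
The function approximator is a dueling network, `Q_a = V + A_a −
softmax(A)_a`, trained with double-DQN targets
`y = r + (1−term)·γ·Q_target(s′, argmax_a Q_online(s′,a))`, summed squared
TD loss, experience replay, Adam, and an ε-greedy policy annealed linearly
from 1 to 0.01 (γ = 0.1).

Around the trainer the package provides the full study apparatus:

* `cohort_config()` / `generate_cohort()` — a synthetic biased-cohort
  generator (rare outcomes, skewed groups, per-group feature offsets,
  one-sided missed-diagnosis label noise, missing cells);
* `read_cohort()`, `fit_preprocess()` / `apply_preprocess()` (training-split
  median imputation + standardization), stratified `split_cohort()`;
* `train_dqn()` and the cost-weighted network baseline
  `train_baseline_nn()`, plus `grid_search_cv()`;
* `equalized_odds_sd()` (per-group TPR/FPR and their population s.d.),
  `auroc()` with `hanley_mcneil_ci()`, `adjust_threshold()` (calibrate the
  decision threshold to a target sensitivity on validation),
  `paired_accuracy_test()` (Wilcoxon signed-rank on paired correctness);
* `compare_models()` and `run_experiment()` — end-to-end, manifest-logged,
  bit-reproducible experiments; a thin CLI lives at `inst/cli/fairdqn`.

## Worked example

```r
library(fairdqn)

# The debiasing weights for a 90/10 outcome imbalance:
compute_lambda(c(90, 10))
#> [1] 0.1104315 0.9938838        # rarer class, ~9x the weight

# Quick-start experiment: synthetic biased cohort (N = 2000, groups 0.8/0.2,
# missed-diagnosis noise 0.05/0.30), debias-mode RL vs unweighted network,
# thresholds calibrated to 0.9 validation sensitivity.
res <- run_experiment(default_run_config(seed = 7), output_dir = "quickstart")
res$comparisons$sens0.9$table[, c("model", "threshold", "sensitivity",
                                  "specificity", "npv", "auroc",
                                  "sd_tp", "sd_fp")]
#>                model threshold sensitivity specificity   npv auroc  sd_tp   sd_fp
#>            rl_debias     0.421       0.923       0.599 0.976 0.898 0.0631 0.05489
#>  baseline_unweighted     0.102       0.969       0.662 0.991 0.913 0.0185 0.00623
```

Each row is one model at its calibrated threshold on the held-out test
split: `sd_tp`/`sd_fp` are the equalized-odds dispersions (population s.d.
of per-group TPR/FPR; 0 = perfectly fair), `npv` the negative predictive
value the screening use-case prizes, and `auroc` threshold-free ranking
quality. A single quick-start replicate at N = 2000 is deliberately small
and seed-noisy — conclusions about the debiasing effect come from the
multi-seed study below, whose medians are the quantity of interest. The
`quickstart/` directory receives the manifest (all resolved settings, λ
vectors, derived seeds), per-model checkpoints, per-group rate tables and
the comparison tables.

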