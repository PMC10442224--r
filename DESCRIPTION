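Package: fairdqn
Title: Fairness-Aware Classification with Dueling Double Deep Q-Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains tabular classifiers by deep reinforcement learning with a
    debiasing reward that is inversely proportional to sensitive-attribute
    class frequency, so that rarer demographic or site groups earn larger
    rewards for correct predictions. Implements a dueling Q-network with
    double-DQN targets and experience replay, equalized-odds fairness metrics
    (standard deviation of per-group true/false positive rates),
    sensitivity-targeted decision-threshold calibration, cost-weighted
    fully connected network baselines, and a synthetic biased-cohort
    generator emulating low outcome prevalence, skewed sensitive attributes,
    site-specific feature shift, group-dependent label noise and missing
    values.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
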