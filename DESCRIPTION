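Package: opponency
Title: Neuromodulated Adaptive Agents in Socioeconomic Games
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale simulator of cost/reward opponency in
    decision-making. Adaptive agents whose choices are gated by simulated
    serotonergic (cost) and dopaminergic (reward) neuromodulation play
    iterated Hawk-Dove, Chicken, and a spatial Stag Hunt against
    set-strategy and adaptive opponents. Includes a mean-firing-rate
    neural network with neuromodulated plasticity and phasic
    amplification, a tabular Actor-Critic with separate Reward and Cost
    Critics, simulated neuromodulatory lesions, Win-Stay-Lose-Shift and
    Tit-for-Tat strategy classification, a seeded experiment runner with
    JSON-lines logging, and a hierarchical Bayesian latent-mixture model
    of per-subject escalation behavior fitted by Markov chain Monte
    Carlo, with a synthetic-subject generator for parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
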