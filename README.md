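# opponency

Simulation toolkit for studying serotonin/dopamine opponency in
decision-making through socioeconomic games.

Serotonergic activity has been tied to cost assessment and harm aversion,
dopaminergic activity to reward expectation, and the two systems often act
in opposition: high expected cost withdraws an organism from risk, high
expected reward invigorates it. `opponency` packages a desk-scale version of
an experimental paradigm built on that idea. Adaptive agents whose choices
are gated by learned cost and reward predictions play iterated **Hawk-Dove**
and **Chicken** (competitive games) and a spatial **Stag Hunt** (a
cooperation game) against set-strategy and adaptive opponents; simulated
lesions of either neuromodulatory system probe the causal role of each; and
a hierarchical Bayesian latent-mixture model detects subgroups of
behavioral change in per-subject choice data.

## The models

**Neural network agent** (Hawk-Dove, Chicken). Game-Dependent Input Neurons
(one per observable state) project through plastic weights to two Action
Neurons and to Cost (serotonergic) and Reward (dopaminergic) neurons. All
units follow a mean-firing-rate rule

    s(t) = rho * s(t-1) + (1 - rho) * 1 / (1 + exp(-5 * I(t))),  rho = 0.1

with synaptic input `I = noise + sum(nm * w * s_pre)`. Phasic
neuromodulation sets `nm` to ten times the mean Cost/Reward activity on
sensory and intrinsic inhibitory connections (winner-take-all, exploitive
choice when neuromodulation is high), and `nm = 1` elsewhere. The Reward
neuron drives the risky action, the Cost neuron the safe one. After each
round, plasticity on connections from the most-active input is Hebbian and
gated by the reinforcement

    R = (Reward_received - s_reward) - (Cost_received - s_cost),

so accurate predictions produce no change. `lesion(agent, "cost")` clamps
the Cost neuron, reproducing the serotonergic-lesion phenotype of
near-total escalation.

**Actor-Critic agent** (Stag Hunt). Separate Reward and Cost Critics hold
values over 81 discretized board states (binned distances of both players
to the stag and nearest hare); an Actor holds stag/hare preferences turned
into choice probabilities by a SoftMax. Critics learn by the delta rule
`delta = r + V(s_now) - V(s_prev)`; the Actor moves by the combined
reward-plus-cost error in advantage form.

**Latent mixture** (cognitive model). For subject `i` in condition `c`,
`k ~ Binomial(n, p)` with `logit(p) = baseline_i + effect[z_i, c]`, group 1
effects negative, group 2 positive. Fitted by seeded
Metropolis-within-Gibbs MCMC (exact Gibbs draws for the group labels);
subjects are assigned only above a posterior-probability threshold.

## Worked example

A paired lesion study in a harsh Hawk-Dove environment (serious injuries
are likely) against a Tit-for-Tat opponent:

```r
library(opponency)

cfg <- experiment_config("hawk_dove",
  players = list(neural_player(), strategy_spec("t4t")),
  game_config = hawk_dove_config(p_serious = 0.75),
  n_rounds = 500, seed = 42)
study <- run_lesion_study(cfg, "cost")
study
#> <lesion_study: cost lesion, hawk_dove>
#>   escalation intact 0.624, lesioned 1.000 (difference +0.376)
```

The intact agent, which has learned that escalation against a retaliatory
opponent is costly, escalates on 62% of rounds; with its cost
(serotonergic) system clamped the same agent, under the same seeds and
opponent, escalates on every round — risk taking unchecked by cost
assessment.

Recovering planted subgroups with the cognitive model:

```r
syn <- synth_subjects(seed = 1)   # 8 subjects, 4 per group, +/-1.5 logits
fit <- fit_escalation_mixture(syn$data, seed = 1)
fit
#> <escalation_mixture: 8 subjects, 2 conditions, 4 chains x 5000 draws>
#>   groups: 4 decrease, 4 increase, 0 unassigned
head(summary(fit)[, c("subject", "p_decrease", "mean_group", "label")], 2)
#>   subject p_decrease mean_group    label
#> 1     s01          1          1 decrease
#> 2     s02          1          1 decrease
plot(fit)   # per-subject posterior mean group with 95% credible intervals
```

All eight synthetic subjects are assigned to their generating group:
subjects whose escalation probability was built to drop under treatment
land on group 1 ("decrease"), the others on group 2.

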