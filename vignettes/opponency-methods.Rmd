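---
title: "Cost/reward opponency in game-playing agents: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost/reward opponency in game-playing agents: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opponency)
```

## The scientific question

Serotonin (5-HT) has been linked to cost assessment and harm aversion, and
dopamine (DA) to reward expectation, with the two systems often acting in
opposition: high serotonergic activity biases an organism toward withdrawn,
risk-averse choices, while dopaminergic activity biases it toward
uninhibited, risk-taking ones. `opponency` implements a desk-scale simulation
paradigm for studying that opponency in socioeconomic games: adaptive agents
whose decisions are gated by learned cost and reward predictions play
iterated Hawk-Dove and Chicken (competition) and a spatial Stag Hunt
(cooperation) against set-strategy and adaptive opponents, with simulated
neuromodulatory lesions, a Win-Stay-Lose-Shift / Tit-for-Tat strategy
classifier, and a hierarchical Bayesian latent-mixture model for detecting
behavioral subgroups in choice data.

## The neural network agent

The network (used for Hawk-Dove and Chicken) has three populations:

* **Game-Dependent Input Neurons** — one per observable environmental state.
  We use one neuron per joint outcome of the previous round (own x opponent
  action, coded risky/safe) plus a game-start state, five in all. The
  salient neuron fires at amplitude $b$ ($b = 0.75$ in Hawk-Dove, $b = 0.45$
  in Chicken) plus uniform noise on $[0, 0.25]$, the others carry noise
  alone. The number of input states is a modeling choice; the previous joint
  outcome is the minimal state sufficient for a one-round memory strategy.
* **Action Neurons** — two, one per action (escalate/display,
  straight/swerve), with fixed reciprocal excitatory ($w_E = 0.1$) and
  inhibitory ($w_I = 1$) connections.
* **Neuromodulatory Neurons** — a Cost neuron (serotonergic) and a Reward
  neuron (dopaminergic), each receiving plastic input connections.

All action and neuromodulatory neurons follow the mean-firing-rate update

$$s_i(t) = \rho\, s_i(t-1) + (1-\rho)\,\frac{1}{1+e^{-5 I_i(t)}}, \qquad
\rho = 0.1,$$

a convex combination of quantities in $[0,1]$, so activities are bounded by
construction. Synaptic input is

$$I_i(t) = \text{noise} + \sum_j nm(t-1)\, w_{ij}(t-1)\, s_j(t-1),$$

with noise uniform on $[-0.5, 0]$. Phasic neuromodulation sets
$nm = 10 \cdot \overline{(s_{cost}, s_{reward})}$ on sensory
(input-to-action) and intrinsic inhibitory connections and $nm = 1$
elsewhere, producing a winner-take-all, exploitive readout when
neuromodulatory activity is high and noise-driven exploration when it is
low.

**Structural opponency.** The Reward neuron projects (weight `w_drive`,
default 3, not amplified, not plastic) onto the risky action neuron and the
Cost neuron onto the safe action neuron. This is the architectural
expression of the base assumptions — reward expectation invigorates risk
taking, cost expectation drives withdrawal — and it is what makes the
reward-vs-cost comparison causally gate choice rather than merely correlate
with it. Without some such asymmetry the two action neurons are
interchangeable and neither the gating phenomenon nor the lesion phenotype
can arise.

**Decision readout.** Each round the action pool is reset and the network
settles for 10 synchronous steps under the current salient input (input
noise resampled each step); the action with the higher final activity is
chosen, exact ties broken uniformly at random. Resetting the action pool at
each decision is deliberate: carrying the previous winner's activity into
the next settling period lets the amplified inhibition entrench it, and
whole sessions collapse into a single repeated action.

**Learning.** After the outcome, the payoff is decomposed into non-negative
reward and cost magnitudes (in Hawk-Dove, the resource share obtained and
the injury cost; in Chicken, the positive payoff and the magnitude of a
negative one). The combined reinforcement is the dual prediction error

$$R = (\text{Reward}_{received} - s_{reward}) -
      (\text{Cost}_{received} - s_{cost}),$$

zero when both predictions are exact. Plasticity is Hebbian and
neuromodulated, applied only to connections from the most-active input
neuron, with $nm = \overline{(s_{cost}, s_{reward})}$:

* input → winning action: $\Delta w = \alpha\, nm\, s_j\, s_i\, R$;
* input → Reward neuron: the same form with the reward prediction error
  $(\text{Reward}_{received} - s_{reward})$ in place of $R$;
* input → Cost neuron: the same form with the cost prediction error.

Driving each neuromodulatory neuron with its own error is what makes the
Cost neuron a cost *predictor* and the Reward neuron a reward predictor;
feeding the combined $R$ to all three targets would depress the Cost
neuron's weights exactly when costs occur, destroying the predictive
interpretation the architecture depends on. Weights are clipped to
$[0, 1]$ to prevent runaway potentiation; $\alpha = 0.5$, and initial
plastic weights are uniform on $[0, 0.1]$ from a dedicated setup stream.
These structural constants (`w_drive`, the clip range, $\alpha$) were fixed
once, by pilot simulation, to give stable opponency dynamics — sessions that
neither freeze into one action nor ignore the learned predictions — and are
exposed as `network_params()` fields.

**Lesions.** `lesion(agent, "cost")` clamps the Cost neuron's activity to
zero (reversibly, weights untouched), emulating a serotonergic lesion; with
the clamp in place the safe action loses its drive and the agent escalates
almost unconditionally. A reward lesion has the opposite phenotype. A double
lesion sets $nm = 0$ and freezes all plasticity.

## The Actor-Critic agent

The Stag Hunt agent holds three tables over a discretized board state: the
binned Manhattan distances (bins $0\!-\!1$, $2\!-\!3$, $\ge 4$) of itself
and of the other player to the stag and to the nearest hare, $3^4 = 81$
states. Separate **Reward** and **Cost Critics** hold state values; the
**Actor** holds preferences for committing to the stag or to a hare.

Each turn the agent samples a commitment from the SoftMax policy
$P[c_1] = e^{V(c_1,s)} / (e^{V(c_1,s)} + e^{V(c_2,s)})$ and emits the greedy
move toward the committed target (ties broken uniformly). After the board
advances, each critic applies the delta rule
$\delta(t) = r(t) + V(s_t) - V(s_{t-1})$ and moves the previous state's
value by `critic_lr` $\cdot\ \delta$; terminal states carry value zero
(episode end). The reward signal is the payoff received; the cost signal is
the committed target's payoff entering negatively when that hunt fails (the
perceived loss of an unfulfilled expectation). The actor is updated with the
combined error $\delta_{total} = \delta_{reward} + \delta_{cost}$ in the
advantage form: chosen preference $+\,$`actor_lr`$\,(1 - P[chosen])\,
\delta_{total}$, unchosen $-\,$`actor_lr`$\,P[other]\,\delta_{total}$. The
naive update applying the same positive step to both choices would drift
both preferences upward irrespective of the decision and erase the SoftMax
contrast, so the advantage form is used.

Defaults: `critic_lr = 0.7`, `actor_lr = 0.5`, actor and Cost Critic start
at 0, Reward Critic at 1.5. The optimistic Reward Critic start (between the
hare and stag payoffs) is the exploration mechanism: early hare captures
undershoot it and register as disappointments, so the policy is pushed off
the sure-hare local optimum long enough to discover the joint stag hunt.
With a neutral start the per-turn SoftMax exploration is absorbing — any
transient hare commitment next to a hare ends the episode at the small
payoff — and policies converge on hare hunting even against a fully
cooperative partner.

## Game environments

* **Hawk-Dove**: two players contest a resource worth $V$ (default 1).
  Display/display splits it; a lone escalator takes it all; mutual
  escalation is a fight costing each player an injury drawn serious with
  probability `p_serious` (0.25 benign, 0.75 harsh; mild cost $0.75V$,
  serious $1.5V$, applied on top of a half share). One severity draw is made
  per fight and shared by both combatants, matching the single injury field
  per outcome. Choices are simultaneous; the spatial approach to the
  territory is abstracted away, since the decision variable is the action
  pair.
* **Chicken**: swerve/straight with payoffs 0 (lone swerver), 6 (lone
  straight), 2 each (both swerve), $-10$ each (collision). Deterministic.
* **Spatial Stag Hunt**: a $5 \times 5$ board with two players, one stag and
  two hares; simultaneous 4-connected moves (off-board moves clamp); games
  end on a capture or at 50 turns. Adjacency (on or orthogonally next to a
  token) is the catch condition, and a player catches what it is currently
  committed to hunting: a committed hare hunter adjacent to a hare captures
  it alone; the stag falls only when both players are adjacent and
  committed. Commitment gating is a deliberate design choice: under pure
  proximity capture, roughly half to two-thirds of games end in accidental
  hare captures even when both players are walking straight at the stag, so
  committed cooperation would be structurally impossible. The pure proximity
  rule remains available via the `hunt = "any"` default of
  `step_stag_hunt()`.

## Opponents and the strategy classifier

Set strategies cover the standard controls: always-cooperate and
always-defect (per game: display/escalate, swerve/straight, stag/hare),
uniform random, Win-Stay-Lose-Shift (repeat after a win, switch after a
loss; a win is a payoff strictly above a configurable threshold, default the
minimal non-negative outcome, 0) and Tit-for-Tat (copy the opponent's last
action), plus an `aggressive` opponent playing the risky action with
probability `p_aggress`. WSLS and T4T open cooperatively, the convention in
the iterated-game literature. `classify_strategy()` scores a realized
history against both templates as the fraction of moves from round 2 onward
matching each template's prediction; it depends only on win/loss labels, so
it is invariant to payoff scaling.

## Experiment runner

`run_session()` plays one seeded session; the master seed fans out into
named substreams (`setup`, `p1`, `p2`, `game`) so that paired arms share
environment randomness. `run_lesion_study()` runs intact and lesioned arms
under the identical master seed and reports both escalation proportions and
their difference. Records are one row per decision, including the agents'
internal variables (cost/reward activities, neuromodulation, reinforcement,
or the policy and delta for the Actor-Critic), serialized as JSON lines at
full precision so that `summarize_records()` recomputed from a persisted log
equals the live summary exactly. A thin command-line front end
(`exec/opponency`) exposes `simulate`, `lesion`, `summarize`,
`synth-subjects` and `fit-cognitive` over YAML configs.

### Study conditions

The two headline network phenomena are measured under fixed default
conditions, chosen once:

* **Gating** (escalation conditioned on $s_{reward} > s_{cost}$): benign
  Hawk-Dove (`p_serious = 0.25`) against Tit-for-Tat, 500 rounds. T4T
  induces the full cooperate / exploit / fight / back-off cycle through the
  state space, so both signs of the reward-cost comparison occur often;
  against fixed or random opponents whole sessions can degenerate into a
  single action and the conditional comparison becomes vacuous.
* **Lesion study**: harsh Hawk-Dove (`p_serious = 0.75`) against
  Tit-for-Tat, 500 rounds per arm, 10 master seeds. The retaliatory
  opponent makes escalation genuinely costly, so the intact agent holds a
  mixed policy while the cost-lesioned agent escalates nearly always.
* **Actor-Critic rationality**: 300 games per session against always-stag
  and always-hare partners, 20 seeds. The final policy is summarized by
  `start_state_policy()`: the SoftMax stag probability at the feature states
  in which the session's games began. Evaluating on fresh random boards
  would mix in feature states never visited during training, where the
  tabular policy is still the uninformative 0.5 prior, biasing both
  endpoints toward 0.5.

## The cognitive model

The latent-mixture model addresses subgroup structure in escalation
behavior. For subject $i$ with group $z_i \in \{1, 2\}$ and condition $c$:

$$k_{ic} \sim \text{Binomial}(n_{ic}, p_{ic}), \qquad
\text{logit}(p_{ic}) = \beta_i + \theta_{z_i, c},$$

with $\theta_{\cdot, baseline} = 0$, $\beta_i \sim N(0, 1.5^2)$ on the logit
scale (weakly informative on the probability scale), and effects given
half-normal$(1)$ magnitudes under the sign constraint
$\theta_{1,c} < 0 < \theta_{2,c}$: group 1 decreases escalation relative to
baseline, group 2 increases it. The sign constraint identifies the groups
and prevents label switching (tested: no retained draw violates the
ordering). Group membership has a uniform prior. Two groups are the tested
default; the middle "unbiased" ground is represented as low-confidence
assignment (`assign_groups()` labels a subject only when its posterior group
probability exceeds 0.75), not as a third mixture component.

The sampler is Metropolis-within-Gibbs: vectorized independent random-walk
proposals for the subject baselines, random-walk proposals for each group
effect rejected outside its sign region, and an exact Gibbs draw of each
$z_i$ from its two-point conditional. Defaults: 4 chains of 5,000 draws
with 2,000 burn-in, proposal SD 0.25, split-chain convergence diagnostic
with threshold 1.01 (reported as a warning, not fatal). The fit is fully
deterministic given its seed, and subjects are ordered internally by label,
so permuting the input rows permutes nothing.

`synth_subjects()` generates recovery datasets from the same generative
process (defaults: 8 subjects, 4 per group, baselines $\sim N(0, 0.5)$,
effects $\pm 1.5$ logits, 100 trials per cell, two conditions), recording
the generating latents. These defaults emulate the scale of the study the
model was built for — a small cohort with many repeated binary decisions and
a clean two-group structure. What synthetic recovery does *not* establish:
that real subjects follow a binomial with a constant per-condition
probability (no learning or drift within a session), that exactly two
subgroups exist, or that condition effects are exchangeable across subjects
within a group. Passing recovery shows the inference machinery is sound, not
that the model is true of any particular population.

## Numerical choices and degenerate inputs

* Firing-rate updates are convex combinations, so no clipping of activities
  is ever needed; weight clipping to $[0, 1]$ is the only projection.
* SoftMax is computed with max subtraction; preferences of $\pm 1000$ are
  safe.
* Exact action-neuron ties (possible only with noise off) are broken
  uniformly from the decision stream.
* Off-board Stag Hunt moves clamp to the current cell; stepping a terminal
  state is an error; boards too small for the token count are rejected at
  setup.
* In the mixture model, subjects missing a condition, counts outside
  $[0, n]$, and datasets without a baseline condition or a non-baseline
  condition are rejected with informative errors. An all-escalate subject is
  handled by the prior, which keeps the posterior proper.
* Every stochastic branch draws from an explicit `rng_stream`; nothing
  touches the global `.Random.seed`.

## Problem sizes

The test suite runs sessions of 40–500 rounds, Stag Hunt training of
150–300 games, and mixture fits of 2 chains x 1,200 draws for unit checks
and the full 4 x 5,000 sampler for recovery; the acceptance script uses 10
seeds x 500 rounds (lesion), 500 rounds (gating), 20 seeds x 300 games x 2
partners (Actor-Critic), 400-round histories (classifier) and 5 generator
seeds of 8 subjects (recovery). These sizes were chosen so each quantity's
sampling error is small relative to the effect it measures.

## Known limitations

* The network agent's state is the previous joint outcome only; longer
  memories (and therefore strategies conditioned on runs) are out of reach.
* The structural drive wiring fixes the direction of the opponency; the
  model cannot discover an inverted mapping.
* The Actor-Critic is tabular and undiscounted with per-turn commitment
  resampling; it has no eligibility traces, so credit reaches early states
  only through the critics' bootstrapping.
* Hawk-Dove and Chicken are reduced to their simultaneous binary choice;
  the embodied navigation phase of the original platform (and any
  asynchronous-choice variant of Hawk-Dove) is not simulated.
* The mixture model fixes two groups with condition effects shared within a
  group; subject-specific effect magnitudes would require a further
  hierarchy level.
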