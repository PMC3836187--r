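#' Neural network agent parameters
#'
#' Parameters of the adaptive mean-firing-rate network. The salient-input
#' amplitude `b` is game-dependent (0.75 for Hawk-Dove, 0.45 for Chicken).
#' Action and neuromodulatory neurons follow
#' `s(t) = rho * s(t-1) + (1 - rho) * sigmoid(gain * I(t))`, with `rho = 0.1`
#' and `gain = 5`. Phasic neuromodulation amplifies sensory (input-to-action)
#' and intrinsic inhibitory connections by `phasic_gain` (10) times the mean
#' activity of the Cost and Reward neurons; all other connections carry a
#' neuromodulation factor of 1.
#'
#' @param game `"hawk_dove"` or `"chicken"`; sets the default `b`.
#' @param b salient-input amplitude; overrides the game default.
#' @param rho persistence constant in \[0, 1).
#' @param sigmoid_gain slope of the activation sigmoid.
#' @param phasic_gain amplification applied to sensory and inhibitory
#'   connections, scaled by mean neuromodulatory activity.
#' @param alpha learning rate of the plasticity rule.
#' @param settle_steps network updates run before an action is read out.
#' @param input_noise_range uniform noise added to every input neuron.
#' @param synaptic_noise_range uniform noise added to every synaptic input.
#' @param weight_init_range uniform range for initial plastic weights.
#' @param weight_clip plastic weights are clipped to this non-negative range
#'   after every update (stabilizes learning under repeated reinforcement).
#' @param w_inhibitory,w_excitatory fixed intrinsic action-to-action weights
#'   (inhibition is phasically amplified, excitation is not).
#' @param w_drive fixed weight of the Reward neuron onto the risky action
#'   neuron and of the Cost neuron onto the safe action neuron. This
#'   structural opponency makes reward expectation drive risk taking and
#'   cost expectation drive withdrawal.
#' @param noise logical; `FALSE` switches all noise off (used by exact
#'   oracle tests).
#' @return a list of class `network_params`.
#' @export
network_params <- function(game = c("hawk_dove", "chicken"), b = NULL,
                           rho = 0.1, sigmoid_gain = 5, phasic_gain = 10,
                           alpha = 0.5, settle_steps = 10,
                           input_noise_range = c(0, 0.25),
                           synaptic_noise_range = c(-0.5, 0),
                           weight_init_range = c(0, 0.1),
                           weight_clip = c(0, 1),
                           w_inhibitory = 1, w_excitatory = 0.1,
                           w_drive = 3, noise = TRUE) {
  game <- match.arg(game)
  if (is.null(b)) b <- if (game == "hawk_dove") 0.75 else 0.45
  stopifnot(rho >= 0, rho < 1, phasic_gain > 1, alpha > 0, settle_steps >= 1,
            weight_clip[1] >= 0)
  structure(list(game = game, b = b, rho = rho, sigmoid_gain = sigmoid_gain,
                 phasic_gain = phasic_gain, alpha = alpha,
                 settle_steps = settle_steps,
                 input_noise_range = input_noise_range,
                 synaptic_noise_range = synaptic_noise_range,
                 weight_init_range = weight_init_range,
                 weight_clip = weight_clip, w_inhibitory = w_inhibitory,
                 w_excitatory = w_excitatory, w_drive = w_drive,
                 noise = noise),
            class = "network_params")
}

.input_states <- c("start", "safe_safe", "safe_risky", "risky_safe",
                   "risky_risky")

.game_actions <- function(game) {
  # action neuron 1 is the risky action, 2 the safe one
  switch(game,
         hawk_dove = c(risky = "escalate", safe = "display"),
         chicken = c(risky = "straight", safe = "swerve"),
         stop(sprintf("unknown game '%s'", game)))
}

#' Construct an adaptive neural network agent
#'
#' The network has one Game-Dependent Input Neuron per observable state (the
#' previous round's joint outcome, plus a game-start state), two Action
#' Neurons with reciprocal excitatory and inhibitory connections, and two
#' Neuromodulatory Neurons: Cost (serotonergic) and Reward (dopaminergic).
#' Plastic weights run from the input neurons to the action and
#' neuromodulatory neurons. The agent is a mutable environment; the
#' per-round verbs [neural_act()] and [neural_learn()] update it in place.
#'
#' @param game `"hawk_dove"` or `"chicken"`.
#' @param params a [network_params()].
#' @param stream [rng_stream()] used to draw the initial plastic weights.
#' @return an environment of class `neural_agent`.
#' @export
neural_agent <- function(game = c("hawk_dove", "chicken"),
                         params = NULL, stream = rng_stream(1)) {
  game <- match.arg(game)
  if (is.null(params)) params <- network_params(game)
  stopifnot(inherits(params, "network_params"))
  n_in <- length(.input_states)
  wr <- params$weight_init_range
  a <- new.env(parent = emptyenv())
  a$game <- game
  a$params <- params
  a$actions <- .game_actions(game)
  a$W_act <- matrix(stream_runif(stream, n_in * 2, wr[1], wr[2]), n_in, 2,
                    dimnames = list(.input_states, c("risky", "safe")))
  a$W_cost <- stats::setNames(stream_runif(stream, n_in, wr[1], wr[2]),
                              .input_states)
  a$W_reward <- stats::setNames(stream_runif(stream, n_in, wr[1], wr[2]),
                                .input_states)
  a$s_act <- c(risky = 0, safe = 0)
  a$s_cost <- 0
  a$s_reward <- 0
  a$lesions <- c(cost = FALSE, reward = FALSE)
  a$last <- NULL
  class(a) <- "neural_agent"
  a
}

#' @export
print.neural_agent <- function(x, ...) {
  cat(sprintf("<neural_agent: %s>\n", x$game))
  cat(sprintf("  actions: %s (risky), %s (safe)\n",
              x$actions["risky"], x$actions["safe"]))
  cat(sprintf("  activities: s_cost = %.3f, s_reward = %.3f\n",
              x$s_cost, x$s_reward))
  les <- names(x$lesions)[x$lesions]
  if (length(les)) cat("  lesioned:", paste(les, collapse = ", "), "\n")
  invisible(x)
}

#' Game-Dependent Input Neuron activities
#'
#' The salient input neuron fires at `b` plus uniform noise; all others
#' carry noise alone. Noise is drawn fresh per neuron per call.
#'
#' @param salient_index index of the currently salient environmental state.
#' @param params a [network_params()].
#' @param stream an [rng_stream()].
#' @param n_inputs number of input neurons.
#' @return numeric vector of activities.
#' @export
input_activity <- function(salient_index, params, stream,
                           n_inputs = length(.input_states)) {
  if (salient_index < 1 || salient_index > n_inputs)
    stop(sprintf("salient index %s out of range", salient_index))
  noise <- if (params$noise)
    stream_runif(stream, n_inputs, params$input_noise_range[1],
                 params$input_noise_range[2])
  else rep(0, n_inputs)
  n <- noise
  n[salient_index] <- n[salient_index] + params$b
  n
}

#' Synaptic input to one neuron
#'
#' `I = noise + sum(nm * w * s_pre)` where `nm` is the neuromodulation level
#' on each connection (the phasic factor on sensory and inhibitory
#' connections, 1 elsewhere).
#'
#' @param w vector of connection weights onto the neuron.
#' @param s_pre presynaptic activities.
#' @param nm neuromodulation factor per connection (recycled).
#' @param noise scalar input noise.
#' @return scalar synaptic input.
#' @export
synaptic_input <- function(w, s_pre, nm = 1, noise = 0)
  noise + sum(nm * w * s_pre)

#' One mean-firing-rate update
#'
#' `s(t) = rho * s(t-1) + (1 - rho) / (1 + exp(-gain * I))`; a convex
#' combination of values in \[0, 1\], so activities stay bounded.
#'
#' @param prev previous activity (vectorized).
#' @param I synaptic input.
#' @param params a [network_params()].
#' @return updated activity.
#' @export
step_neuron <- function(prev, I, params)
  params$rho * prev + (1 - params$rho) /
    (1 + exp(-params$sigmoid_gain * I))

.syn_noise <- function(params, stream, n) {
  if (params$noise)
    stream_runif(stream, n, params$synaptic_noise_range[1],
                 params$synaptic_noise_range[2])
  else rep(0, n)
}

#' Settle the network and read out an action
#'
#' Runs `settle_steps` synchronous updates of the action and neuromodulatory
#' neurons under the current salient input (input noise resampled each
#' step), then returns the action whose neuron ends with the higher
#' activity; exact ties are broken uniformly at random.
#'
#' @param agent a [neural_agent()], updated in place.
#' @param salient_index index into the agent's input states (see
#'   [neural_salient_index()]).
#' @param stream an [rng_stream()] for all agent-internal randomness.
#' @return the chosen action label.
#' @export
neural_act <- function(agent, salient_index, stream) {
  p <- agent$params
  # each round is a fresh decision: the action pool settles anew, while the
  # neuromodulatory activities persist and carry the learned predictions
  agent$s_act <- c(risky = 0, safe = 0)
  n <- NULL
  for (step in seq_len(p$settle_steps)) {
    n <- input_activity(salient_index, p, stream)
    sc <- if (agent$lesions["cost"]) 0 else agent$s_cost
    sr <- if (agent$lesions["reward"]) 0 else agent$s_reward
    nm_ph <- p$phasic_gain * mean(c(sc, sr))
    noise <- .syn_noise(p, stream, 4)
    I_risky <- synaptic_input(agent$W_act[, "risky"], n, nm_ph, noise[1]) +
      nm_ph * (-p$w_inhibitory) * agent$s_act["safe"] +
      p$w_excitatory * agent$s_act["safe"] + p$w_drive * sr
    I_safe <- synaptic_input(agent$W_act[, "safe"], n, nm_ph, noise[2]) +
      nm_ph * (-p$w_inhibitory) * agent$s_act["risky"] +
      p$w_excitatory * agent$s_act["risky"] + p$w_drive * sc
    I_cost <- synaptic_input(agent$W_cost, n, 1, noise[3])
    I_reward <- synaptic_input(agent$W_reward, n, 1, noise[4])
    agent$s_act <- step_neuron(agent$s_act, c(I_risky, I_safe), p)
    agent$s_cost <- if (agent$lesions["cost"]) 0
                    else unname(step_neuron(sc, I_cost, p))
    agent$s_reward <- if (agent$lesions["reward"]) 0
                      else unname(step_neuron(sr, I_reward, p))
  }
  idx <- if (agent$s_act[1] == agent$s_act[2])
    stream_sample(stream, 1:2) else which.max(agent$s_act)
  agent$last <- list(salient = salient_index, n = n, action = idx,
                     s_act = agent$s_act, s_cost = agent$s_cost,
                     s_reward = agent$s_reward)
  unname(agent$actions[idx])
}

#' Reinforcement signal
#'
#' Dual prediction error: positive when reward was under-predicted or cost
#' over-predicted, zero when both neuromodulatory neurons exactly predict
#' the magnitudes received.
#'
#' @param reward_received,cost_received non-negative magnitudes extracted
#'   from the game payoff.
#' @param s_reward,s_cost neuromodulatory activities at decision time.
#' @return scalar reinforcement `(reward_received - s_reward) -
#'   (cost_received - s_cost)`.
#' @export
reinforcement <- function(reward_received, cost_received, s_reward, s_cost) {
  stopifnot(reward_received >= 0, cost_received >= 0,
            is.finite(reward_received), is.finite(cost_received))
  (reward_received - s_reward) - (cost_received - s_cost)
}

#' Apply the neuromodulated plasticity rule
#'
#' Only connections from the most-active input neuron change. The
#' input-to-action weight of the winning action neuron moves with the
#' combined reinforcement `R`; the input weights of the Cost and Reward
#' neurons move with their own prediction errors, so that each
#' neuromodulatory neuron learns to predict the magnitude it encodes. Every
#' update is the Hebbian product `alpha * nm * s_pre * s_post * error` with
#' `nm` the mean neuromodulatory activity, and weights are clipped to
#' `weight_clip`.
#'
#' @param agent a [neural_agent()] that has acted this round (in place).
#' @param reward_received,cost_received magnitudes from the game outcome.
#' @return invisibly, a list with `R`, `nm` and the three weight changes.
#' @export
neural_learn <- function(agent, reward_received, cost_received) {
  if (is.null(agent$last)) stop("agent has not acted yet this round")
  p <- agent$params
  sc <- agent$last$s_cost
  sr <- agent$last$s_reward
  err_r <- reward_received - sr
  err_c <- cost_received - sc
  R <- reinforcement(reward_received, cost_received, sr, sc)
  nm <- mean(c(sc, sr))
  j <- which.max(agent$last$n)
  i <- agent$last$action
  n_j <- agent$last$n[j]
  clip <- function(w) pmin(pmax(w, p$weight_clip[1]), p$weight_clip[2])
  dw_act <- p$alpha * nm * n_j * agent$last$s_act[i] * R
  dw_rew <- p$alpha * nm * n_j * sr * err_r
  dw_cost <- p$alpha * nm * n_j * sc * err_c
  agent$W_act[j, i] <- clip(agent$W_act[j, i] + dw_act)
  agent$W_reward[j] <- clip(agent$W_reward[j] + dw_rew)
  agent$W_cost[j] <- clip(agent$W_cost[j] + dw_cost)
  agent$last$R <- R
  agent$last$nm <- nm
  agent$last$dw <- c(action = unname(dw_act), reward = dw_rew,
                     cost = dw_cost)
  invisible(agent$last[c("R", "nm", "dw")])
}

#' Simulated neuromodulatory lesion
#'
#' Clamps the named neuromodulatory neuron's activity to 0 for all
#' subsequent steps; `unlesion()` removes the clamp, and dynamics resume
#' from the current weights (no weight destruction).
#'
#' @param agent a [neural_agent()], modified in place.
#' @param target `"cost"` (serotonergic) or `"reward"` (dopaminergic).
#' @return the agent, invisibly.
#' @export
lesion <- function(agent, target = c("cost", "reward")) {
  target <- match.arg(target)
  agent$lesions[target] <- TRUE
  if (target == "cost") agent$s_cost <- 0 else agent$s_reward <- 0
  invisible(agent)
}

#' @rdname lesion
#' @export
unlesion <- function(agent, target = c("cost", "reward")) {
  target <- match.arg(target)
  agent$lesions[target] <- FALSE
  invisible(agent)
}

#' Index of the salient environmental state
#'
#' The network observes the previous round's joint outcome (own action
#' crossed with the opponent's, coded risky/safe) or the game-start state.
#'
#' @param own_prev,opp_prev previous-round action labels, or `NULL` at game
#'   start.
#' @param actions named action vector (`risky`, `safe`) as stored on the
#'   agent.
#' @return integer index into the input-state alphabet.
#' @export
neural_salient_index <- function(own_prev, opp_prev, actions) {
  if (is.null(own_prev) || is.null(opp_prev)) return(1L)
  code <- function(x) if (x == actions[["risky"]]) "risky" else "safe"
  match(paste(code(own_prev), code(opp_prev), sep = "_"), .input_states)
}

#' Reward and cost magnitudes of a game outcome
#'
#' Decomposes a player's payoff into the non-negative reward and cost
#' magnitudes the neuromodulatory neurons predict. In Hawk-Dove the reward
#' is the share of the resource obtained (all, half, or none) and the cost
#' is the injury cost on a fight; in Chicken the reward is the positive
#' payoff and the cost the magnitude of a negative payoff.
#'
#' @param outcome a `game_outcome`.
#' @param player 1 or 2.
#' @param cfg the game configuration the outcome came from.
#' @return list with elements `reward` and `cost`.
#' @export
outcome_reinforcement <- function(outcome, player, cfg) {
  stopifnot(inherits(outcome, "game_outcome"), player %in% 1:2)
  own <- if (player == 1) outcome$action_p1 else outcome$action_p2
  pay <- if (player == 1) outcome$payoff_p1 else outcome$payoff_p2
  if (inherits(cfg, "hawk_dove_config")) {
    v <- cfg$resource_value
    fight <- outcome$injury != "none"
    reward <- if (fight) v / 2
      else if (own == "escalate" && pay > 0) v
      else if (own == "display" && pay > 0) v / 2
      else 0
    cost <- if (fight)
      switch(outcome$injury, mild = cfg$mild_injury_cost,
             serious = cfg$serious_injury_cost)
    else 0
    list(reward = reward, cost = cost)
  } else {
    list(reward = max(pay, 0), cost = max(-pay, 0))
  }
}
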