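#' Actor-Critic parameters
#'
#' @param critic_lr learning rate of the Reward and Cost Critic updates,
#'   in (0, 1].
#' @param actor_lr learning rate of the Actor preference updates, in (0, 1].
#' @param init_value initial value of the Actor and Cost Critic entries.
#' @param reward_init initial value of the Reward Critic entries. The
#'   mildly optimistic default (between the hare and stag payoffs) makes
#'   early captures that undershoot it register as disappointments, which
#'   drives systematic early exploration and keeps the policy from locking
#'   onto the first hare it meets.
#' @return a list of class `ac_params`.
#' @export
ac_params <- function(critic_lr = 0.7, actor_lr = 0.5, init_value = 0,
                      reward_init = 1.5) {
  stopifnot(critic_lr > 0, critic_lr <= 1, actor_lr > 0, actor_lr <= 1)
  structure(list(critic_lr = critic_lr, actor_lr = actor_lr,
                 init_value = init_value, reward_init = reward_init),
            class = "ac_params")
}

.dist_bin <- function(d) if (d <= 1) 1L else if (d <= 3) 2L else 3L

.manhattan <- function(a, b) sum(abs(a - b))

#' Featurize a Stag Hunt board state
#'
#' The state is the tuple of binned Manhattan distances (bins 0-1, 2-3, >= 4)
#' of the player and of the other player to the stag and to the nearest
#' hare, giving a 3^4 = 81-entry state table. The agent is thus sensitive
#' not only to its own distance to the tokens but to the other player's.
#'
#' @param state a `stag_hunt_state`.
#' @param player which player (1 or 2) is "self".
#' @return a 4-character state key, e.g. `"1231"`.
#' @export
stag_features <- function(state, player = 1) {
  own <- if (player == 1) state$p1 else state$p2
  oth <- if (player == 1) state$p2 else state$p1
  d_hare <- function(p) min(apply(state$hares, 1, .manhattan, b = p))
  bins <- c(.dist_bin(.manhattan(own, state$stag)), .dist_bin(d_hare(own)),
            .dist_bin(.manhattan(oth, state$stag)), .dist_bin(d_hare(oth)))
  paste(bins, collapse = "")
}

.all_state_keys <- function() {
  g <- expand.grid(1:3, 1:3, 1:3, 1:3)
  apply(g[, 4:1], 1, paste, collapse = "")
}

#' Temporal-difference error
#'
#' `delta(t) = r(t) + V(s_now) - V(s_prev)`.
#'
#' @param r scalar signal at time t (reward, or the negated cost).
#' @param v_now value of the current state.
#' @param v_prev value of the previous state.
#' @return scalar prediction error.
#' @export
td_delta <- function(r, v_now, v_prev) {
  stopifnot(is.finite(r), is.finite(v_now), is.finite(v_prev))
  r + v_now - v_prev
}

#' Critic table update
#'
#' Moves the previous state's value by `lr * delta`.
#'
#' @param values named numeric vector of state values.
#' @param key state key of the previous state.
#' @param delta prediction error from [td_delta()].
#' @param lr critic learning rate.
#' @return the updated value vector.
#' @export
update_critic <- function(values, key, delta, lr) {
  values[key] <- values[key] + lr * delta
  values
}

#' SoftMax action probabilities
#'
#' `P[c] = exp(V(c, s)) / sum(exp(V(., s)))`, computed with max subtraction
#' for overflow safety (mathematically unchanged).
#'
#' @param prefs named numeric vector of actor preferences for one state.
#' @return probabilities summing to 1, same names.
#' @export
softmax_policy <- function(prefs) {
  stopifnot(all(is.finite(prefs)))
  e <- exp(prefs - max(prefs))
  e / sum(e)
}

#' Actor table update
#'
#' Advantage-style update: the chosen action's preference moves by
#' `lr * (1 - P[chosen]) * delta_total` and the unchosen one by
#' `-lr * P[other] * delta_total`, where `delta_total` combines the Reward
#' and Cost Critic errors.
#'
#' @param actor matrix of preferences (states x choices).
#' @param key state key.
#' @param chosen chosen action label (a column of `actor`).
#' @param delta_total combined prediction error.
#' @param P policy probabilities from [softmax_policy()] at this state.
#' @param lr actor learning rate.
#' @return the updated actor matrix.
#' @export
update_actor <- function(actor, key, chosen, delta_total, P, lr) {
  other <- setdiff(colnames(actor), chosen)
  actor[key, chosen] <- actor[key, chosen] +
    lr * (1 - P[[chosen]]) * delta_total
  actor[key, other] <- actor[key, other] - lr * P[[other]] * delta_total
  actor
}

#' Construct an Actor-Critic Stag Hunt agent
#'
#' Holds three state tables over the 81 featurized board states: a Reward
#' Critic and a Cost Critic (state values) and an Actor (preferences for
#' hunting stag vs. hare). Each turn the agent samples a target from the
#' SoftMax policy, emits the greedy move toward it, and after the board
#' advances updates both critics by the delta rule and the actor by the
#' combined error. The reward signal is the payoff received; the cost
#' signal is the chosen target's payoff, forfeited when that hunt fails
#' (perceived loss of an unfulfilled expectation).
#'
#' @param cfg a [stag_hunt_config()].
#' @param params an [ac_params()].
#' @param player which seat the agent occupies (1 or 2).
#' @return an environment of class `ac_agent`.
#' @export
ac_agent <- function(cfg, params = ac_params(), player = 1) {
  stopifnot(inherits(cfg, "stag_hunt_config"), inherits(params, "ac_params"))
  keys <- .all_state_keys()
  a <- new.env(parent = emptyenv())
  a$cfg <- cfg
  a$params <- params
  a$player <- player
  a$v_reward <- stats::setNames(rep(params$reward_init, length(keys)), keys)
  a$v_cost <- stats::setNames(rep(params$init_value, length(keys)), keys)
  a$actor <- matrix(params$init_value, length(keys), 2,
                    dimnames = list(keys, c("stag", "hare")))
  a$prev <- NULL
  class(a) <- "ac_agent"
  a
}

#' @export
print.ac_agent <- function(x, ...) {
  cat(sprintf("<ac_agent: player %d, %d states>\n", x$player,
              nrow(x$actor)))
  cat(sprintf("  critic lr %.3g, actor lr %.3g\n",
              x$params$critic_lr, x$params$actor_lr))
  invisible(x)
}

.nearest_hare <- function(state, pos) {
  d <- apply(state$hares, 1, .manhattan, b = pos)
  state$hares[which.min(d), ]
}

#' Greedy move toward a target cell
#'
#' Picks, uniformly among ties, a move (cardinal or stay) minimizing the
#' Manhattan distance of the resulting on-board position to `target`.
#'
#' @param pos current 0-based position.
#' @param target 0-based target cell.
#' @param board_size board side length.
#' @param stream an [rng_stream()] for tie-breaking.
#' @return a move label.
#' @export
greedy_move <- function(pos, target, board_size, stream) {
  moves <- c("up", "down", "left", "right", "stay")
  d <- vapply(moves, function(m)
    .manhattan(.clamp_move(pos, m, board_size), target), numeric(1))
  best <- moves[d == min(d)]
  if (length(best) == 1) best else stream_sample(stream, best)
}

#' Choose the agent's move for the current turn
#'
#' Featurizes the board, samples a hunt target (stag or hare) from the
#' SoftMax policy, and returns the greedy move toward the sampled target.
#'
#' @param agent an [ac_agent()], updated in place.
#' @param state a non-terminal `stag_hunt_state`.
#' @param stream an [rng_stream()].
#' @return a move label.
#' @export
ac_act <- function(agent, state, stream) {
  if (state$terminal) stop("cannot act in a terminal state")
  key <- stag_features(state, agent$player)
  P <- softmax_policy(agent$actor[key, ])
  choice <- stream_sample(stream, c("stag", "hare"), prob = P)
  own <- if (agent$player == 1) state$p1 else state$p2
  target <- if (choice == "stag") state$stag else .nearest_hare(state, own)
  agent$prev <- list(key = key, choice = choice, P = P)
  greedy_move(own, target, state$board_size, stream)
}

#' Update the Actor-Critic tables after a turn
#'
#' Runs the delta rule for both critics (the cost signal enters with
#' negative sign) against the new board state, updates the previous state's
#' critic values, and applies the actor update with the combined error.
#' Terminal states carry value 0 (episode end).
#'
#' @param agent an [ac_agent()] that acted this turn, updated in place.
#' @param state the `stag_hunt_state` after the turn.
#' @return invisibly, a list with `delta_reward`, `delta_cost`,
#'   `delta_total` and the policy used.
#' @export
ac_learn <- function(agent, state) {
  if (is.null(agent$prev)) stop("agent has not acted this turn")
  p <- agent$params
  prev <- agent$prev
  own_pay <- if (agent$player == 1) state$outcome$payoff_p1
             else state$outcome$payoff_p2
  terminal <- state$terminal
  r_reward <- if (terminal) own_pay else 0
  r_cost <- 0
  if (terminal) {
    hunted_value <- if (prev$choice == "stag") agent$cfg$stag_payoff
                    else agent$cfg$hare_payoff
    fulfilled <- (prev$choice == "stag" && identical(state$capture, "stag")) ||
      (prev$choice == "hare" && identical(state$capture, "hare") &&
         own_pay > 0)
    if (!fulfilled) r_cost <- hunted_value
  }
  key_now <- stag_features(state, agent$player)
  v_r_now <- if (terminal) 0 else agent$v_reward[[key_now]]
  v_c_now <- if (terminal) 0 else agent$v_cost[[key_now]]
  d_r <- td_delta(r_reward, v_r_now, agent$v_reward[[prev$key]])
  d_c <- td_delta(-r_cost, v_c_now, agent$v_cost[[prev$key]])
  agent$v_reward <- update_critic(agent$v_reward, prev$key, d_r, p$critic_lr)
  agent$v_cost <- update_critic(agent$v_cost, prev$key, d_c, p$critic_lr)
  d_tot <- d_r + d_c
  agent$actor <- update_actor(agent$actor, prev$key, prev$choice, d_tot,
                              prev$P, p$actor_lr)
  agent$prev <- NULL
  invisible(list(delta_reward = d_r, delta_cost = d_c, delta_total = d_tot,
                 P = prev$P))
}

#' Serialize Actor-Critic tables to a flat data frame
#'
#' One row per (state, table, choice) with the current weight; suitable for
#' writing as CSV and for replay tests.
#'
#' @param agent an [ac_agent()].
#' @return data frame with columns `state`, `table`, `choice`, `weight`.
#' @export
ac_tables <- function(agent) {
  keys <- rownames(agent$actor)
  rbind(
    data.frame(state = keys, table = "reward_critic", choice = NA,
               weight = unname(agent$v_reward[keys])),
    data.frame(state = keys, table = "cost_critic", choice = NA,
               weight = unname(agent$v_cost[keys])),
    data.frame(state = rep(keys, 2), table = "actor",
               choice = rep(c("stag", "hare"), each = length(keys)),
               weight = c(agent$actor[, "stag"], agent$actor[, "hare"])))
}

#' Mean SoftMax probability of hunting stag at game start
#'
#' Averages the policy's stag probability over `n` random initial boards.
#'
#' @param agent an [ac_agent()].
#' @param cfg the [stag_hunt_config()].
#' @param stream an [rng_stream()] for the evaluation boards.
#' @param n number of boards.
#' @return scalar probability.
#' @export
p_stag_at_start <- function(agent, cfg, stream, n = 200) {
  mean(vapply(seq_len(n), function(i) {
    st <- stag_hunt_setup(cfg, stream)
    softmax_policy(agent$actor[stag_features(st, agent$player), ])[["stag"]]
  }, numeric(1)))
}
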