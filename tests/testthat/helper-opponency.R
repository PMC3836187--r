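# shared fixtures, built in code

noiseless_params <- function(game = "hawk_dove", ...)
  network_params(game, noise = FALSE, ...)

# a neural agent with frozen, hand-set weights and no noise, for exact oracles
frozen_agent <- function(game = "hawk_dove") {
  a <- neural_agent(game, noiseless_params(game), rng_stream(1))
  n_in <- nrow(a$W_act)
  a$W_act[] <- matrix(seq(0.05, 0.5, length.out = n_in * 2), n_in, 2)
  a$W_cost[] <- seq(0.02, 0.2, length.out = n_in)
  a$W_reward[] <- seq(0.3, 0.06, length.out = n_in)
  a
}

# deterministic history generator for strategy classification tests:
# a player following `model` (wsls/t4t) with flip probability eps, against
# a seeded random opponent in Hawk-Dove
simulate_strategy_history <- function(model, eps = 0, n = 400, seed = 42) {
  st <- stream_split(seed, c("opp", "noise", "game"))
  cfg <- hawk_dove_config()
  actions <- c(risky = "escalate", safe = "display")
  spec <- strategy_spec(model)
  opp_spec <- strategy_spec("random")
  h_own <- data.frame(own = character(), opp = character(),
                      payoff = numeric())
  h_opp <- h_own
  for (r in seq_len(n)) {
    a1 <- next_move(spec, h_own, actions, st$noise)
    if (eps > 0 && stream_runif(st$noise, 1) < eps)
      a1 <- setdiff(actions, a1)
    a2 <- next_move(opp_spec, h_opp, actions, st$opp)
    out <- resolve_hawk_dove(a1, a2, cfg, st$game)
    h_own[r, ] <- list(a1, a2, out$payoff_p1)
    h_opp[r, ] <- list(a2, a1, out$payoff_p2)
  }
  h_own
}

hd_session <- function(seed, opponent = "t4t", p_serious = 0.25,
                       n_rounds = 500, lesion = NULL) {
  run_session(experiment_config(
    "hawk_dove",
    players = list(neural_player(), strategy_spec(opponent)),
    game_config = hawk_dove_config(p_serious = p_serious),
    n_rounds = n_rounds, seed = seed, lesion = lesion))
}
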