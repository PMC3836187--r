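test_that("input neurons fire at the game's salient amplitude", {
  s <- rng_stream(1)
  hd <- noiseless_params("hawk_dove")
  n <- input_activity(2, hd, s)
  expect_equal(n[2], 0.75)
  expect_equal(n[-2], rep(0, 4))

  ch <- noiseless_params("chicken")
  expect_equal(input_activity(1, ch, s)[1], 0.45)

  noisy <- network_params("hawk_dove")
  for (i in 1:20) {
    n <- input_activity(3, noisy, s)
    expect_true(all(n >= 0 & n <= 0.75 + 0.25))
  }
  expect_error(input_activity(9, hd, s), "out of range")
})

test_that("synaptic input follows the neuromodulated sum", {
  expect_equal(synaptic_input(rep(0, 4), rep(0.5, 4)), 0)
  # phasic amplification: nm = 10 * mean(0.4, 0.4) = 4
  expect_equal(synaptic_input(0.5, 0.75, nm = 10 * mean(c(0.4, 0.4))), 1.5)
  # the same connection without amplification
  expect_equal(synaptic_input(0.5, 0.75, nm = 1), 0.375)
})

test_that("the firing-rate update has the sigmoid fixed point", {
  p <- noiseless_params()
  expect_equal(step_neuron(0.5, 0, p), 0.5)
  expect_equal(step_neuron(0, 1, p), 0.9 * (1 / (1 + exp(-5))),
               tolerance = 1e-12)
  expect_lte(step_neuron(1, 50, p), 1)
  # geometric convergence to the closed form at I in {-1, 0, 1}
  for (I in c(-1, 0, 1)) {
    s <- 0.123
    for (k in 1:60) s <- step_neuron(s, I, p)
    expect_equal(s, 1 / (1 + exp(-5 * I)), tolerance = 1e-9)
  }
})

test_that("activities stay in [0, 1] over 10,000 random steps", {
  s <- 0.5
  set.seed(4)
  for (k in 1:10000) {
    s <- step_neuron(s, stats::runif(1, -8, 8), noiseless_params())
    if (s < 0 || s > 1) break
  }
  expect_true(s >= 0 && s <= 1)

  # and at the agent level, with all noise sources active
  ses <- hd_session(31, n_rounds = 100)
  acts <- c(ses$records$p1_s_cost, ses$records$p1_s_reward)
  expect_true(all(acts >= 0 & acts <= 1))
})

test_that("reinforcement is the dual prediction error", {
  expect_equal(reinforcement(0.4, 0.7, s_reward = 0.4, s_cost = 0.7), 0)
  expect_equal(reinforcement(1, 0, 0, 0), 1)
  expect_equal(reinforcement(0, 1, 0, 0), -1)
  expect_equal(reinforcement(1.5, 0.5, s_reward = 0.5, s_cost = 0.5), 1)
  expect_error(reinforcement(-1, 0, 0, 0))
})

test_that("plasticity follows the Hebbian neuromodulated rule", {
  a <- neural_agent("hawk_dove", noiseless_params(alpha = 0.1),
                    rng_stream(2))
  w0 <- list(a$W_act, a$W_cost, a$W_reward)
  # hand-set post-decision state: n_j = 0.8 at input 1, winner activity 0.6,
  # both neuromodulatory activities 0.5 (nm = 0.5)
  a$last <- list(salient = 1L, n = c(0.8, 0, 0, 0, 0), action = 1L,
                 s_act = c(risky = 0.6, safe = 0.1),
                 s_cost = 0.5, s_reward = 0.5)
  # reward 1.5, cost 0.5 -> R = (1.5 - 0.5) - (0.5 - 0.5) = 1
  upd <- neural_learn(a, 1.5, 0.5)
  expect_equal(upd$R, 1)
  expect_equal(unname(upd$dw["action"]), 0.1 * 0.5 * 0.8 * 0.6 * 1)
  expect_equal(a$W_act[1, 1] - w0[[1]][1, 1], 0.024)
  # only the most-active input's connections change
  expect_equal(a$W_act[-1, ], w0[[1]][-1, ])
  expect_equal(a$W_cost[-1], w0[[2]][-1])

  # R = 0 freezes the action pathway; matching predictions freeze everything
  a$last <- list(salient = 1L, n = c(0.8, 0, 0, 0, 0), action = 1L,
                 s_act = c(risky = 0.6, safe = 0.1),
                 s_cost = 0.5, s_reward = 0.5)
  before <- a$W_act
  neural_learn(a, 0.5, 0.5)
  expect_equal(a$W_act, before)

  # a double lesion makes nm = 0 and freezes all plasticity
  b <- neural_agent("hawk_dove", noiseless_params(), rng_stream(3))
  lesion(b, "cost")
  lesion(b, "reward")
  st <- rng_stream(4)
  neural_act(b, 1, st)
  wb <- list(b$W_act, b$W_cost, b$W_reward)
  neural_learn(b, 1, 1)
  expect_identical(list(b$W_act, b$W_cost, b$W_reward), wb)
})

test_that("a full decide-learn cycle matches a straight-line transcription", {
  a <- frozen_agent("hawk_dove")
  p <- a$params
  W_act <- a$W_act
  W_cost <- a$W_cost
  W_reward <- a$W_reward

  # independent straight-line transcription of the update equations
  s_act <- c(0, 0)
  sc <- sr <- 0
  sal <- 2L
  for (step in 1:p$settle_steps) {
    n <- rep(0, 5)
    n[sal] <- p$b
    nm_ph <- p$phasic_gain * mean(c(sc, sr))
    sig <- function(I) 1 / (1 + exp(-p$sigmoid_gain * I))
    I1 <- sum(nm_ph * W_act[, 1] * n) - nm_ph * p$w_inhibitory * s_act[2] +
      p$w_excitatory * s_act[2] + p$w_drive * sr
    I2 <- sum(nm_ph * W_act[, 2] * n) - nm_ph * p$w_inhibitory * s_act[1] +
      p$w_excitatory * s_act[1] + p$w_drive * sc
    Ic <- sum(W_cost * n)
    Ir <- sum(W_reward * n)
    s_act <- p$rho * s_act + (1 - p$rho) * c(sig(I1), sig(I2))
    sc <- p$rho * sc + (1 - p$rho) * sig(Ic)
    sr <- p$rho * sr + (1 - p$rho) * sig(Ir)
  }
  choice <- which.max(s_act)
  reward <- 0.5
  cost <- 0.75
  err_r <- reward - sr
  err_c <- cost - sc
  R <- err_r - err_c
  nm <- mean(c(sc, sr))
  exp_W_act <- W_act
  exp_W_act[sal, choice] <- min(max(
    W_act[sal, choice] + p$alpha * nm * p$b * s_act[choice] * R,
    p$weight_clip[1]), p$weight_clip[2])
  exp_W_rew <- W_reward
  exp_W_rew[sal] <- min(max(W_reward[sal] + p$alpha * nm * p$b * sr * err_r,
                            p$weight_clip[1]), p$weight_clip[2])
  exp_W_cost <- W_cost
  exp_W_cost[sal] <- min(max(W_cost[sal] + p$alpha * nm * p$b * sc * err_c,
                             p$weight_clip[1]), p$weight_clip[2])

  st <- rng_stream(10)
  act <- neural_act(a, sal, st)
  expect_identical(act, unname(a$actions[choice]))
  expect_equal(a$s_act, c(risky = s_act[1], safe = s_act[2]),
               tolerance = 1e-12)
  expect_equal(a$s_cost, sc, tolerance = 1e-12)
  expect_equal(a$s_reward, sr, tolerance = 1e-12)
  neural_learn(a, reward, cost)
  expect_equal(a$W_act, exp_W_act, tolerance = 1e-12)
  expect_equal(a$W_reward, exp_W_rew, tolerance = 1e-12)
  expect_equal(a$W_cost, exp_W_cost, tolerance = 1e-12)
})

test_that("lesions clamp activity, halve nm, and are reversible", {
  a <- neural_agent("hawk_dove", network_params("hawk_dove"), rng_stream(5))
  st <- rng_stream(6)
  lesion(a, "cost")
  neural_act(a, 1, st)
  expect_identical(a$s_cost, 0)
  expect_gt(a$s_reward, 0)
  # matched states: with s_cost clamped, nm halves when s_cost == s_reward
  sr <- a$s_reward
  expect_equal(mean(c(0, sr)), mean(c(sr, sr)) / 2)
  w_after <- a$W_act
  unlesion(a, "cost")
  expect_identical(a$W_act, w_after) # no weight destruction
  neural_act(a, 1, st)
  expect_gt(a$s_cost, 0)
  expect_error(lesion(a, "serotonin"))
})

test_that("tied symmetric activities split the decision about 50/50", {
  n_risky <- 0
  for (seed in 1:200) {
    a <- neural_agent("hawk_dove", noiseless_params(), rng_stream(1))
    # fully symmetric weights and no noise -> exact tie
    a$W_act[] <- 0.1
    a$W_cost[] <- 0.1
    a$W_reward[] <- 0.1
    st <- rng_stream(seed)
    if (neural_act(a, 1, st) == "escalate") n_risky <- n_risky + 1
  }
  expect_gt(n_risky, 70)
  expect_lt(n_risky, 130)
})

test_that("salient index encodes the previous joint outcome", {
  actions <- c(risky = "escalate", safe = "display")
  expect_equal(neural_salient_index(NULL, NULL, actions), 1L)
  expect_equal(neural_salient_index("display", "display", actions), 2L)
  expect_equal(neural_salient_index("display", "escalate", actions), 3L)
  expect_equal(neural_salient_index("escalate", "display", actions), 4L)
  expect_equal(neural_salient_index("escalate", "escalate", actions), 5L)
})

test_that("outcome decomposition extracts reward and cost magnitudes", {
  cfg <- hawk_dove_config(p_serious = 1)
  s <- rng_stream(8)
  fight <- resolve_hawk_dove("escalate", "escalate", cfg, s)
  rc <- outcome_reinforcement(fight, 1, cfg)
  expect_equal(rc$reward, 0.5)
  expect_equal(rc$cost, 1.5)

  win <- resolve_hawk_dove("escalate", "display", cfg, s)
  expect_equal(outcome_reinforcement(win, 1, cfg),
               list(reward = 1, cost = 0))
  expect_equal(outcome_reinforcement(win, 2, cfg),
               list(reward = 0, cost = 0))

  ch <- chicken_config()
  crash <- resolve_chicken("straight", "straight", ch)
  expect_equal(outcome_reinforcement(crash, 1, ch),
               list(reward = 0, cost = 10))
  both <- resolve_chicken("swerve", "swerve", ch)
  expect_equal(outcome_reinforcement(both, 2, ch),
               list(reward = 2, cost = 0))
})

test_that("escalation is gated by reward-vs-cost activity", {
  ses <- hd_session(1, opponent = "t4t", p_serious = 0.25, n_rounds = 500)
  rec <- ses$records
  esc <- rec$action_p1 == "escalate"
  gate <- rec$p1_s_reward > rec$p1_s_cost
  expect_gt(sum(gate), 50)
  expect_gt(sum(!gate), 50)
  expect_gt(mean(esc[gate]), mean(esc[!gate]))
})
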