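#' Adaptive player specifications
#'
#' `neural_player()` requests an adaptive neural network seat (Hawk-Dove or
#' Chicken); `ac_player()` an Actor-Critic seat (Stag Hunt). Set-strategy
#' seats are requested with [strategy_spec()].
#'
#' @param params a [network_params()] / [ac_params()], or `NULL` for the
#'   game defaults.
#' @return a player specification.
#' @export
neural_player <- function(params = NULL)
  structure(list(params = params), class = "neural_player_spec")

#' @rdname neural_player
#' @export
ac_player <- function(params = ac_params())
  structure(list(params = params), class = "ac_player_spec")

#' Experiment configuration
#'
#' Describes one seeded session: the game and its configuration, the two
#' players, the session length, and an optional lesion schedule. The master
#' seed fans out into named substreams (`setup`, `p1`, `p2`, `game`) so that
#' paired arms (e.g. intact vs. lesioned) share environment randomness.
#'
#' @param game `"hawk_dove"`, `"chicken"` or `"stag_hunt"`.
#' @param players list of two player specs ([neural_player()],
#'   [ac_player()] or [strategy_spec()]).
#' @param game_config game configuration, or `NULL` for defaults.
#' @param n_rounds rounds per session (matrix games).
#' @param n_games games per session (Stag Hunt).
#' @param seed master seed.
#' @param lesion `NULL`, or `list(player =, target =, rounds = c(from, to))`
#'   clamping a neuromodulatory neuron of a neural player for a round range
#'   (`to = Inf` for the rest of the session).
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(game = c("hawk_dove", "chicken", "stag_hunt"),
                              players, game_config = NULL, n_rounds = 500,
                              n_games = 100, seed = 1, lesion = NULL) {
  game <- match.arg(game)
  if (is.null(game_config))
    game_config <- switch(game, hawk_dove = hawk_dove_config(),
                          chicken = chicken_config(),
                          stag_hunt = stag_hunt_config())
  expected <- paste0(game, "_config")
  if (!inherits(game_config, expected))
    stop(sprintf("`game_config` must be a %s", expected))
  stopifnot(length(players) == 2)
  for (p in players) {
    if (inherits(p, "ac_player_spec") && game != "stag_hunt")
      stop("Actor-Critic players only play the Stag Hunt")
    if (inherits(p, "neural_player_spec") && game == "stag_hunt")
      stop("the neural network agent plays Hawk-Dove or Chicken, not ",
           "the Stag Hunt")
    if (!inherits(p, c("ac_player_spec", "neural_player_spec",
                       "strategy_spec")))
      stop("each player must be a strategy_spec, neural_player or ac_player")
  }
  if (!is.null(lesion)) {
    stopifnot(is.list(lesion), lesion$target %in% c("cost", "reward"))
    if (is.null(lesion$rounds)) lesion$rounds <- c(1, Inf)
    if (is.null(lesion$player)) lesion$player <- 1
    if (!inherits(players[[lesion$player]], "neural_player_spec"))
      stop("lesion target player is not a neural agent")
  }
  structure(list(game = game, game_config = game_config, players = players,
                 n_rounds = n_rounds, n_games = n_games, seed = seed,
                 lesion = lesion),
            class = "experiment_config")
}

.make_player <- function(spec, game, stream) {
  if (inherits(spec, "neural_player_spec")) {
    params <- if (is.null(spec$params)) network_params(game) else spec$params
    neural_agent(game, params, stream)
  } else spec
}

.stream_names <- c("setup", "p1", "p2", "game")

#' Run one seeded session
#'
#' Plays the configured game for the configured number of rounds (or games),
#' letting adaptive agents learn online, and returns one trial record per
#' decision plus a summary. Deterministic given the master seed.
#'
#' @param config an [experiment_config()].
#' @return a list of class `game_session` with elements `records` (data
#'   frame), `summary` (see [summarize_records()]), `players` (the final
#'   player objects, including learned weights/tables) and `config`.
#' @export
run_session <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  if (config$game == "stag_hunt") .run_stag_session(config)
  else .run_matrix_session(config)
}

.lesion_sync <- function(agent, config, seat, round) {
  les <- config$lesion
  if (is.null(les) || les$player != seat || !inherits(agent, "neural_agent"))
    return(invisible(NULL))
  active <- round >= les$rounds[1] && round <= les$rounds[2]
  if (active && !agent$lesions[les$target]) lesion(agent, les$target)
  if (!active && agent$lesions[les$target]) unlesion(agent, les$target)
  invisible(NULL)
}

.run_matrix_session <- function(config) {
  st <- stream_split(config$seed, .stream_names)
  actions <- .game_actions(config$game)
  p1 <- .make_player(config$players[[1]], config$game, st$setup)
  p2 <- .make_player(config$players[[2]], config$game, st$setup)
  n <- config$n_rounds
  hist1 <- data.frame(own = character(n), opp = character(n),
                      payoff = numeric(n))
  hist2 <- hist1
  rec <- vector("list", n)
  for (r in seq_len(n)) {
    .lesion_sync(p1, config, 1, r)
    .lesion_sync(p2, config, 2, r)
    acts <- character(2)
    for (seat in 1:2) {
      pl <- if (seat == 1) p1 else p2
      hs <- if (seat == 1) hist1 else hist2
      sm <- if (seat == 1) st$p1 else st$p2
      acts[seat] <- if (inherits(pl, "neural_agent")) {
        sal <- if (r == 1) 1L
               else neural_salient_index(hs$own[r - 1], hs$opp[r - 1],
                                         pl$actions)
        neural_act(pl, sal, sm)
      } else {
        next_move(pl, hs[seq_len(r - 1), , drop = FALSE], actions, sm)
      }
    }
    out <- if (config$game == "hawk_dove")
      resolve_hawk_dove(acts[1], acts[2], config$game_config, st$game)
    else resolve_chicken(acts[1], acts[2], config$game_config)
    row <- list(game = config$game, round = r,
                action_p1 = out$action_p1, action_p2 = out$action_p2,
                payoff_p1 = out$payoff_p1, payoff_p2 = out$payoff_p2,
                injury = out$injury)
    for (seat in 1:2) {
      pl <- if (seat == 1) p1 else p2
      pre <- paste0("p", seat, "_")
      if (inherits(pl, "neural_agent")) {
        rc <- outcome_reinforcement(out, seat, config$game_config)
        neural_learn(pl, rc$reward, rc$cost)
        row[[paste0(pre, "s_cost")]] <- pl$last$s_cost
        row[[paste0(pre, "s_reward")]] <- pl$last$s_reward
        row[[paste0(pre, "nm")]] <- pl$last$nm
        row[[paste0(pre, "R")]] <- pl$last$R
      } else {
        row[[paste0(pre, "s_cost")]] <- NA_real_
        row[[paste0(pre, "s_reward")]] <- NA_real_
        row[[paste0(pre, "nm")]] <- NA_real_
        row[[paste0(pre, "R")]] <- NA_real_
      }
    }
    rec[[r]] <- row
    hist1[r, ] <- list(out$action_p1, out$action_p2, out$payoff_p1)
    hist2[r, ] <- list(out$action_p2, out$action_p1, out$payoff_p2)
  }
  records <- do.call(rbind, lapply(rec, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  structure(list(records = records, summary = summarize_records(records),
                 players = list(p1, p2), config = config),
            class = "game_session")
}

# set-strategy movement policies on the Stag Hunt board; WSLS keeps its
# target across games, switching after a no-payoff game
.stag_partner_env <- function(spec) {
  e <- new.env(parent = emptyenv())
  e$spec <- spec
  e$target <- if (!is.null(spec$first_move)) spec$first_move else "stag"
  e
}

.stag_partner_move <- function(partner, state, seat, stream) {
  spec <- partner$spec
  own <- if (seat == 1) state$p1 else state$p2
  kind <- spec$kind
  if (kind == "random")
    return(list(move = stream_sample(stream, c("up", "down", "left",
                                               "right", "stay")),
                hunt = "any"))
  target_name <- switch(kind,
    always_risky = "stag", always_safe = "hare", wsls = partner$target,
    aggressive = if (stream_runif(stream, 1) < spec$p_aggress) "hare"
                 else "stag",
    stop(sprintf("strategy '%s' cannot play the Stag Hunt", kind)))
  target <- if (target_name == "stag") state$stag
            else .nearest_hare(state, own)
  list(move = greedy_move(own, target, state$board_size, stream),
       hunt = target_name)
}

.stag_partner_update <- function(partner, own_payoff) {
  if (partner$spec$kind == "wsls" && own_payoff <= partner$spec$win_threshold)
    partner$target <- if (partner$target == "stag") "hare" else "stag"
  invisible(NULL)
}

.run_stag_session <- function(config) {
  st <- stream_split(config$seed, .stream_names)
  seats <- vector("list", 2)
  for (seat in 1:2) {
    sp <- config$players[[seat]]
    seats[[seat]] <- if (inherits(sp, "ac_player_spec"))
      ac_agent(config$game_config, sp$params, player = seat)
    else .stag_partner_env(sp)
  }
  rec <- list()
  for (g in seq_len(config$n_games)) {
    state <- stag_hunt_setup(config$game_config, st$setup)
    path <- c(0, 0)
    repeat {
      moves <- character(2)
      hunts <- character(2)
      internals <- vector("list", 2)
      for (seat in 1:2) {
        sm <- if (seat == 1) st$p1 else st$p2
        if (inherits(seats[[seat]], "ac_agent")) {
          moves[seat] <- ac_act(seats[[seat]], state, sm)
          internals[[seat]] <- seats[[seat]]$prev
          hunts[seat] <- internals[[seat]]$choice
        } else {
          mv <- .stag_partner_move(seats[[seat]], state, seat, sm)
          moves[seat] <- mv$move
          hunts[seat] <- mv$hunt
        }
      }
      before <- list(state$p1, state$p2)
      keys_before <- c(stag_features(state, 1), stag_features(state, 2))
      state <- step_stag_hunt(state, moves[1], moves[2], config$game_config,
                              hunts[1], hunts[2])
      path <- path + c(.manhattan(before[[1]], state$p1),
                       .manhattan(before[[2]], state$p2))
      row <- list(game = g, turn = state$turn,
                  state_p1 = keys_before[1], state_p2 = keys_before[2],
                  move_p1 = moves[1], move_p2 = moves[2],
                  p1_row = state$p1[1], p1_col = state$p1[2],
                  p2_row = state$p2[1], p2_col = state$p2[2],
                  terminal = state$terminal,
                  capture = if (state$terminal) state$capture
                            else NA_character_,
                  payoff_p1 = if (state$terminal) state$outcome$payoff_p1
                              else NA_real_,
                  payoff_p2 = if (state$terminal) state$outcome$payoff_p2
                              else NA_real_)
      for (seat in 1:2) {
        pre <- paste0("p", seat, "_")
        isac <- inherits(seats[[seat]], "ac_agent")
        row[[paste0(pre, "P_stag")]] <-
          if (isac) unname(internals[[seat]]$P["stag"]) else NA_real_
        row[[paste0(pre, "choice")]] <-
          if (isac) internals[[seat]]$choice else NA_character_
        if (isac) {
          upd <- ac_learn(seats[[seat]], if (state$terminal) state else {
            s2 <- state; s2$outcome <- game_outcome(moves[1], moves[2], 0, 0)
            s2
          })
          row[[paste0(pre, "delta")]] <- upd$delta_total
        } else row[[paste0(pre, "delta")]] <- NA_real_
      }
      row$path_p1 <- path[1]
      row$path_p2 <- path[2]
      rec[[length(rec) + 1]] <- row
      if (state$terminal) break
    }
    for (seat in 1:2)
      if (!inherits(seats[[seat]], "ac_agent"))
        .stag_partner_update(seats[[seat]],
                             if (seat == 1) state$outcome$payoff_p1
                             else state$outcome$payoff_p2)
  }
  records <- do.call(rbind, lapply(rec, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  records$game_id <- "stag_hunt"
  structure(list(records = records, summary = summarize_records(records),
                 players = seats, config = config),
            class = "game_session")
}

#' @export
print.game_session <- function(x, ...) {
  cat(sprintf("<game_session: %s, seed %s>\n", x$config$game,
              x$config$seed))
  s <- x$summary
  for (nm in names(s))
    if (is.numeric(s[[nm]]) && length(s[[nm]]) == 1)
      cat(sprintf("  %s: %.4g\n", nm, s[[nm]]))
  invisible(x)
}

#' Summarize trial records
#'
#' A pure function of the record table, so a summary can be recomputed
#' exactly from a persisted log. Matrix-game records yield escalation and
#' cooperation proportions, mean payoffs and WSLS/T4T consistency scores;
#' Stag Hunt records yield capture counts, the stag-to-hare capture ratio,
#' mean turns and path lengths.
#'
#' @param records a record data frame from [run_session()] (or reloaded via
#'   [read_trial_log()]).
#' @return a named list.
#' @export
summarize_records <- function(records) {
  if (is.null(records) || nrow(records) == 0) stop("no records to summarize")
  if ("turn" %in% names(records)) return(.summarize_stag(records))
  game <- records$game[1]
  actions <- .game_actions(game)
  risky <- actions[["risky"]]
  safe <- actions[["safe"]]
  esc1 <- mean(records$action_p1 == risky)
  esc2 <- mean(records$action_p2 == risky)
  consistency <- function(own, opp, payoff) {
    h <- data.frame(own = own, opp = opp, payoff = payoff)
    if (nrow(h) < 2) c(wsls = NA_real_, t4t = NA_real_)
    else classify_strategy(h, actions)
  }
  c1 <- consistency(records$action_p1, records$action_p2, records$payoff_p1)
  c2 <- consistency(records$action_p2, records$action_p1, records$payoff_p2)
  list(game = game, n_rounds = nrow(records),
       escalation_p1 = esc1, escalation_p2 = esc2,
       escalation_prop = mean(c(esc1, esc2)),
       cooperation_prop = mean(records$action_p1 == safe &
                                 records$action_p2 == safe),
       mean_payoff_p1 = mean(records$payoff_p1),
       mean_payoff_p2 = mean(records$payoff_p2),
       consistency_p1 = as.list(c1), consistency_p2 = as.list(c2),
       joint_counts = as.list(table(paste(records$action_p1,
                                          records$action_p2))))
}

.summarize_stag <- function(records) {
  term <- records[records$terminal, , drop = FALSE]
  caps <- table(factor(term$capture, c("stag", "hare", "timeout")))
  list(game = "stag_hunt", n_games = nrow(term),
       stag_captures = unname(caps["stag"]),
       hare_captures = unname(caps["hare"]),
       timeouts = unname(caps["timeout"]),
       stag_hare_ratio = unname(caps["stag"]) / max(unname(caps["hare"]), 1),
       mean_payoff_p1 = mean(term$payoff_p1),
       mean_payoff_p2 = mean(term$payoff_p2),
       mean_turns = mean(term$turn),
       mean_path_p1 = mean(term$path_p1),
       mean_path_p2 = mean(term$path_p2))
}

#' Final stag policy at the session's game-start states
#'
#' Evaluates the trained Actor's SoftMax probability of committing to the
#' stag at the feature states in which the session's games began (the
#' states where the policy was actually exercised), averaged over games.
#'
#' @param session a Stag Hunt [run_session()] result with an Actor-Critic
#'   player.
#' @param player seat of the Actor-Critic agent.
#' @return mean probability of choosing stag at the start states.
#' @export
start_state_policy <- function(session, player = 1) {
  agent <- session$players[[player]]
  if (!inherits(agent, "ac_agent"))
    stop("player ", player, " is not an Actor-Critic agent")
  rec <- session$records
  keys <- rec[[paste0("state_p", player)]][rec$turn == 1]
  mean(vapply(keys, function(k)
    softmax_policy(agent$actor[k, ])[["stag"]], numeric(1)))
}

#' Paired lesion study
#'
#' Runs the configured session twice with identical master seed and
#' opponents: once intact and once with the named neuromodulatory neuron of
#' the (first) neural player clamped to zero throughout, and reports the
#' escalation proportions of both arms and their difference.
#'
#' @param config an [experiment_config()] with a neural player in seat 1.
#' @param target `"cost"` or `"reward"`.
#' @return a list of class `lesion_study` with the two sessions and an
#'   `escalation` vector (`intact`, `lesioned`, `difference`, the focal
#'   player's escalation proportions).
#' @export
run_lesion_study <- function(config, target = c("cost", "reward")) {
  target <- match.arg(target)
  if (!inherits(config$players[[1]], "neural_player_spec"))
    stop("lesion studies need a neural agent in seat 1")
  cfg_intact <- config
  cfg_intact$lesion <- NULL
  cfg_les <- config
  cfg_les$lesion <- list(player = 1, target = target, rounds = c(1, Inf))
  intact <- run_session(cfg_intact)
  lesioned <- run_session(cfg_les)
  esc <- c(intact = intact$summary$escalation_p1,
           lesioned = lesioned$summary$escalation_p1)
  structure(list(intact = intact, lesioned = lesioned, target = target,
                 escalation = c(esc, difference =
                                  unname(esc["lesioned"] - esc["intact"]))),
            class = "lesion_study")
}

#' @export
print.lesion_study <- function(x, ...) {
  cat(sprintf("<lesion_study: %s lesion, %s>\n", x$target,
              x$intact$config$game))
  cat(sprintf("  escalation intact %.3f, lesioned %.3f (difference %+.3f)\n",
              x$escalation["intact"], x$escalation["lesioned"],
              x$escalation["difference"]))
  invisible(x)
}

#' Trial logs as JSON lines
#'
#' One JSON object per record line; numbers are written at full precision so
#' a summary recomputed from the persisted log equals the live one exactly.
#'
#' @param records record data frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records)))
    writeLines(jsonlite::toJSON(as.list(records[i, , drop = FALSE]),
                                auto_unbox = TRUE, digits = NA,
                                na = "null"), con)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    x[vapply(x, is.null, logical(1))] <- NA
    as.data.frame(x, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read an experiment configuration from a YAML file
#'
#' Flat key-value format with one section per component: `game`, `seed`,
#' `rounds`/`games`, a section named after the game carrying its
#' configuration fields, a `players` list (each entry `kind:` plus strategy
#' fields, or `kind: neural` / `kind: actor_critic`), and an optional
#' `lesion` section. Unknown keys are an error; omitted fields take their
#' defaults.
#'
#' @param path YAML file path.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("game", "seed", "rounds", "games", "players",
             "hawk_dove", "chicken", "stag_hunt", "lesion")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  game <- y$game %||% "hawk_dove"
  gc_args <- y[[game]] %||% list()
  maker <- switch(game, hawk_dove = hawk_dove_config,
                  chicken = chicken_config, stag_hunt = stag_hunt_config)
  bad <- setdiff(names(gc_args), names(formals(maker)))
  if (length(bad))
    stop(sprintf("unknown %s keys: %s", game, paste(bad, collapse = ", ")))
  game_config <- do.call(maker, gc_args)
  players <- lapply(y$players %||% list(list(kind = "neural"),
                                        list(kind = "t4t")),
                    .player_from_config)
  experiment_config(game, players, game_config,
                    n_rounds = y$rounds %||% 500,
                    n_games = y$games %||% 100,
                    seed = y$seed %||% 1, lesion = y$lesion)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.player_from_config <- function(p) {
  kind <- p$kind %||% stop("each player needs a `kind`")
  if (kind == "neural") return(neural_player())
  if (kind == "actor_critic") return(ac_player())
  args <- p[setdiff(names(p), "kind")]
  bad <- setdiff(names(args), c("p_aggress", "first_move", "win_threshold"))
  if (length(bad))
    stop("unknown player keys: ", paste(bad, collapse = ", "))
  do.call(strategy_spec, c(list(kind = kind), args))
}
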