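#' Hawk-Dove game configuration
#'
#' Two players contest a territory of interest (TOI) worth `resource_value`
#' points, each choosing to `escalate` (aggressive) or `display`
#' (cooperative). If both escalate they fight and are injured; environment
#' "harshness" is the probability `p_serious` that the injury is serious
#' rather than mild. The spatial approach phase to the TOI is abstracted
#' away; each round is the simultaneous binary choice. `grid_size` is kept
#' for board display only.
#'
#' @param resource_value value of the contested territory (> 0).
#' @param mild_injury_cost cost of a mild injury (>= 0).
#' @param serious_injury_cost cost of a serious injury (>= mild).
#' @param p_serious probability a fight injury is serious, in \[0, 1\].
#'   0.25 is a benign environment, 0.75 a harsh one.
#' @param grid_size board side length (display only).
#' @return an object of class `hawk_dove_config`.
#' @export
hawk_dove_config <- function(resource_value = 1, mild_injury_cost = 0.75,
                             serious_injury_cost = 1.5, p_serious = 0.25,
                             grid_size = 5) {
  if (!is.numeric(resource_value) || resource_value <= 0)
    stop("`resource_value` must be > 0")
  if (mild_injury_cost < 0)
    stop("`mild_injury_cost` must be >= 0")
  if (serious_injury_cost < mild_injury_cost)
    stop("`serious_injury_cost` must be >= `mild_injury_cost`")
  if (p_serious < 0 || p_serious > 1)
    stop("`p_serious` must be in [0, 1]")
  structure(list(resource_value = resource_value,
                 mild_injury_cost = mild_injury_cost,
                 serious_injury_cost = serious_injury_cost,
                 p_serious = p_serious, grid_size = grid_size),
            class = "hawk_dove_config")
}

#' Chicken game configuration
#'
#' Two cars head toward each other on a single-lane track; each player
#' swerves or stays straight. The lone swerver relinquishes the lane and
#' scores 0 while the other takes `max_payoff`; mutual swerving pays each
#' the `min_payoff`; mutual straight is a head-on collision, the worst
#' outcome.
#'
#' @param max_payoff payoff to the player who stays straight alone.
#' @param min_payoff payoff to each player when both swerve
#'   (0 <= min < max).
#' @param collision_payoff payoff to each on collision (< 0 by convention,
#'   must be below the swerve-alone payoff of 0).
#' @return an object of class `chicken_config`.
#' @export
chicken_config <- function(max_payoff = 6, min_payoff = 2,
                           collision_payoff = -10) {
  if (collision_payoff >= 0)
    stop("`collision_payoff` must be below the swerve-alone payoff of 0")
  if (min_payoff < 0 || min_payoff >= max_payoff)
    stop("need 0 <= min_payoff < max_payoff")
  structure(list(max_payoff = max_payoff, min_payoff = min_payoff,
                 swerve_alone_payoff = 0, collision_payoff = collision_payoff),
            class = "chicken_config")
}

#' Spatial Stag Hunt configuration
#'
#' Played on a `board_size` x `board_size` grid carrying two players, one
#' stag and `n_hares` hares. Players move simultaneously (4-connected, or
#' stay). A player orthogonally adjacent to a hare captures it alone for
#' `hare_payoff`; the stag is captured only when both players are adjacent
#' to it simultaneously, paying each `stag_payoff`. Games end on a capture
#' or at `timeout` turns with no payoff.
#'
#' @param board_size board side length.
#' @param stag_payoff payoff to each player on a joint stag capture.
#' @param hare_payoff payoff to a lone hare captor (< stag_payoff).
#' @param n_hares number of hare tokens.
#' @param timeout maximum number of turns.
#' @return an object of class `stag_hunt_config`.
#' @export
stag_hunt_config <- function(board_size = 5, stag_payoff = 5, hare_payoff = 1,
                             n_hares = 2, timeout = 50) {
  if (stag_payoff <= hare_payoff || hare_payoff <= 0)
    stop("need stag_payoff > hare_payoff > 0")
  if (timeout <= 0) stop("`timeout` must be > 0")
  if (n_hares < 1) stop("need at least one hare")
  if (board_size^2 < 3 + n_hares)
    stop("board too small for the requested tokens")
  structure(list(board_size = board_size, stag_payoff = stag_payoff,
                 hare_payoff = hare_payoff, n_hares = n_hares,
                 timeout = timeout),
            class = "stag_hunt_config")
}

game_outcome <- function(action_p1, action_p2, payoff_p1, payoff_p2,
                         injury = "none") {
  structure(list(action_p1 = action_p1, action_p2 = action_p2,
                 payoff_p1 = payoff_p1, payoff_p2 = payoff_p2,
                 injury = injury),
            class = "game_outcome")
}

.check_action <- function(a, valid, game) {
  if (!is.character(a) || length(a) != 1L || !(a %in% valid))
    stop(sprintf("invalid %s action: '%s' (must be one of %s)",
                 game, as.character(a)[1], paste(valid, collapse = ", ")))
  a
}

#' Resolve one Hawk-Dove round
#'
#' Mutual display splits the resource; a lone escalator takes it all; mutual
#' escalation is a fight in which each player receives half the resource
#' minus an injury cost, drawn serious with probability `p_serious` (one
#' draw per fight; both combatants share the severity).
#'
#' @param a1,a2 `"escalate"` or `"display"`.
#' @param cfg a [hawk_dove_config()].
#' @param stream an [rng_stream()] consumed only on a fight.
#' @return a `game_outcome` with actions, payoffs and injury severity
#'   (`"none"`, `"mild"` or `"serious"`).
#' @export
resolve_hawk_dove <- function(a1, a2, cfg, stream) {
  stopifnot(inherits(cfg, "hawk_dove_config"))
  .check_action(a1, c("escalate", "display"), "Hawk-Dove")
  .check_action(a2, c("escalate", "display"), "Hawk-Dove")
  v <- cfg$resource_value
  if (a1 == "display" && a2 == "display")
    return(game_outcome(a1, a2, v / 2, v / 2))
  if (a1 == "escalate" && a2 == "display")
    return(game_outcome(a1, a2, v, 0))
  if (a1 == "display" && a2 == "escalate")
    return(game_outcome(a1, a2, 0, v))
  serious <- stream_runif(stream, 1) < cfg$p_serious
  injury <- if (serious) "serious" else "mild"
  cost <- if (serious) cfg$serious_injury_cost else cfg$mild_injury_cost
  game_outcome(a1, a2, v / 2 - cost, v / 2 - cost, injury)
}

#' Resolve one Chicken round
#'
#' @param a1,a2 `"swerve"` or `"straight"`.
#' @param cfg a [chicken_config()].
#' @return a `game_outcome`; deterministic.
#' @export
resolve_chicken <- function(a1, a2, cfg) {
  stopifnot(inherits(cfg, "chicken_config"))
  .check_action(a1, c("swerve", "straight"), "Chicken")
  .check_action(a2, c("swerve", "straight"), "Chicken")
  if (a1 == "swerve" && a2 == "swerve")
    return(game_outcome(a1, a2, cfg$min_payoff, cfg$min_payoff))
  if (a1 == "swerve")
    return(game_outcome(a1, a2, cfg$swerve_alone_payoff, cfg$max_payoff))
  if (a2 == "swerve")
    return(game_outcome(a1, a2, cfg$max_payoff, cfg$swerve_alone_payoff))
  game_outcome(a1, a2, cfg$collision_payoff, cfg$collision_payoff)
}

#' Random Stag Hunt setup
#'
#' Places both players, the stag and the hares uniformly at random on
#' distinct cells. Coordinates are 0-based (row, column).
#'
#' @param cfg a [stag_hunt_config()].
#' @param stream an [rng_stream()].
#' @return an object of class `stag_hunt_state`.
#' @export
stag_hunt_setup <- function(cfg, stream) {
  stopifnot(inherits(cfg, "stag_hunt_config"))
  n_tok <- 3 + cfg$n_hares
  if (cfg$board_size^2 < n_tok)
    stop("board too small for the requested tokens")
  cells <- stream_sample(stream, cfg$board_size^2, n_tok) - 1L
  coord <- cbind(cells %/% cfg$board_size, cells %% cfg$board_size)
  structure(list(
    p1 = coord[1, ], p2 = coord[2, ], stag = coord[3, ],
    hares = coord[4:n_tok, , drop = FALSE],
    turn = 0L, terminal = FALSE, capture = NA_character_,
    outcome = NULL, board_size = cfg$board_size),
    class = "stag_hunt_state")
}

.clamp_move <- function(pos, move, board_size) {
  new <- pos + switch(move,
    up = c(-1L, 0L), down = c(1L, 0L), left = c(0L, -1L),
    right = c(0L, 1L), stay = c(0L, 0L),
    stop(sprintf("invalid Stag Hunt move: '%s'", move)))
  if (any(new < 0) || any(new >= board_size)) pos else new
}

.adjacent <- function(a, b) sum(abs(a - b)) <= 1L

#' Advance the Stag Hunt one turn
#'
#' Both players move simultaneously (off-board moves leave the player in
#' place), then captures are checked. Adjacency (being on or orthogonally
#' next to a token) is the catch condition, and a player catches what it is
#' currently committed to hunting: a player adjacent to a hare while
#' hunting hare catches it alone (simultaneous catches by both players each
#' pay); the stag is caught only when both players are adjacent to it and
#' committed to it, paying each the stag payoff. Hare captures are checked
#' before stag captures, then timeout. The default commitment `"any"`
#' captures whatever the player is adjacent to (pure proximity rule).
#'
#' @param state a `stag_hunt_state`.
#' @param move_p1,move_p2 one of `"up"`, `"down"`, `"left"`, `"right"`,
#'   `"stay"`.
#' @param cfg the [stag_hunt_config()].
#' @param hunt_p1,hunt_p2 each player's current hunt commitment: `"stag"`,
#'   `"hare"` or `"any"`.
#' @return the updated state; if the game ended, `state$terminal` is `TRUE`,
#'   `state$capture` is one of `"stag"`, `"hare"`, `"timeout"` and
#'   `state$outcome` holds the `game_outcome`.
#' @export
step_stag_hunt <- function(state, move_p1, move_p2, cfg,
                           hunt_p1 = "any", hunt_p2 = "any") {
  stopifnot(inherits(state, "stag_hunt_state"),
            inherits(cfg, "stag_hunt_config"),
            hunt_p1 %in% c("stag", "hare", "any"),
            hunt_p2 %in% c("stag", "hare", "any"))
  if (state$terminal) stop("cannot step a terminal Stag Hunt state")
  state$p1 <- .clamp_move(state$p1, move_p1, cfg$board_size)
  state$p2 <- .clamp_move(state$p2, move_p2, cfg$board_size)
  state$turn <- state$turn + 1L

  hare1 <- hunt_p1 %in% c("hare", "any") &&
    any(apply(state$hares, 1, .adjacent, a = state$p1))
  hare2 <- hunt_p2 %in% c("hare", "any") &&
    any(apply(state$hares, 1, .adjacent, a = state$p2))
  stag_committed <- hunt_p1 %in% c("stag", "any") &&
    hunt_p2 %in% c("stag", "any")
  if (hare1 || hare2) {
    state$terminal <- TRUE
    state$capture <- "hare"
    state$outcome <- game_outcome(move_p1, move_p2,
                                  if (hare1) cfg$hare_payoff else 0,
                                  if (hare2) cfg$hare_payoff else 0)
  } else if (stag_committed && .adjacent(state$p1, state$stag) &&
             .adjacent(state$p2, state$stag)) {
    state$terminal <- TRUE
    state$capture <- "stag"
    state$outcome <- game_outcome(move_p1, move_p2,
                                  cfg$stag_payoff, cfg$stag_payoff)
  } else if (state$turn >= cfg$timeout) {
    state$terminal <- TRUE
    state$capture <- "timeout"
    state$outcome <- game_outcome(move_p1, move_p2, 0, 0)
  }
  state
}

#' @export
print.stag_hunt_state <- function(x, ...) {
  b <- matrix(".", x$board_size, x$board_size)
  for (i in seq_len(nrow(x$hares)))
    b[x$hares[i, 1] + 1, x$hares[i, 2] + 1] <- "h"
  b[x$stag[1] + 1, x$stag[2] + 1] <- "S"
  b[x$p1[1] + 1, x$p1[2] + 1] <- "1"
  b[x$p2[1] + 1, x$p2[2] + 1] <- "2"
  cat(sprintf("Stag Hunt, turn %d%s\n", x$turn,
              if (x$terminal) sprintf(" [terminal: %s]", x$capture) else ""))
  for (r in seq_len(nrow(b))) cat(paste(b[r, ], collapse = " "), "\n")
  invisible(x)
}
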