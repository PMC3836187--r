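#' Set-strategy opponent specification
#'
#' Fixed-policy agents used as controls. `always_risky`/`always_safe` play
#' the game's aggressive or cooperative action unconditionally (escalate or
#' display in Hawk-Dove, straight or swerve in Chicken, hare or stag target
#' in Stag Hunt); `random` picks uniformly; `wsls` repeats its last action
#' after a win (payoff above `win_threshold`) and switches after a loss;
#' `t4t` copies the opponent's last action; `aggressive` plays the risky
#' action with probability `p_aggress` and the safe one otherwise.
#'
#' @param kind strategy name.
#' @param p_aggress probability of the aggressive action for
#'   `kind = "aggressive"`.
#' @param first_move action played on round 1 when the rule needs history;
#'   `NULL` means the conventional cooperative opening for `wsls`/`t4t`.
#' @param win_threshold a WSLS round counts as a win when its payoff is
#'   strictly above this (default 0, the minimum non-negative outcome).
#' @return an object of class `strategy_spec`.
#' @export
strategy_spec <- function(kind = c("always_safe", "always_risky", "random",
                                   "wsls", "t4t", "aggressive",
                                   "always_display", "always_escalate",
                                   "always_swerve", "always_straight",
                                   "always_stag", "always_hare"),
                          p_aggress = 1, first_move = NULL,
                          win_threshold = 0) {
  kind <- match.arg(kind)
  # game-specific aliases for the fixed strategies
  kind <- switch(kind,
                 always_display = , always_swerve = , always_hare =
                   "always_safe",
                 always_escalate = , always_straight = , always_stag =
                   "always_risky",
                 kind)
  if (p_aggress < 0 || p_aggress > 1) stop("`p_aggress` must be in [0, 1]")
  structure(list(kind = kind, p_aggress = p_aggress,
                 first_move = first_move, win_threshold = win_threshold),
            class = "strategy_spec")
}

#' Next move of a set-strategy agent
#'
#' @param spec a [strategy_spec()].
#' @param history data frame with columns `own`, `opp`, `payoff` (one row
#'   per completed round, oldest first); zero rows on the first move.
#' @param actions named character vector with elements `risky` and `safe`
#'   giving the game's action alphabet.
#' @param stream an [rng_stream()] (consumed by `random` and `aggressive`).
#' @return an action label.
#' @export
next_move <- function(spec, history, actions, stream) {
  stopifnot(inherits(spec, "strategy_spec"))
  risky <- actions[["risky"]]
  safe <- actions[["safe"]]
  n <- if (is.null(history)) 0L else nrow(history)
  first <- if (!is.null(spec$first_move)) spec$first_move else safe
  switch(spec$kind,
    always_risky = risky,
    always_safe = safe,
    random = stream_sample(stream, c(risky, safe)),
    aggressive = if (stream_runif(stream, 1) < spec$p_aggress) risky
                 else safe,
    wsls = if (n == 0) first
           else .wsls_prediction(history$own[n], history$payoff[n],
                                 spec$win_threshold, risky, safe),
    t4t = if (n == 0) first else history$opp[n],
    stop(sprintf("unknown strategy kind '%s'", spec$kind)))
}

.wsls_prediction <- function(last_own, last_payoff, win_threshold,
                             risky, safe) {
  if (last_payoff > win_threshold) last_own
  else if (last_own == risky) safe else risky
}

#' Strategy-consistency classification
#'
#' Scores how consistent a player's realized move sequence is with
#' Win-Stay-Lose-Shift and with Tit-for-Tat: for each template, the fraction
#' of moves from round 2 onward that match the template's prediction given
#' the realized history. Depends only on win/loss labels (payoff relative to
#' `win_threshold`), so it is invariant to payoff scaling that preserves
#' sign.
#'
#' @param history data frame with columns `own`, `opp`, `payoff`.
#' @param actions named action alphabet (`risky`, `safe`).
#' @param win_threshold payoff above which a WSLS round is a win.
#' @return named numeric vector `c(wsls = ..., t4t = ...)`, both in
#'   \[0, 1\].
#' @export
classify_strategy <- function(history, actions, win_threshold = 0) {
  if (is.null(history) || nrow(history) < 2)
    stop("need at least 2 rounds of history to classify a strategy")
  n <- nrow(history)
  idx <- 2:n
  wsls_pred <- vapply(idx, function(t)
    .wsls_prediction(history$own[t - 1], history$payoff[t - 1],
                     win_threshold, actions[["risky"]], actions[["safe"]]),
    character(1))
  t4t_pred <- history$opp[idx - 1]
  c(wsls = mean(history$own[idx] == wsls_pred),
    t4t = mean(history$own[idx] == t4t_pred))
}
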