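#' Rock-Paper-Scissors moves
#'
#' Moves are represented throughout the package as the single characters
#' `"R"`, `"P"` and `"S"`. `rps_moves()` returns the three moves in their
#' canonical order; `counter_move()` returns the move that beats its input
#' (the move an AI plays once it has predicted the opponent).
#'
#' Dominance is the usual 3-cycle: Rock beats Scissors, Scissors beats Paper,
#' Paper beats Rock; no move beats itself.
#'
#' @param move Character vector of moves (`"R"`, `"P"` or `"S"`).
#' @return `rps_moves()`: the character vector `c("R", "P", "S")`.
#'   `counter_move()`: a character vector of the same length as `move`.
#' @examples
#' counter_move("R") # "P"
#' counter_move(c("R", "P", "S"))
#' @export
rps_moves <- function() c("R", "P", "S")

#' @rdname rps_moves
#' @export
counter_move <- function(move) {
  check_moves(move)
  unname(c(R = "P", P = "S", S = "R")[move])
}

# The move beaten by `move` (counter_move run backwards).
beaten_by <- function(move) {
  unname(c(R = "S", P = "R", S = "P")[move])
}

check_moves <- function(move, arg = "move") {
  if (length(move) == 0) return(invisible(move))
  bad <- !(move %in% c("R", "P", "S"))
  if (any(bad)) {
    rlang::abort(sprintf(
      "`%s` must contain only \"R\", \"P\" or \"S\"; found %s.",
      arg, paste0('"', unique(move[bad]), '"', collapse = ", ")
    ))
  }
  invisible(move)
}

#' Resolve a round and score it
#'
#' `round_outcome()` resolves one simultaneous round from the AI's
#' perspective. `competitive_score()` maps an outcome to the match scoring
#' convention win +1 / draw 0 / loss -1, so a match total equals wins minus
#' losses. `virtual_points()` maps an outcome *from the player's perspective*
#' to the experimental currency: 2 points for a win, 1 for a draw, 0 for a
#' loss.
#'
#' @param ai,opponent Character vectors of moves.
#' @param outcome Character vector of outcomes (`"win"`, `"draw"`, `"loss"`).
#' @return `round_outcome()`: a character vector of outcomes.
#'   `competitive_score()`: an integer vector in -1/0/+1.
#'   `virtual_points()`: an integer vector in 0/1/2.
#' @examples
#' round_outcome("R", "S") # "win"
#' competitive_score(round_outcome(c("R", "R", "S"), c("S", "R", "R")))
#' virtual_points("draw") # 1
#' @export
round_outcome <- function(ai, opponent) {
  check_moves(ai, "ai")
  check_moves(opponent, "opponent")
  out <- rep("draw", length(ai))
  out[opponent == beaten_by(ai)] <- "win"
  out[ai == beaten_by(opponent)] <- "loss"
  out
}

check_outcomes <- function(outcome) {
  bad <- !(outcome %in% c("win", "draw", "loss"))
  if (any(bad)) {
    rlang::abort(sprintf(
      "`outcome` must be \"win\", \"draw\" or \"loss\"; found %s.",
      paste0('"', unique(outcome[bad]), '"', collapse = ", ")
    ))
  }
  invisible(outcome)
}

#' @rdname round_outcome
#' @export
competitive_score <- function(outcome) {
  check_outcomes(outcome)
  unname(c(win = 1L, draw = 0L, loss = -1L)[outcome])
}

#' @rdname round_outcome
#' @export
virtual_points <- function(outcome) {
  check_outcomes(outcome)
  unname(c(win = 2L, draw = 1L, loss = 0L)[outcome])
}

#' Experimental payoff parameters and cash reward
#'
#' The experimental sessions pay the human player in virtual points (2 per
#' win, 1 per draw, 0 per loss) converted to cash as `y = x * r + show_up_fee`
#' where `r` is the exchange rate. With payoff parameter `a` (incentive for
#' winning divided by incentive for drawing; `a = 2` gives the neutral game)
#' the rate is set to `r = 0.45 / (1 + a)`, so that a player at the
#' mixed-strategy Nash equilibrium — expected payoff `(1 + a) / 3` virtual
#' points per round — earns 50 RMB over a 300-round session.
#'
#' @param a Payoff parameter, a positive number. Default 2 (neutral game).
#' @param rounds Number of rounds in a session. Default 300.
#' @param show_up_fee Participation fee added to every reward. Default 5 RMB.
#' @param r Exchange rate in RMB per virtual point. Defaults to
#'   `exchange_rate(a)`; pass a value to override the derivation.
#' @param x Total virtual points earned (non-negative).
#' @param params A list from `payoff_params()`.
#' @return `payoff_params()`: a list with elements `a`, `rounds`,
#'   `show_up_fee`, `r`. `exchange_rate()`: a number. `reward()`: the cash
#'   reward in the same currency as `show_up_fee`.
#' @examples
#' exchange_rate(2) # 0.15
#' reward(300, payoff_params(a = 2)) # 50: the Nash-expectation session
#' @export
payoff_params <- function(a = 2, rounds = 300L, show_up_fee = 5, r = NULL) {
  stopifnot(is.numeric(a), length(a) == 1, a > 0)
  stopifnot(is.numeric(rounds), length(rounds) == 1, rounds >= 0)
  if (is.null(r)) r <- exchange_rate(a)
  list(a = a, rounds = as.integer(rounds), show_up_fee = show_up_fee, r = r)
}

#' @rdname payoff_params
#' @export
exchange_rate <- function(a = 2) {
  stopifnot(is.numeric(a), length(a) == 1, a > 0)
  0.45 / (1 + a)
}

#' @rdname payoff_params
#' @export
reward <- function(x, params = payoff_params()) {
  stopifnot(is.numeric(x))
  if (any(x < 0)) rlang::abort("`x` (total virtual points) must be non-negative.")
  x * params$r + params$show_up_fee
}

#' Summarise a match from its win/draw/loss totals
#'
#' Applies the match arithmetic to printed totals: competitive score
#' (wins - losses), win/loss ratio, the player's virtual points
#' (2 per AI loss + 1 per draw, since AI losses are player wins) and the
#' resulting cash reward.
#'
#' @param ai_wins,draws,ai_losses Non-negative round counts, from the AI's
#'   perspective.
#' @param params Payoff parameters, see [payoff_params()].
#' @return A one-row tibble with columns `rounds`, `ai_wins`, `draws`,
#'   `ai_losses`, `ai_score`, `win_loss_ratio`, `player_virtual_points`,
#'   `player_reward`.
#' @examples
#' match_totals_summary(198, 55, 47) # score 151
#' @export
match_totals_summary <- function(ai_wins, draws, ai_losses,
                                 params = payoff_params()) {
  stopifnot(ai_wins >= 0, draws >= 0, ai_losses >= 0)
  x <- 2L * ai_losses + draws
  tibble::tibble(
    rounds = ai_wins + draws + ai_losses,
    ai_wins = as.integer(ai_wins),
    draws = as.integer(draws),
    ai_losses = as.integer(ai_losses),
    ai_score = as.integer(ai_wins - ai_losses),
    win_loss_ratio = ifelse(ai_losses > 0, ai_wins / ai_losses, Inf),
    player_virtual_points = as.integer(x),
    player_reward = reward(x, params)
  )
}
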