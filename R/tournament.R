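#' Play a full match between a multi-AI ensemble and a scripted opponent
#'
#' Alternates [ensemble_move()], [next_opponent_move()] and
#' [ensemble_update()] for the given number of rounds. The whole match is
#' reproducible from `(orders, focus, rounds, master_seed, opponent)`:
#' member streams derive from the master seed and the member order, the
#' opponent stream from the master seed (or from the instance's own seed if
#' an already-seeded [opponent_instance()] is supplied — the instance is
#' re-seeded from scratch, so the caller's object is never mutated).
#'
#' @param opponent A `rps_strategy` template or a seeded `rps_opponent`.
#' @param orders,focus,master_seed,sample_prediction See [multi_ai()].
#' @param rounds Number of rounds to play (>= 0).
#' @param params Payoff parameters, see [payoff_params()]; its `a` sets the
#'   virtual-point-to-cash conversion of the summary.
#' @return An object of class `rps_match`: a list with `history` (one-row-
#'   per-round tibble, see [ensemble_update()], plus `cum_score`), `summary`
#'   (named list: `rounds`, `ai_wins`, `draws`, `ai_losses`, `ai_score`,
#'   `player_virtual_points`, `player_reward`, `preference_counts`,
#'   `trajectory`) and `config`.
#' @examples
#' m <- run_match(opp_cycle("RPS"), orders = 1:5, focus = 5,
#'                rounds = 50, master_seed = 1)
#' glance(m)
#' @export
run_match <- function(opponent, orders = 1:5, focus = 5, rounds = 300,
                      master_seed = 0, params = payoff_params(),
                      sample_prediction = FALSE) {
  stopifnot(rounds >= 0)
  rounds <- as.integer(rounds)
  if (inherits(opponent, "rps_opponent")) {
    inst <- opponent_instance(
      new_strategy(opponent$name, opponent$params, opponent$fn,
                   type = opponent$type),
      opponent$seed
    )
  } else if (inherits(opponent, "rps_strategy")) {
    inst <- opponent_instance(opponent, opponent_seed(master_seed))
  } else {
    rlang::abort("`opponent` must be a rps_strategy or rps_opponent.")
  }
  ens <- multi_ai(orders, focus, master_seed, sample_prediction)
  ai_moves <- character(rounds)
  human_moves <- character(rounds)
  dominant <- integer(rounds)
  for (t in seq_len(rounds)) {
    mv <- ensemble_move(ens)
    past <- seq_len(t - 1L)
    opp_mv <- inst$fn(inst, human_moves[past], ai_moves[past])
    check_moves(opp_mv, "opponent move")
    ensemble_update(ens, opp_mv, record = FALSE)
    ai_moves[t] <- mv$ai_move
    human_moves[t] <- opp_mv
    dominant[t] <- mv$dominant_order
  }
  history <- assemble_history(ens, ai_moves, human_moves, dominant, rounds)
  config <- list(
    orders = ens$orders, focus = ens$focus, rounds = rounds,
    a = params$a, master_seed = as.integer(master_seed),
    opponent = inst$name, opponent_seed = inst$seed,
    sample_prediction = sample_prediction
  )
  new_match(history, config, params)
}

assemble_history <- function(ens, ai_moves, human_moves, dominant, rounds) {
  outcome <- round_outcome(ai_moves, human_moves)
  history <- tibble::tibble(
    t = seq_len(rounds),
    human_move = human_moves,
    ai_move = ai_moves,
    outcome = outcome,
    dominant_order = dominant
  )
  hm <- member_moves(ens)
  hs <- member_scores(ens)
  for (ord in colnames(hm)) {
    history[[paste0("hyp_move_", ord)]] <- as.character(hm[, ord])
    history[[paste0("hyp_score_", ord)]] <- as.integer(hs[, ord])
  }
  history$cum_score <- cumsum(competitive_score(outcome))
  if (rounds == 0) history$cum_score <- integer(0)
  history
}

new_match <- function(history, config, params = payoff_params(a = config$a)) {
  outcome <- history$outcome
  wins <- sum(outcome == "win")
  draws <- sum(outcome == "draw")
  losses <- sum(outcome == "loss")
  x <- 2L * losses + draws # player virtual points: AI losses are player wins
  pref <- vapply(rps_moves(), function(mv) sum(history$human_move == mv),
                 integer(1))
  summary <- list(
    rounds = nrow(history),
    ai_wins = wins, draws = draws, ai_losses = losses,
    ai_score = wins - losses,
    player_virtual_points = x,
    player_reward = reward(x, params),
    preference_counts = pref,
    trajectory = history$cum_score
  )
  structure(list(history = history, summary = summary, config = config),
            class = "rps_match")
}

#' @export
print.rps_match <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<rps_match> %d rounds vs %s: AI score %d ",
           "(%d wins / %d draws / %d losses), player reward %.2f\n"),
    s$rounds, x$config$opponent, s$ai_score, s$ai_wins, s$draws, s$ai_losses,
    s$player_reward
  ))
  invisible(x)
}

#' In-match hypothetical totals per member
#'
#' The total score each member *would* have earned had it played every round
#' of an already-played match. This is the in-match bookkeeping alternative
#' to [standalone_model_scores()]: it shares one match (and hence the
#' opponent's reactions to the ensemble), whereas standalone scores come
#' from independent matches.
#'
#' @param match A `rps_match`.
#' @return A tibble with columns `order` and `hypothetical_total`.
#' @export
hypothetical_totals <- function(match) {
  stopifnot(inherits(match, "rps_match"))
  cols <- grep("^hyp_score_", names(match$history), value = TRUE)
  tibble::tibble(
    order = as.integer(sub("^hyp_score_", "", cols)),
    hypothetical_total = vapply(cols, function(cc) sum(match$history[[cc]]),
                                numeric(1), USE.NAMES = FALSE)
  )
}

#' Standalone per-order scores against a strategy
#'
#' Plays each single AI alone (a one-member ensemble) against fresh,
#' independently seeded instances of the same strategy — one match per
#' (order, seed) pair — and returns the per-match totals. This is the
#' independent-matches analogue of a per-model score table; see
#' [hypothetical_totals()] for the in-match alternative.
#'
#' @param strategy A `rps_strategy` template.
#' @param orders Integer vector of model orders to evaluate.
#' @param rounds Rounds per match.
#' @param seeds Integer vector of base seeds; each (order, seed) match gets
#'   its own derived master seed.
#' @param params Payoff parameters.
#' @return A tibble with columns `order`, `seed`, `ai_score`.
#' @export
standalone_model_scores <- function(strategy, orders = 1:10, rounds = 300,
                                    seeds = 0:9, params = payoff_params()) {
  stopifnot(inherits(strategy, "rps_strategy"))
  purrr::map_dfr(seeds, function(s) {
    derived <- seed_table(s, 64L)
    purrr::map_dfr(seq_along(orders), function(i) {
      m <- run_match(strategy, orders = orders[i], focus = 1,
                     rounds = rounds, master_seed = derived[33L + i],
                     params = params)
      tibble::tibble(order = orders[i], seed = s,
                     ai_score = m$summary$ai_score)
    })
  })
}

#' Run a multi-AI against a whole opponent population
#'
#' Plays one match per opponent in the population and aggregates the
#' per-match summaries: mean and sample (n-1) standard deviation of the AI
#' scores and the fraction of matches the AI won (score > 0).
#'
#' @param population A list of seeded `rps_opponent` instances (see
#'   [generate_population()], [default_population()]).
#' @param orders,focus,rounds,master_seed,params As in [run_match()]. Each
#'   match's ensemble gets its own master seed derived from `master_seed`;
#'   opponents keep their population seeds.
#' @return An object of class `rps_population`: a list with `matches` (list
#'   of `rps_match`), `summaries` (per-match tibble), `mean_score`,
#'   `sd_score` (`NA` with `single_match = TRUE` when only one match),
#'   `fraction_won` and `config`.
#' @export
population_run <- function(population, orders = 1:5, focus = 5, rounds = 300,
                           master_seed = 0, params = payoff_params()) {
  if (length(population) == 0) rlang::abort("`population` must be nonempty.")
  stopifnot(all(vapply(population, inherits, logical(1), "rps_opponent")))
  match_seeds <- seed_table(master_seed, max(64L, length(population)))
  matches <- purrr::imap(population, function(opp, i) {
    run_match(opp, orders = orders, focus = focus, rounds = rounds,
              master_seed = match_seeds[i], params = params)
  })
  summaries <- purrr::imap_dfr(matches, function(m, i) {
    dplyr::bind_cols(
      tibble::tibble(match = i, opponent = m$config$opponent,
                     opponent_seed = m$config$opponent_seed),
      glance(m)
    )
  })
  scores <- summaries$ai_score
  structure(list(
    matches = matches,
    summaries = summaries,
    mean_score = mean(scores),
    sd_score = if (length(scores) > 1) stats::sd(scores) else NA_real_,
    single_match = length(scores) == 1,
    fraction_won = mean(scores > 0),
    config = list(orders = sort(as.integer(orders)), focus = focus,
                  rounds = rounds, a = params$a,
                  master_seed = as.integer(master_seed))
  ), class = "rps_population")
}

#' @export
print.rps_population <- function(x, ...) {
  cat(sprintf(
    paste0("<rps_population> %d matches of %d rounds: mean AI score %.2f ",
           "(sd %.2f), AI won %.1f%% of matches\n"),
    nrow(x$summaries), x$config$rounds, x$mean_score,
    if (is.na(x$sd_score)) 0 else x$sd_score, 100 * x$fraction_won
  ))
  invisible(x)
}
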