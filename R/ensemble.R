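#' A multi-AI ensemble of fixed-order Markov predictors
#'
#' The ensemble keeps one order-m member per requested order. Every round
#' each member plays *hypothetically* and is scored against the opponent's
#' actual move whether or not it is dominant; the dominant member for the
#' next round is the one with the highest score over the last `focus` rounds
#' (ties go to the lowest order), and its hypothetical move becomes the
#' ensemble's play. The focus length controls how quickly the ensemble
#' re-adapts when the opponent's strategy drifts.
#'
#' Standard presets: `multi_ai(1:5, focus = 5)` ("multi-5AI") and
#' `multi_ai(1:10, focus = 10)` ("multi-10AI").
#'
#' @param orders Distinct positive integer orders, at most 32, any order;
#'   stored sorted ascending.
#' @param focus Focus length F, a positive integer: the number of most
#'   recent completed rounds over which member performance is summed.
#' @param master_seed Integer master seed. Each member's private stream is
#'   derived from it and the member's own order, so a member's draws do not
#'   depend on `focus` or on which other orders are present.
#' @param sample_prediction Passed to [choose_move()] for every member.
#' @return An environment of class `rps_ensemble`. Per-round hypothetical
#'   moves and scores are available through [member_moves()] and
#'   [member_scores()]; the opponent moves seen so far through
#'   `opponent_history()`.
#' @export
multi_ai <- function(orders = 1:5, focus = 5, master_seed = 0,
                     sample_prediction = FALSE) {
  orders <- as.integer(orders)
  if (length(orders) == 0 || any(orders < 1) || anyDuplicated(orders)) {
    rlang::abort("`orders` must be a nonempty set of distinct positive integers.")
  }
  if (any(orders > 32)) rlang::abort("orders above 32 are not supported.")
  stopifnot(length(focus) == 1, focus >= 1)
  orders <- sort(orders)
  e <- new.env(parent = emptyenv())
  e$orders <- orders
  e$focus <- as.integer(focus)
  e$master_seed <- as.integer(master_seed)
  e$sample_prediction <- isTRUE(sample_prediction)
  e$members <- lapply(orders, function(m) {
    single_ai(m, member_seed(master_seed, m))
  })
  e$round_index <- 0L
  e$dominant_order <- orders[1L]
  # Preallocated per-round storage (grown by doubling): opponent moves, and
  # one column per member of hypothetical moves / scores.
  cap <- 512L
  e$opp_hist <- character(cap)
  e$hyp_moves <- matrix(NA_character_, cap, length(orders),
                        dimnames = list(NULL, as.character(orders)))
  e$hyp_scores <- matrix(NA_integer_, cap, length(orders),
                         dimnames = list(NULL, as.character(orders)))
  e$pending <- NULL
  class(e) <- "rps_ensemble"
  e
}

#' @export
print.rps_ensemble <- function(x, ...) {
  cat(sprintf(
    "<rps_ensemble> orders %s, focus length %d, %d rounds played, dominant AI-%d\n",
    paste(x$orders, collapse = ","), x$focus, x$round_index, x$dominant_order
  ))
  invisible(x)
}

grow_ensemble_storage <- function(ens) {
  cap <- length(ens$opp_hist)
  if (ens$round_index < cap) return(invisible(ens))
  add <- cap
  ens$opp_hist <- c(ens$opp_hist, character(add))
  pad_m <- matrix(NA_character_, add, length(ens$orders))
  pad_s <- matrix(NA_integer_, add, length(ens$orders))
  ens$hyp_moves <- rbind(ens$hyp_moves, pad_m)
  ens$hyp_scores <- rbind(ens$hyp_scores, pad_s)
  invisible(ens)
}

#' Per-round ensemble bookkeeping
#'
#' `member_moves()` and `member_scores()` return the hypothetical move and
#' score of every member for every completed round (one row per round, one
#' column per member order); `opponent_history()` the opponent moves seen so
#' far. Every member is scored each round whether or not it was dominant —
#' this is the experts bookkeeping the focus-window selection runs on.
#'
#' @param ens A `rps_ensemble`.
#' @return A character (moves) or integer (scores) matrix with
#'   `ens$round_index` rows, or a character vector for `opponent_history()`.
#' @export
member_scores <- function(ens) {
  ens$hyp_scores[seq_len(ens$round_index), , drop = FALSE]
}

#' @rdname member_scores
#' @export
member_moves <- function(ens) {
  ens$hyp_moves[seq_len(ens$round_index), , drop = FALSE]
}

#' @rdname member_scores
#' @export
opponent_history <- function(ens) {
  ens$opp_hist[seq_len(ens$round_index)]
}

#' Windowed per-member performance totals
#'
#' Sums each member's hypothetical scores over the focus window for the
#' upcoming round `t`: rounds `max(1, t - focus)` to `t - 1` inclusive. The
#' current round is excluded (it has not been played), and while fewer than
#' `focus` rounds exist all completed rounds are used. At `t = 1` all totals
#' are zero.
#'
#' @param scores A numeric matrix of per-round hypothetical scores, one row
#'   per completed round and one column per member, or a match history tibble
#'   holding `hyp_score_<order>` columns (see [run_match()]).
#' @param t Upcoming 1-based round index; `scores` must hold at least rounds
#'   `1..t-1`.
#' @param focus Focus length F.
#' @return A named numeric vector of totals, one per member column.
#' @examples
#' s <- matrix(c(1, -1, 0, 1), 2, 2, dimnames = list(NULL, c("1", "2")))
#' windowed_scores(s, t = 3, focus = 5)
#' @export
windowed_scores <- function(scores, t, focus) {
  if (is.data.frame(scores)) {
    cols <- grep("^hyp_score_", names(scores), value = TRUE)
    mat <- as.matrix(scores[cols])
    colnames(mat) <- sub("^hyp_score_", "", cols)
    scores <- mat
  }
  stopifnot(t >= 1, focus >= 1, nrow(scores) >= t - 1)
  window <- focus_window(t, focus)
  if (length(window) == 0) {
    return(stats::setNames(rep(0, ncol(scores)), colnames(scores)))
  }
  colSums(scores[window, , drop = FALSE])
}

#' @rdname windowed_scores
#' @return `focus_window()`: the integer indices of the rounds in the window
#'   (empty at `t = 1`).
#' @export
focus_window <- function(t, focus) {
  stopifnot(t >= 1, focus >= 1)
  if (t == 1) return(integer(0))
  seq(max(1L, as.integer(t) - as.integer(focus)), as.integer(t) - 1L)
}

#' Pick the dominant member from windowed totals
#'
#' Returns the order achieving the maximum windowed total; ties are broken
#' in favour of the lowest order (which is why the dominant model over the
#' all-zero opening rounds is AI-1).
#'
#' @param totals Numeric vector of windowed totals, one per member, in the
#'   same order as `member_orders`.
#' @param member_orders Ascending integer member orders.
#' @return The dominant member's order (a single integer).
#' @examples
#' select_dominant(c(0, 3), c(1, 4)) # 4
#' select_dominant(c(0, 0, 0), 1:3) # 1
#' @export
select_dominant <- function(totals, member_orders) {
  stopifnot(length(totals) == length(member_orders), length(totals) > 0)
  member_orders[which.max(totals)]
}

#' Generate the ensemble's move for the upcoming round
#'
#' Every member produces a hypothetical move from the opponent-move history;
#' the dominant member is selected from the windowed totals of the members'
#' past hypothetical scores, and its move is returned as the ensemble's play.
#' In round 1 all totals are zero, so the lowest order (AI-1 in the standard
#' banks) is dominant and plays uniformly at random.
#'
#' Must be followed by [ensemble_update()] with the opponent's actual move
#' before the next call.
#'
#' @param ens A `rps_ensemble`.
#' @return A list with elements `ai_move`, `hypothetical_moves` (named by
#'   order) and `dominant_order`.
#' @export
ensemble_move <- function(ens) {
  stopifnot(inherits(ens, "rps_ensemble"))
  if (!is.null(ens$pending)) {
    rlang::abort("ensemble_move() called twice without ensemble_update().")
  }
  opp <- opponent_history(ens)
  hyp <- vapply(ens$members, function(ai) {
    choose_move(ai, opp, ens$sample_prediction)
  }, character(1))
  names(hyp) <- as.character(ens$orders)
  t <- ens$round_index + 1L
  window <- focus_window(t, ens$focus)
  totals <- if (length(window) == 0) {
    rep(0, length(ens$orders))
  } else {
    colSums(ens$hyp_scores[window, , drop = FALSE])
  }
  dominant <- select_dominant(totals, ens$orders)
  ens$dominant_order <- dominant
  res <- list(
    ai_move = unname(hyp[[as.character(dominant)]]),
    hypothetical_moves = hyp,
    dominant_order = dominant
  )
  ens$pending <- res
  res
}

#' Score a round and absorb the opponent's move
#'
#' Closes the round opened by [ensemble_move()]: every member's hypothetical
#' move is scored against the opponent's actual move, the move is fed into
#' every member's transition counts, and a one-row round record is returned.
#'
#' @param ens A `rps_ensemble` with a pending [ensemble_move()].
#' @param opponent_move The opponent's actual move this round.
#' @param record Build and return the round-record tibble (default). Heavy
#'   simulation loops pass `FALSE` and assemble the history once at the end
#'   from [member_moves()] / [member_scores()].
#' @return A one-row tibble with columns `t`, `human_move`, `ai_move`,
#'   `outcome` (AI perspective), `dominant_order`, then `hyp_move_<order>`
#'   and `hyp_score_<order>` per member; `NULL` invisibly when
#'   `record = FALSE`.
#' @export
ensemble_update <- function(ens, opponent_move, record = TRUE) {
  stopifnot(inherits(ens, "rps_ensemble"))
  if (is.null(ens$pending)) {
    rlang::abort("ensemble_update() called without a preceding ensemble_move().")
  }
  check_moves(opponent_move, "opponent_move")
  stopifnot(length(opponent_move) == 1)
  pend <- ens$pending
  hyp <- unname(pend$hypothetical_moves)
  hyp_scores <- competitive_score(
    round_outcome(hyp, rep(opponent_move, length(hyp)))
  )
  for (ai in ens$members) observe(ai$model, opponent_move)
  grow_ensemble_storage(ens)
  t <- ens$round_index + 1L
  ens$opp_hist[t] <- opponent_move
  ens$hyp_moves[t, ] <- hyp
  ens$hyp_scores[t, ] <- hyp_scores
  ens$round_index <- t
  ens$pending <- NULL
  if (!record) return(invisible(NULL))
  rec <- tibble::tibble(
    t = t,
    human_move = opponent_move,
    ai_move = pend$ai_move,
    outcome = round_outcome(pend$ai_move, opponent_move),
    dominant_order = pend$dominant_order
  )
  for (i in seq_along(ens$orders)) {
    rec[[paste0("hyp_move_", ens$orders[i])]] <- hyp[[i]]
    rec[[paste0("hyp_score_", ens$orders[i])]] <- hyp_scores[[i]]
  }
  rec
}
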