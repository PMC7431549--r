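#' Order-m transition counts over an opponent's move sequence
#'
#' A `rps_counts` object accumulates, over the opponent's observed move
#' history, how often each length-m context (the opponent's previous m moves,
#' oldest to newest) was followed by each next move. It is the sufficient
#' statistic of the order-m Markov chain predictor: prediction conditions on
#' the current context's count column, normalised within that column.
#'
#' Counts objects are environments with reference semantics: [observe()]
#' updates them in place (and returns them invisibly), so per-round updates
#' are O(1) regardless of history length.
#'
#' @param m Positive integer order (memory length).
#' @return An environment of class `rps_counts` with fields `m`, `counts`
#'   (a hash of context string to named integer count triple), `n_obs`
#'   (opponent moves observed so far) and `recent` (the last `m` moves).
#' @examples
#' tc <- transition_counts(2)
#' observe(tc, c("R", "P", "S", "R"))
#' tc$n_obs # 4; total counts 4 - 2 = 2
#' predict_distribution(tc, c("R", "P")) # (0, 0, 1): P,S was followed by S...
#' @export
transition_counts <- function(m) {
  stopifnot(is.numeric(m), length(m) == 1, m >= 1, m == as.integer(m))
  e <- new.env(parent = emptyenv())
  e$m <- as.integer(m)
  e$counts <- new.env(parent = emptyenv())
  e$n_obs <- 0L
  e$recent <- character(0)
  class(e) <- "rps_counts"
  e
}

#' @export
print.rps_counts <- function(x, ...) {
  cat(sprintf(
    "<rps_counts> order m = %d, %d moves observed, total counts = %d\n",
    x$m, x$n_obs, total_counts(x)
  ))
  invisible(x)
}

#' Feed opponent moves into a transition-count table
#'
#' Counts every full (context, next move) pair in the history exactly once:
#' after observing `n` moves an order-m table holds `max(0, n - m)` counts in
#' total. Moves may be fed one at a time or in batches; both give identical
#' tables.
#'
#' @param state A `rps_counts` object.
#' @param moves Character vector of newly observed opponent moves, oldest
#'   first. These *extend* the history observed so far.
#' @return The updated `state`, invisibly (updated in place).
#' @export
observe <- function(state, moves) {
  stopifnot(inherits(state, "rps_counts"))
  check_moves(moves, "moves")
  m <- state$m
  recent <- state$recent
  counts <- state$counts
  for (mv in moves) {
    if (length(recent) == m) {
      ctx <- paste(recent, collapse = "")
      col <- counts[[ctx]]
      if (is.null(col)) col <- c(R = 0L, P = 0L, S = 0L)
      col[[mv]] <- col[[mv]] + 1L
      counts[[ctx]] <- col
      recent <- c(recent[-1L], mv)
    } else {
      recent <- c(recent, mv)
    }
  }
  state$recent <- recent
  state$n_obs <- state$n_obs + length(moves)
  invisible(state)
}

#' @rdname observe
#' @export
total_counts <- function(state) {
  sum(vapply(ls(state$counts), function(k) sum(state$counts[[k]]), integer(1))) +
    0L
}

#' Predicted distribution of the opponent's next move
#'
#' Given the current context (the opponent's last m moves), returns the
#' conditional distribution of the next move estimated by normalising that
#' context's count column. If the context is shorter than m or has never been
#' continued, the model falls back to the uniform distribution
#' (1/3, 1/3, 1/3) — there is deliberately no pseudocount smoothing.
#'
#' @param state A `rps_counts` object.
#' @param context Character vector of moves (oldest to newest), or a single
#'   context string such as `"PS"`. May be shorter than `m`.
#' @return A named numeric triple over `R`, `P`, `S` summing to 1.
#' @examples
#' tc <- transition_counts(2)
#' predict_distribution(tc, "PS") # c(R = 1/3, P = 1/3, S = 1/3)
#' @export
predict_distribution <- function(state, context = character(0)) {
  stopifnot(inherits(state, "rps_counts"))
  context <- split_context(context)
  uniform <- c(R = 1 / 3, P = 1 / 3, S = 1 / 3)
  if (length(context) < state$m) return(uniform)
  ctx <- paste(utils::tail(context, state$m), collapse = "")
  col <- state$counts[[ctx]]
  if (is.null(col) || sum(col) == 0L) return(uniform)
  col / sum(col)
}

split_context <- function(context) {
  if (length(context) == 1L && nchar(context) > 1L) {
    context <- strsplit(context, "")[[1]]
  }
  check_moves(context, "context")
  context
}

#' A single fixed-order Markov predictor (AI-m)
#'
#' Bundles an order-m transition-count table with its own deterministic
#' random stream and per-round bookkeeping (the hypothetical move it played
#' and the score it would have earned each round). `single_ai(m, seed)`
#' constructs one; [choose_move()] plays it.
#'
#' @param m Positive integer order.
#' @param seed Integer seed for the model's private random stream.
#' @return An environment of class `rps_single_ai` with fields `m`, `model`
#'   (a `rps_counts`) and `rng` (the model's private random stream). The
#'   per-round hypothetical moves and scores of a member live in its
#'   ensemble, see [member_scores()].
#' @export
single_ai <- function(m, seed) {
  e <- new.env(parent = emptyenv())
  e$m <- as.integer(m)
  e$model <- transition_counts(m)
  e$rng <- new_rng(seed)
  class(e) <- "rps_single_ai"
  e
}

#' @export
print.rps_single_ai <- function(x, ...) {
  cat(sprintf(
    "<rps_single_ai> AI-%d: %d opponent moves observed\n",
    x$m, x$model$n_obs
  ))
  invisible(x)
}

#' Choose the single AI's move for the upcoming round
#'
#' If fewer than m opponent moves have been observed, or the current context
#' has never been continued, the move is drawn uniformly from the model's own
#' random stream. Otherwise the opponent's next move is predicted as the
#' argmax of [predict_distribution()] (ties broken uniformly at random among
#' the tied maxima, again from the model's own stream) and the counter of the
#' prediction is played. With `sample_prediction = TRUE` the prediction is
#' instead sampled from the conditional distribution; the default argmax rule
#' maximises expected score against a stationary opponent.
#'
#' @param ai A `rps_single_ai`.
#' @param opponent_history Character vector of all opponent moves so far.
#' @param sample_prediction Sample the predicted move from the conditional
#'   distribution instead of taking its argmax. Default `FALSE`.
#' @return A single move, `"R"`, `"P"` or `"S"`.
#' @export
choose_move <- function(ai, opponent_history = character(0),
                        sample_prediction = FALSE) {
  stopifnot(inherits(ai, "rps_single_ai"))
  m <- ai$m
  n <- length(opponent_history)
  if (n < m) return(rng_move(ai$rng))
  ctx <- paste(opponent_history[(n - m + 1L):n], collapse = "")
  col <- ai$model$counts[[ctx]]
  if (is.null(col) || sum(col) == 0L) return(rng_move(ai$rng))
  if (sample_prediction) {
    prediction <- rng_move(ai$rng, prob = col / sum(col))
  } else {
    prediction <- rng_pick(ai$rng, names(col)[col == max(col)])
  }
  counter_move(prediction)
}

#' Export a transition-count table as a tidy matrix layout
#'
#' Lays the table out with one row per next move (R, P, S) and one column per
#' length-m context, contexts in lexicographic order with R < P < S, as
#' counts or as fractions of the total count. This is the conventional
#' display for the order-2 table after a short match.
#'
#' @param state A `rps_counts` object.
#' @param normalize One of `"counts"` (raw integers), `"total"` (each cell
#'   divided by the table total, the display convention for short matches) or
#'   `"context"` (each column normalised to sum to 1, the predictive
#'   conditionals; all-zero columns become NA).
#' @return A tibble with a `next_move` column followed by one column per
#'   context.
#' @export
transition_table <- function(state, normalize = c("counts", "total", "context")) {
  stopifnot(inherits(state, "rps_counts"))
  normalize <- match.arg(normalize)
  contexts <- all_contexts(state$m)
  mat <- vapply(contexts, function(ctx) {
    col <- state$counts[[ctx]]
    if (is.null(col)) c(R = 0L, P = 0L, S = 0L) else col
  }, integer(3))
  mat <- switch(normalize,
    counts = mat,
    total = if (sum(mat) > 0) mat / sum(mat) else mat,
    context = sweep(mat, 2, ifelse(colSums(mat) > 0, colSums(mat), NA), "/")
  )
  out <- tibble::as_tibble(as.data.frame(mat, check.names = FALSE))
  dplyr::bind_cols(tibble::tibble(next_move = c("R", "P", "S")), out)
}

# All 3^m contexts, lexicographic with R < P < S, oldest symbol first
# (most significant). expand.grid varies its first factor fastest, so list
# the newest symbol first and reverse the columns when pasting.
all_contexts <- function(m) {
  idx <- as.matrix(expand.grid(rep(list(1:3), m)))[, m:1, drop = FALSE]
  apply(idx, 1L, function(r) paste(rps_moves()[r], collapse = ""))
}
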