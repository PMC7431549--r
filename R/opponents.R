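#' Synthetic opponent strategies
#'
#' Scripted opponents stand in for human players so every other component is
#' testable without human subjects. A strategy is a template (name +
#' parameters + move rule); [opponent_instance()] binds it to a seed to give
#' a reproducible playing instance. Strategies see the full two-sided
#' history — their own and the AI's past moves — which conditional rules such
#' as win-stay-lose-shift require.
#'
#' Shipped strategies:
#' * `opp_uniform()` — the mixed-strategy Nash equilibrium, uniform over
#'   R/P/S; unexploitable by construction.
#' * `opp_biased(prob)` — i.i.d. draws with the given R/P/S probabilities.
#' * `opp_constant(move)` — always the same move.
#' * `opp_cycle(sequence)` — repeats a fixed move sequence.
#' * `opp_wsls()` — win-stay-lose-shift: repeat the own move after a win or
#'   draw; after a loss, shift to the move that would have beaten the AI's
#'   last move.
#' * `opp_counter_own_last()` — plays the counter of its own previous move.
#' * `opp_markov(k, trans)` — an order-k Markov generator over its own
#'   moves, with transition matrix `trans` (one row per length-k context in
#'   the order of `rpsmarkov:::all_contexts(k)`, columns R/P/S, rows summing
#'   to 1); uniform until k moves exist.
#' * `opp_switching(schedule)` — plays each sub-strategy for a fixed number
#'   of rounds in turn (staying on the last one), emulating an opponent
#'   whose strategy changes mid-match.
#'
#' @param prob Numeric length-3 probability vector over R, P, S.
#' @param move A single move `"R"`, `"P"` or `"S"`.
#' @param sequence A move string such as `"RPS"` or a character vector.
#' @param k Positive integer generator order.
#' @param trans Numeric matrix, `3^k` rows (contexts, oldest symbol first,
#'   lexicographic R < P < S) by 3 columns (R, P, S), each row a probability
#'   distribution. Row/column names, if present, must match.
#' @param schedule A list of `list(strategy = <rps_strategy>, rounds = <n>)`
#'   entries.
#' @return An object of class `rps_strategy`.
#' @examples
#' s <- opp_cycle("RPS")
#' inst <- opponent_instance(s, seed = 1)
#' next_opponent_move(inst) # "R"
#' @name opponents
NULL

new_strategy <- function(name, params, fn, type = name) {
  structure(list(name = name, type = type, params = params, fn = fn),
            class = "rps_strategy")
}

#' @export
print.rps_strategy <- function(x, ...) {
  cat(sprintf("<rps_strategy> %s\n", x$name))
  invisible(x)
}

#' @rdname opponents
#' @export
opp_uniform <- function() {
  new_strategy("uniform", list(),
               function(self, own, ai) rng_move(self$rng),
               type = "uniform")
}

#' @rdname opponents
#' @export
opp_biased <- function(prob) {
  prob <- unname(prob)
  if (!is.numeric(prob) || length(prob) != 3 || any(prob < 0) ||
      abs(sum(prob) - 1) > 1e-8) {
    rlang::abort("`prob` must be a length-3 probability vector over R, P, S.")
  }
  new_strategy(sprintf("biased(%.2f,%.2f,%.2f)", prob[1], prob[2], prob[3]),
               list(prob = prob),
               function(self, own, ai) rng_move(self$rng, self$params$prob),
               type = "biased")
}

#' @rdname opponents
#' @export
opp_constant <- function(move) {
  stopifnot(length(move) == 1)
  check_moves(move)
  new_strategy(paste0("constant(", move, ")"), list(move = move),
               function(self, own, ai) self$params$move,
               type = "constant")
}

#' @rdname opponents
#' @export
opp_cycle <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence) > 1L) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  check_moves(sequence, "sequence")
  if (length(sequence) == 0) rlang::abort("`sequence` must be nonempty.")
  new_strategy(paste0("cycle(", paste(sequence, collapse = ""), ")"),
               list(sequence = sequence),
               function(self, own, ai) {
                 seqn <- self$params$sequence
                 seqn[(length(own) %% length(seqn)) + 1L]
               }, type = "cycle")
}

#' @rdname opponents
#' @export
opp_wsls <- function() {
  new_strategy("wsls", list(), function(self, own, ai) {
    n <- length(own)
    if (n == 0) return(rng_move(self$rng))
    last_own <- own[n]
    last_ai <- ai[n]
    # outcome from the strategy's own perspective
    if (round_outcome(last_own, last_ai) == "loss") {
      counter_move(last_ai)
    } else {
      last_own
    }
  }, type = "wsls")
}

#' @rdname opponents
#' @export
opp_counter_own_last <- function() {
  new_strategy("counter_own_last", list(), function(self, own, ai) {
    n <- length(own)
    if (n == 0) rng_move(self$rng) else counter_move(own[n])
  }, type = "counter_own_last")
}

#' @rdname opponents
#' @export
opp_markov <- function(k, trans) {
  stopifnot(length(k) == 1, k >= 1, k == as.integer(k))
  trans <- as.matrix(trans)
  contexts <- all_contexts(k)
  if (nrow(trans) != length(contexts) || ncol(trans) != 3) {
    rlang::abort(sprintf("`trans` must be a %d x 3 matrix.", length(contexts)))
  }
  if (!is.null(rownames(trans)) && !identical(rownames(trans), contexts)) {
    trans <- trans[contexts, , drop = FALSE]
  }
  if (!is.null(colnames(trans)) && !identical(colnames(trans), rps_moves())) {
    trans <- trans[, rps_moves(), drop = FALSE]
  }
  if (any(trans < 0) || any(abs(rowSums(trans) - 1) > 1e-8)) {
    rlang::abort("each row of `trans` must be a probability distribution.")
  }
  dimnames(trans) <- list(contexts, rps_moves())
  new_strategy(paste0("markov_gen(k=", k, ")"),
               list(k = as.integer(k), trans = trans),
               function(self, own, ai) {
                 k <- self$params$k
                 if (length(own) < k) return(rng_move(self$rng))
                 ctx <- paste(utils::tail(own, k), collapse = "")
                 rng_move(self$rng, self$params$trans[ctx, ])
               }, type = "markov_gen")
}

#' @rdname opponents
#' @export
opp_switching <- function(schedule) {
  if (!is.list(schedule) || length(schedule) == 0) {
    rlang::abort("`schedule` must be a nonempty list.")
  }
  for (entry in schedule) {
    if (!inherits(entry$strategy, "rps_strategy") ||
        !is.numeric(entry$rounds) || entry$rounds < 1) {
      rlang::abort("each schedule entry needs a `strategy` and `rounds` >= 1.")
    }
  }
  label <- paste(vapply(schedule, function(e) {
    sprintf("%s:%d", e$strategy$name, as.integer(e$rounds))
  }, character(1)), collapse = "+")
  new_strategy(paste0("switching(", label, ")"), list(schedule = schedule),
               function(self, own, ai) {
                 t <- length(own) + 1L
                 bounds <- cumsum(vapply(self$params$schedule,
                                         function(e) as.integer(e$rounds),
                                         integer(1)))
                 idx <- min(which(t <= bounds), length(bounds))
                 if (t > bounds[length(bounds)]) idx <- length(bounds)
                 sub <- self$params$schedule[[idx]]$strategy
                 pseudo <- list(name = sub$name, params = sub$params,
                                rng = self$rng)
                 sub$fn(pseudo, own, ai)
               }, type = "switching")
}

#' Bind a strategy to a seed
#'
#' Returns a playing instance of a strategy template: an environment holding
#' the strategy and a private deterministic random stream. Given the same
#' (parameters, seed, observed history), the emitted move is reproducible.
#'
#' @param strategy A `rps_strategy` template.
#' @param seed Integer seed for the instance's random stream.
#' @return An environment of class `rps_opponent`.
#' @export
opponent_instance <- function(strategy, seed) {
  stopifnot(inherits(strategy, "rps_strategy"))
  e <- new.env(parent = emptyenv())
  e$name <- strategy$name
  e$type <- strategy$type
  e$params <- strategy$params
  e$fn <- strategy$fn
  e$seed <- as.integer(seed)
  e$rng <- new_rng(seed)
  class(e) <- "rps_opponent"
  e
}

#' @export
print.rps_opponent <- function(x, ...) {
  cat(sprintf("<rps_opponent> %s (seed %d)\n", x$name, x$seed))
  invisible(x)
}

#' Emit the opponent's next move
#'
#' @param opponent A seeded `rps_opponent` instance.
#' @param history The match history so far: a data frame with `human_move`
#'   (the opponent's own past moves) and `ai_move` columns, as produced by
#'   [run_match()], or `NULL` before the first round.
#' @return A single move.
#' @export
next_opponent_move <- function(opponent, history = NULL) {
  stopifnot(inherits(opponent, "rps_opponent"))
  own <- if (is.null(history)) character(0) else history$human_move
  ai <- if (is.null(history)) character(0) else history$ai_move
  opponent$fn(opponent, own, ai)
}

#' Instantiate a reproducibly seeded population of opponents
#'
#' Expands a population specification — a list of entries, each a
#' `list(strategy = <rps_strategy>, count = <n>, seed_base = <s>)` — into
#' seeded instances. Entry `i` with count `n` yields instances with seeds
#' `seed_base, seed_base + 1, ..., seed_base + n - 1`; duplicate seeds
#' anywhere in the population are rejected so no two instances share a
#' random stream.
#'
#' @param spec A list of entries as above.
#' @return A list of `rps_opponent` instances.
#' @seealso [default_population()] for the shipped 52-opponent bank,
#'   [write_population_spec()] for serialisation.
#' @export
generate_population <- function(spec) {
  if (!is.list(spec)) rlang::abort("`spec` must be a list of entries.")
  if (length(spec) == 0) return(list())
  out <- list()
  for (entry in spec) {
    if (!inherits(entry$strategy, "rps_strategy")) {
      rlang::abort("each entry needs a `strategy` of class rps_strategy.")
    }
    count <- entry$count %||% 1L
    if (!is.numeric(count) || count < 1) rlang::abort("`count` must be positive.")
    seed_base <- entry$seed_base %||% rlang::abort("each entry needs a `seed_base`.")
    for (j in seq_len(count)) {
      out <- c(out, list(opponent_instance(entry$strategy, seed_base + j - 1L)))
    }
  }
  seeds <- vapply(out, function(o) o$seed, integer(1))
  if (anyDuplicated(seeds)) {
    rlang::abort("population seeds must be distinct across all instances.")
  }
  out
}

#' The shipped 52-opponent synthetic population
#'
#' A bank of 52 scripted opponents mixing constant players, short cycles
#' (periods 2-5), biased i.i.d. players, win-stay-lose-shift, players who
#' counter their own last move, biased Markov generators and mid-match
#' strategy switchers. All are pattern-bearing (none plays the uniform Nash
#' equilibrium), so a competent opponent-modeling ensemble should beat
#' nearly all of them; the bank is an engineering stand-in for a human
#' cohort, not a model of any particular subjects.
#'
#' @param seed_base Base seed; instance `i` uses `seed_base + i - 1`.
#' @return A list of 52 `rps_opponent` instances.
#' @export
default_population <- function(seed_base = 1000L) {
  sticky <- function(p = 0.8) {
    trans <- matrix((1 - p) / 2, 3, 3, dimnames = list(rps_moves(), rps_moves()))
    diag(trans) <- p
    trans
  }
  templates <- list(
    list(strategy = opp_constant("R"), count = 2),
    list(strategy = opp_constant("P"), count = 2),
    list(strategy = opp_constant("S"), count = 2),
    list(strategy = opp_cycle("RP"), count = 2),
    list(strategy = opp_cycle("RS"), count = 2),
    list(strategy = opp_cycle("PS"), count = 2),
    list(strategy = opp_cycle("RPS"), count = 2),
    list(strategy = opp_cycle("RSP"), count = 2),
    list(strategy = opp_cycle("RRPS"), count = 2),
    list(strategy = opp_cycle("RPPS"), count = 2),
    list(strategy = opp_cycle("RRPSS"), count = 2),
    list(strategy = opp_biased(c(0.6, 0.2, 0.2)), count = 2),
    list(strategy = opp_biased(c(0.2, 0.6, 0.2)), count = 2),
    list(strategy = opp_biased(c(0.2, 0.2, 0.6)), count = 2),
    list(strategy = opp_biased(c(0.5, 0.3, 0.2)), count = 2),
    list(strategy = opp_wsls(), count = 4),
    list(strategy = opp_counter_own_last(), count = 2),
    list(strategy = opp_markov(1, sticky(0.8)), count = 4),
    list(strategy = opp_markov(1, peaked_cycle(0.75)), count = 4),
    list(strategy = opp_markov(1, sticky(0.65)), count = 2),
    list(strategy = opp_switching(list(
      list(strategy = opp_constant("R"), rounds = 100),
      list(strategy = opp_cycle("RPS"), rounds = 200)
    )), count = 2),
    list(strategy = opp_switching(list(
      list(strategy = opp_cycle("PS"), rounds = 150),
      list(strategy = opp_constant("S"), rounds = 150)
    )), count = 2),
    list(strategy = opp_switching(list(
      list(strategy = opp_wsls(), rounds = 150),
      list(strategy = opp_cycle("RRPS"), rounds = 150)
    )), count = 2)
  )
  base <- as.integer(seed_base)
  offset <- 0L
  spec <- lapply(templates, function(tpl) {
    entry <- list(strategy = tpl$strategy, count = tpl$count,
                  seed_base = base + offset)
    offset <<- offset + as.integer(tpl$count)
    entry
  })
  generate_population(spec)
}

# order-1 generator that tends to play the counter of its own last move
peaked_cycle <- function(p = 0.75) {
  trans <- matrix((1 - p) / 2, 3, 3, dimnames = list(rps_moves(), rps_moves()))
  for (ctx in rps_moves()) trans[ctx, counter_move(ctx)] <- p
  trans
}
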