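# Deterministic per-object random streams.
#
# Each single AI and each opponent instance owns an independent stream so
# that replay is bit-stable and one object's draws never perturb another's.
# A stream is an environment holding a saved .Random.seed; draws swap it in,
# run, and swap the caller's RNG state back.

new_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  e$state <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  restore_rng_state(old)
  e
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

rng_draw <- function(rng, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    restore_rng_state(old)
  })
  expr()
}

rng_move <- function(rng, prob = NULL) {
  rng_draw(rng, function() {
    if (is.null(prob)) rps_moves()[sample.int(3L, 1L)]
    else sample(rps_moves(), 1L, prob = prob)
  })
}

rng_pick <- function(rng, x) {
  if (length(x) == 1L) return(x)
  rng_draw(rng, function() x[sample.int(length(x), 1L)])
}

# Fixed 64-slot seed table derived from one master seed. Member streams use
# slot = model order, the opponent stream uses slot 33: which seeds a member
# receives therefore depends only on the master seed and its own order, never
# on the focus length or on which other orders are present.
seed_table <- function(master_seed, n = 64L) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(master_seed))
  s <- sample.int(.Machine$integer.max - 1L, n)
  restore_rng_state(old)
  s
}

member_seed <- function(master_seed, order) {
  stopifnot(order >= 1, order <= 32)
  seed_table(master_seed)[order]
}

opponent_seed <- function(master_seed) seed_table(master_seed)[33L]
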