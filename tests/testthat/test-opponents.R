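test_that("scripted strategies emit the moves their definitions force", {
  # cycle: round 4 of RPS is R again
  inst <- opponent_instance(opp_cycle("RPS"), 1)
  moves <- gen_opponent_moves(inst, 7)
  expect_equal(moves, c("R", "P", "S", "R", "P", "S", "R"))
  expect_equal(gen_opponent_moves(opponent_instance(opp_constant("P"), 1), 4),
               rep("P", 4))
  # counter-own-last settles into the R -> P -> S cycle
  col <- opponent_instance(opp_counter_own_last(), 3)
  mv <- gen_opponent_moves(col, 6)
  expect_equal(mv[2:6], counter_move(mv[1:5]))
})

test_that("win-stay-lose-shift repeats after win/draw and shifts after loss", {
  inst <- opponent_instance(opp_wsls(), 2)
  # opponent played R, AI played S: opponent won -> stays on R
  expect_equal(inst$fn(inst, own = "R", ai = "S"), "R")
  # draw -> stay
  expect_equal(inst$fn(inst, own = "P", ai = "P"), "P")
  # opponent played R, AI played P: opponent lost -> play what beats AI's P
  expect_equal(inst$fn(inst, own = "R", ai = "P"), "S")
})

test_that("random strategies hit their target frequencies", {
  u <- opponent_instance(opp_uniform(), 11)
  moves <- gen_opponent_moves(u, 9999)
  sigma <- sqrt(9999 * (1 / 3) * (2 / 3))
  expect_true(all(abs(table(moves) - 3333) < 3 * sigma))

  trans <- matrix(0.05, 3, 3, dimnames = list(rps_moves(), rps_moves()))
  trans["R", ] <- c(0.05, 0.9, 0.05)
  trans["P", ] <- c(0.9, 0.05, 0.05)
  trans["S", ] <- c(0.45, 0.45, 0.10)
  mk <- opponent_instance(opp_markov(1, trans), 12)
  moves <- gen_opponent_moves(mk, 10000)
  after_r <- moves[which(moves[-length(moves)] == "R") + 1]
  n <- length(after_r)
  sigma <- sqrt(n * 0.9 * 0.1)
  expect_lt(abs(sum(after_r == "P") - 0.9 * n), 3 * sigma)
})

test_that("switching strategies change behaviour on schedule", {
  sw <- opp_switching(list(
    list(strategy = opp_constant("R"), rounds = 5),
    list(strategy = opp_constant("S"), rounds = 5)
  ))
  moves <- gen_opponent_moves(opponent_instance(sw, 1), 13)
  expect_equal(moves, c(rep("R", 5), rep("S", 8))) # stays on the last entry
})

test_that("malformed strategy parameters are rejected at construction", {
  expect_error(opp_biased(c(0.5, 0.5)), "length-3")
  expect_error(opp_biased(c(0.5, 0.4, 0.2)), "probability")
  expect_error(opp_constant("Q"), "must contain only")
  expect_error(opp_cycle(character(0)), "nonempty")
  expect_error(opp_markov(1, matrix(1, 2, 3)), "3 x 3")
  expect_error(opp_markov(1, matrix(0.5, 3, 3)), "probability")
  expect_error(opp_switching(list()), "nonempty")
})

test_that("populations are reproducibly seeded and reject duplicate seeds", {
  spec <- list(
    list(strategy = opp_cycle("RP"), count = 2, seed_base = 10),
    list(strategy = opp_wsls(), count = 3, seed_base = 100)
  )
  pop <- generate_population(spec)
  expect_length(pop, 5)
  expect_equal(vapply(pop, function(o) o$seed, integer(1)),
               c(10L, 11L, 100L, 101L, 102L))
  # same spec twice: identical move sequences per instance
  pop2 <- generate_population(spec)
  for (i in seq_along(pop)) {
    expect_identical(gen_opponent_moves(pop[[i]], 30),
                     gen_opponent_moves(pop2[[i]], 30))
  }
  expect_identical(generate_population(list()), list())
  clash <- list(
    list(strategy = opp_wsls(), count = 2, seed_base = 1),
    list(strategy = opp_uniform(), count = 1, seed_base = 2)
  )
  expect_error(generate_population(clash), "distinct")
})

test_that("the shipped default population has 52 distinctly seeded members", {
  pop <- default_population()
  expect_length(pop, 52)
  seeds <- vapply(pop, function(o) o$seed, integer(1))
  expect_false(anyDuplicated(seeds) > 0)
})

test_that("deterministic strategies are exploited within a short burn-in", {
  # per-round score is permanently +1 after at most round 30
  strategies <- list(opp_constant("R"), opp_cycle("RP"), opp_cycle("RPS"),
                     opp_cycle("RRPS"), opp_cycle("RRPSS"))
  for (strat in strategies) {
    for (s in c(0, 25, 50, 75, 99)) {
      m <- run_match(strat, 1:5, 5, 100, master_seed = s)
      sc <- competitive_score(m$history$outcome)
      expect_true(all(sc[31:100] == 1),
                  label = sprintf("%s, seed %d exploited after burn-in",
                                  strat$name, s))
    }
  }
})

test_that("the Nash-uniform opponent is not exploitable", {
  m <- run_match(opp_uniform(), 1:5, 5, 10000, master_seed = 8)
  expect_lt(abs(m$summary$ai_score / 10000), 3 / sqrt(10000))
})
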