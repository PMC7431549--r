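test_that("transition counts match hand-enumerated pairs", {
  # m=1, R P R P: R->P twice, P->R once
  tc <- transition_counts(1)
  observe(tc, c("R", "P", "R", "P"))
  expect_equal(tc$counts[["R"]], c(R = 0L, P = 2L, S = 0L))
  expect_equal(tc$counts[["P"]], c(R = 1L, P = 0L, S = 0L))
  expect_equal(total_counts(tc), 3L)
  # m=3 with history of length 3: no full (context, next) pair yet
  tc3 <- transition_counts(3)
  observe(tc3, c("R", "P", "S"))
  expect_equal(total_counts(tc3), 0L)
  expect_error(observe(tc3, "Q"), "must contain only")
})

test_that("count conservation holds: total counts = max(0, n - m)", {
  set.seed(11)
  for (m in c(1, 2, 4)) {
    for (n in c(0, 1, m, m + 1, 20, 57)) {
      hist <- sample(rps_moves(), n, replace = TRUE)
      tc <- transition_counts(m)
      observe(tc, hist)
      expect_equal(total_counts(tc), max(0L, n - m))
      expect_equal(tc$n_obs, n)
    }
  }
})

test_that("incremental observation equals batch rebuild and the enumeration oracle", {
  # exhaustive over short histories; the full-depth sweep runs in the
  # acceptance property suite
  set.seed(7)
  for (m in 1:3) {
    n_bad <- 0L
    for (len in 0:5) {
      hmat <- all_histories(len)
      for (r in seq_len(nrow(hmat))) {
        hist <- as.character(hmat[r, ])
        inc <- transition_counts(m)
        for (mv in hist) observe(inc, mv)
        batch <- transition_counts(m)
        observe(batch, hist)
        ok <- identical(counts_as_list(inc), counts_as_list(batch)) &&
          identical(counts_as_list(inc), oracle_counts(hist, m))
        if (!ok) n_bad <- n_bad + 1L
      }
    }
    expect_equal(n_bad, 0L, label = sprintf("mismatching histories (m=%d)", m))
  }
})

test_that("prediction normalises within the context column, uniform fallback otherwise", {
  tc <- transition_counts(2)
  # unseen context -> exact uniform
  expect_identical(predict_distribution(tc, "PS"),
                   c(R = 1 / 3, P = 1 / 3, S = 1 / 3))
  # context shorter than m -> uniform
  expect_identical(predict_distribution(tc, "R"),
                   c(R = 1 / 3, P = 1 / 3, S = 1 / 3))
  tc$counts[["RP"]] <- c(R = 1L, P = 0L, S = 0L)
  expect_equal(predict_distribution(tc, "RP"), c(R = 1, P = 0, S = 0))
  tc$counts[["SS"]] <- c(R = 2L, P = 1L, S = 1L)
  d <- predict_distribution(tc, c("S", "S"))
  expect_equal(d, c(R = 0.5, P = 0.25, S = 0.25))
  expect_equal(sum(d), 1)
})

test_that("choose_move counters a certain prediction and randomises ties", {
  ai <- single_ai(2, seed = 123)
  ai$model$counts[["RR"]] <- c(R = 5L, P = 0L, S = 0L)
  expect_equal(choose_move(ai, c("P", "R", "R")), "P")
  # tie between R and P predictions -> counter is P or S, about half each
  ai$model$counts[["RR"]] <- c(R = 2L, P = 2L, S = 0L)
  draws <- vapply(1:4000, function(i) {
    a <- single_ai(2, seed = i)
    a$model$counts[["RR"]] <- c(R = 2L, P = 2L, S = 0L)
    choose_move(a, c("R", "R"))
  }, character(1))
  expect_setequal(unique(draws), c("P", "S"))
  n <- length(draws)
  sigma <- sqrt(n * 0.25)
  expect_lt(abs(sum(draws == "P") - n / 2), 3 * sigma)
})

test_that("a short history forces a uniform random move from the model's own stream", {
  draws <- vapply(1:9999, function(i) {
    choose_move(single_ai(2, seed = i), "R")
  }, character(1))
  freq <- table(draws)
  expect_setequal(names(freq), rps_moves())
  sigma <- sqrt(9999 * (1 / 3) * (2 / 3))
  expect_true(all(abs(freq - 3333) < 3 * sigma))
})

test_that("a single AI recovers the generating transition matrix", {
  p_stay <- 0.8
  trans <- matrix((1 - p_stay) / 2, 3, 3,
                  dimnames = list(rps_moves(), rps_moves()))
  diag(trans) <- p_stay
  inst <- opponent_instance(opp_markov(1, trans), seed = 5)
  moves <- gen_opponent_moves(inst, 10000)
  tc <- transition_counts(1)
  observe(tc, moves)
  est <- t(vapply(rps_moves(), function(ctx) {
    col <- tc$counts[[ctx]]
    col / sum(col)
  }, numeric(3)))
  expect_lt(mean(abs(est - trans)), 0.05)
})

test_that("AI-1 locks onto a constant opponent after the opening rounds", {
  # uniform first round, first observation in round 2, winning counter after
  for (s in c(0, 17, 99)) {
    m <- run_match(opp_constant("S"), orders = 1, focus = 1, rounds = 50,
                   master_seed = s)
    expect_true(all(m$history$outcome[3:50] == "win"))
  }
})

test_that("the exported transition table is laid out next-move by context", {
  tc <- transition_counts(1)
  observe(tc, c("R", "P", "R", "P"))
  tab <- transition_table(tc)
  expect_equal(names(tab), c("next_move", "R", "P", "S"))
  expect_equal(tab$next_move, c("R", "P", "S"))
  expect_equal(tab$R, c(0L, 2L, 0L)) # R was followed by P twice
  expect_equal(tab$P, c(1L, 0L, 0L))
  frac <- transition_table(tc, normalize = "total")
  expect_equal(sum(frac$R + frac$P + frac$S), 1)
  # order-2 context ordering: oldest symbol most significant, R < P < S
  expect_equal(
    names(transition_table(transition_counts(2)))[-1][1:4],
    c("RR", "RP", "RS", "PR")
  )
})
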