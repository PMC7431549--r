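test_that("match summaries satisfy their accounting identities", {
  for (opp in list(opp_uniform(), opp_wsls(), opp_biased(c(0.5, 0.3, 0.2)))) {
    m <- run_match(opp, 1:5, 5, 150, master_seed = 6)
    s <- m$summary
    expect_equal(s$ai_wins + s$draws + s$ai_losses, s$rounds)
    expect_equal(s$ai_score, s$ai_wins - s$ai_losses)
    expect_equal(sum(s$preference_counts), s$rounds)
    expect_equal(s$player_virtual_points, 2 * s$ai_losses + s$draws)
    expect_equal(s$player_reward, s$player_virtual_points * 0.15 + 5)
    # trajectory ends at the total and matches the cumulative outcome sum
    expect_equal(s$trajectory[length(s$trajectory)], s$ai_score)
    expect_equal(s$trajectory, cumsum(competitive_score(m$history$outcome)))
    # zero-sum: the player's competitive score is the mirror image
    expect_equal(sum(competitive_score(round_outcome(m$history$human_move,
                                                     m$history$ai_move))),
                 -s$ai_score)
  }
})

test_that("a zero-round match is empty but well-formed", {
  m <- run_match(opp_uniform(), 1:3, 5, 0, master_seed = 1)
  expect_equal(m$summary$ai_score, 0)
  expect_length(m$summary$trajectory, 0)
  expect_equal(nrow(m$history), 0)
  expect_equal(m$summary$player_reward, 5)
})

test_that("matches replay bit-identically from the same configuration", {
  a <- run_match(opp_wsls(), 1:5, 5, 200, master_seed = 31)
  b <- run_match(opp_wsls(), 1:5, 5, 200, master_seed = 31)
  expect_identical(a$history, b$history)
  c <- run_match(opp_wsls(), 1:5, 5, 200, master_seed = 32)
  expect_false(identical(a$history$ai_move, c$history$ai_move))
})

test_that("constant opponents are beaten in nearly every round", {
  for (s in c(0, 11, 47, 99)) {
    m <- run_match(opp_constant("R"), 1:5, 5, 300, master_seed = s)
    expect_gte(m$summary$ai_score, 296)
  }
})

test_that("standalone per-order scores find the order a cycle requires", {
  # a period-4 cycle carries no order-1 information on part of its contexts,
  # so AI-4 beats AI-1 in every paired seed
  sc <- standalone_model_scores(opp_cycle("RPPS"), orders = c(1, 4),
                                rounds = 300, seeds = 0:19)
  wide <- tidyr::pivot_wider(sc, names_from = "order", values_from = "ai_score",
                             names_prefix = "ai")
  expect_true(all(wide$ai4 > wide$ai1))
  # worst case: 8 burn-in rounds (4 with n < m, 4 unseen contexts) all lost,
  # perfect play afterwards: 292 - 8 = 284
  expect_true(all(wide$ai4 >= 284))
})

test_that("standalone scores of a Nash opponent hover at zero", {
  sc <- standalone_model_scores(opp_uniform(), orders = c(1, 3), rounds = 500,
                                seeds = 0:9)
  per_order <- dplyr::summarise(dplyr::group_by(sc, order),
                                mean = mean(ai_score), n = dplyr::n())
  # mean per-round score within 3 sigma of 0 (sigma <= 1 per round)
  expect_true(all(abs(per_order$mean) / 500 < 3 / sqrt(500 * 10)))
})

test_that("a single-member ensemble match equals the standalone match", {
  m1 <- run_match(opp_cycle("RSP"), orders = 2, focus = 1, rounds = 100,
                  master_seed = 5)
  m2 <- run_match(opp_cycle("RSP"), orders = 2, focus = 9, rounds = 100,
                  master_seed = 5)
  # focus is irrelevant with one member
  expect_identical(m1$history$ai_move, m2$history$ai_move)
})

test_that("population aggregation matches a two-pass oracle and its invariants", {
  pop <- generate_population(list(
    list(strategy = opp_cycle("RP"), count = 2, seed_base = 1),
    list(strategy = opp_wsls(), count = 2, seed_base = 50),
    list(strategy = opp_uniform(), count = 1, seed_base = 99)
  ))
  pr <- population_run(pop, 1:5, 5, 120, master_seed = 3)
  scores <- pr$summaries$ai_score
  # two-pass mean/sd oracle
  n <- length(scores)
  mu <- sum(scores) / n
  ss <- sum((scores - mu)^2)
  expect_equal(pr$mean_score, mu)
  expect_equal(pr$sd_score, sqrt(ss / (n - 1)))
  expect_equal(pr$fraction_won, sum(scores > 0) / n)
  expect_equal(nrow(pr$summaries), 5)
  # single-match population: sd undefined, flagged
  one <- population_run(pop[1], 1:5, 5, 60, master_seed = 3)
  expect_true(one$single_match)
  expect_true(is.na(one$sd_score))
  expect_equal(one$mean_score, one$summaries$ai_score[1])
  expect_error(population_run(list()), "nonempty")
})

test_that("in-match hypothetical totals recompute from the history columns", {
  m <- run_match(opp_cycle("RRPS"), 1:5, 5, 80, master_seed = 9)
  ht <- hypothetical_totals(m)
  expect_equal(ht$order, 1:5)
  for (i in 1:5) {
    expect_equal(ht$hypothetical_total[i],
                 sum(m$history[[paste0("hyp_score_", i)]]))
  }
})

test_that("preference and model-score tables summarise a population", {
  pop <- generate_population(list(
    list(strategy = opp_biased(c(0.6, 0.2, 0.2)), count = 3, seed_base = 7)
  ))
  pr <- population_run(pop, 1:3, 3, 200, master_seed = 2)
  pt <- preference_table(pr)
  expect_equal(pt$move, c("R", "P", "S"))
  expect_equal(sum(pt$mean), 200)
  expect_gt(pt$mean[pt$move == "R"], pt$mean[pt$move == "P"]) # the bias shows
  mst <- model_score_table(pop, orders = 1:3, rounds = 100, master_seed = 1)
  expect_equal(nrow(mst), 3 + 2) # players + MEAN + STDEVA
  expect_equal(mst$player[4:5], c("MEAN", "STDEVA"))
  expect_equal(mst$single_model_avg[1], mean(unlist(mst[1, c("AI1", "AI2", "AI3")])))
  expect_equal(mst$AI1[4], mean(mst$AI1[1:3]))
  expect_equal(mst$AI1[5], stats::sd(mst$AI1[1:3]))
})

test_that("tidy and glance expose the standard views", {
  m <- run_match(opp_cycle("RPS"), 1:3, 5, 40, master_seed = 1)
  expect_identical(tidy(m), m$history)
  g <- glance(m)
  expect_equal(g$rounds, 40)
  expect_equal(g$ai_score, m$summary$ai_score)
  pop <- population_run(default_population()[1:3], 1:3, 5, 40, master_seed = 1)
  expect_equal(nrow(tidy(pop)), 3)
  expect_equal(glance(pop)$n_matches, 3)
  tc <- transition_counts(1)
  observe(tc, c("R", "P", "R", "P"))
  td <- tidy(tc)
  expect_equal(sum(td$count), 3)
  expect_equal(glance(tc)$total_counts, 3)
})

test_that("autoplot returns ggplot objects for matches and populations", {
  m <- run_match(opp_cycle("RPS"), 1:3, 5, 30, master_seed = 1)
  expect_s3_class(autoplot(m), "ggplot")
  expect_s3_class(autoplot(m, show_dominant = TRUE), "ggplot")
  pop <- population_run(default_population()[1:3], 1:3, 5, 30, master_seed = 1)
  expect_s3_class(autoplot(pop), "ggplot")
  sc <- standalone_model_scores(opp_cycle("RP"), orders = 1:2, rounds = 50,
                                seeds = 0:2)
  expect_s3_class(plot_model_scores(sc), "ggplot")
})
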