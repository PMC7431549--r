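# rpsmarkov

Opponent modeling for iterated Rock-Paper-Scissors with an ensemble of
fixed-memory Markov-chain predictors.

## The problem

In iterated RPS the mixed-strategy Nash equilibrium — play R, P, S with
probability 1/3 each — is unexploitable, but humans are poor randomisers:
their move streams carry short sequential patterns, and different people
carry different ones. A single fixed-memory predictor beats some opponents
and is blind to others. This package is for researchers in behavioural game
theory and sequential decision modeling who want a reference implementation
of the adaptive-ensemble approach: a bank of Markov models of different
memory lengths plus an online model-selection rule, with the payoff
accounting, opponent simulators, logging and replay verification needed to
run and audit experiments.

## The model

**AI-m** is an order-m Markov chain over the opponent's move sequence: it
counts transitions (x<sub>n−m</sub>, …, x<sub>n−1</sub>) → x<sub>n</sub>,
predicts the opponent's next move as the argmax of
Pr(X<sub>n</sub> | X<sub>n−1</sub>, …, X<sub>n−m</sub>) estimated by those
counts, and plays the counter of the prediction. With fewer than m moves
observed, an unseen context, or tied maxima it falls back to a uniform
random move (no smoothing).

**Multi-AI** keeps one member per order (presets: orders 1–5 with F = 5,
"multi-5AI"; orders 1–10 with F = 10, "multi-10AI"). Every round each
member plays hypothetically and is scored +1/0/−1 against the opponent's
actual move; the member with the highest score over the last **F** rounds
(the *focus length* window, ties to the lowest order) becomes dominant and
its move is played. F controls the speed and sensitivity of adaptation
when the opponent's strategy changes.

**Payoffs.** The match metric is the competitive score, wins − losses. The
experimental currency gives the human 2 virtual points per win, 1 per
draw, 0 per loss, cashed out as y = x·r + 5 RMB with r = 0.45/(1+a); at
the neutral payoff parameter a = 2, r = 0.15 and a Nash-equilibrium player
expects exactly 50 RMB over 300 rounds.

## A worked example

Play the multi-5AI against a win-stay-lose-shift opponent for 300 rounds:

```r
library(rpsmarkov)
m <- run_match(opp_wsls(), orders = 1:5, focus = 5, rounds = 300,
               master_seed = 7)
m
#> <rps_match> 300 rounds vs wsls: AI score 54 (144 wins / 66 draws / 90 losses), player reward 41.90
glance(m)
#> # A tibble: 1 × 10
#>   rounds ai_wins draws ai_losses ai_score player_virtual_points player_reward ...
#> 1    300     144    66        90       54                   246          41.9
```

The AI finished 54 up (144 wins vs 90 losses out of 300 rounds). The
"player reward" line is what the opponent would have been paid in the
experimental protocol: 2·90 + 66 = 246 virtual points × 0.15 + 5 = 41.90
RMB — below the 50 RMB a Nash-playing opponent expects, the monetary face
of being exploited. Per-member bookkeeping shows why the ensemble helps:

```r
hypothetical_totals(m)
#> # A tibble: 5 × 2
#>   order hypothetical_total
#> 1     1                 30
#> 2     2                 94
#> 3     3                 99
#> 4     4                103
#> 5     5                113
```

Order 1 alone would have scored 30; the higher-order members see more of
the win-stay-lose-shift structure, and the focus window routes play to
them. `tidy(m)` returns the full round-by-round history (moves, outcome,
dominant member, every member's hypothetical move and score),
`autoplot(m)` plots the cumulative score trajectory, and
`write_match_log(m, "match.tsv")` / `replay("match.tsv")` round-trip and
verify the log bit-for-bit.

Population-level experiments mirror a cohort study:

```r
pr <- population_run(default_population(), orders = 1:5, focus = 5,
                     rounds = 300, master_seed = 1)
pr
#> <rps_population> 52 matches of 300 rounds: mean AI score 217.69 (sd 91.86), AI won 100.0% of matches
```

A command-line interface wraps the same functions
(`inst/cli/rps simulate|play|replay|bench`), including live interactive
play against the ensemble.

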