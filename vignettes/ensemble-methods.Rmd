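---
title: "Opponent modeling in iterated Rock-Paper-Scissors: the Markov ensemble, its parameters, and what the synthetic tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Opponent modeling in iterated Rock-Paper-Scissors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpsmarkov)
library(dplyr)
```

## The model

Iterated Rock-Paper-Scissors against a rational opponent has a unique
mixed-strategy Nash equilibrium — play each move with probability 1/3 — and
under it no strategy gains an edge. People, however, are poor randomisers:
their move streams carry short sequential dependencies. This package
implements a predictor bank that exploits exactly that.

**Single model (AI-m).** An order-m Markov chain over the *opponent's* move
sequence. The model keeps a table of transition counts indexed by context
(the opponent's previous m moves, oldest to newest) and next move. After
`n` observed moves the table holds exactly `max(0, n - m)` counts — every
full (context, next) pair in the history is counted once. To play, the
model conditions on the current context, takes the argmax of the
normalised count column as its prediction of the opponent's next move, and
plays the counter of that prediction. Three situations fall back to a
uniformly random move drawn from the model's own stream: fewer than m moves
observed, a context that has never been continued, and ties among the
argmax (broken uniformly among the tied maxima). There is deliberately *no*
pseudocount smoothing: the empty-context behaviour is an explicit uniform
fallback, which keeps the predictive semantics identical to the counting
semantics.

The chains model only the opponent's own stream, not joint
(own move, opponent move) states. Conditional opponent rules such as
win-stay-lose-shift are therefore not perfectly representable — but their
*statistical* footprint in the opponent's own stream (e.g. "repeat after
most rounds") is, and that is what gets exploited.

**Ensemble (multi-AI).** One member per order, typically orders 1..5
("multi-5AI") or 1..10 ("multi-10AI"). Every round *every* member plays
hypothetically and is scored against the opponent's actual move
(+1 win / 0 draw / −1 loss), whether or not it was the member whose move
was used. The member whose hypothetical score summed over the last F
completed rounds — the **focus length** window — is highest becomes
dominant and plays the next round. The window excludes the round being
played; while fewer than F rounds exist, all completed rounds are used.
Ties go to the lowest order, which makes AI-1 the opening dominant model
while all totals are zero. Re-selection happens every round with no
hysteresis: F alone controls how quickly the ensemble abandons a member
when the opponent's strategy drifts (small F adapts fast but is noisy,
large F is stable but slow).

**Payoff accounting.** Matches are scored two ways, both derived from the
same outcome sequence. The competitive score is wins minus losses, the
headline match metric. The experimental payoff gives the *human* player
2 virtual points per win, 1 per draw, 0 per loss, converted to cash as
`y = x·r + 5` with exchange rate `r = 0.45/(1 + a)` and show-up fee 5 RMB.
The payoff parameter `a` (incentive for winning over incentive for
drawing) is 2 throughout, the neutral game, giving `r = 0.15`; a player at
the Nash equilibrium expects `(1 + a)/3 = 1` point per round and hence
50 RMB over a 300-round session. These identities are computed, not
stored:

```{r payoff}
exchange_rate(2)
reward(300, payoff_params(a = 2))
match_totals_summary(198, 55, 47)[, c("ai_score", "win_loss_ratio")]
```

## Parameters that matter

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `orders` | member memory lengths (rounds) | 1–5 | the standard small bank; 1–10 with `focus = 10` is the large preset |
| `focus` (F) | performance window (rounds) | 5 | matches the small bank; re-selection granularity |
| `rounds` | session length | 300 | the standard session length for which the payoff calibration gives 50 RMB at Nash |
| `a` | win/draw incentive ratio | 2 | the neutral game |
| `master_seed` | reproducibility root | — | all streams derive from it |
| `sample_prediction` | sample prediction from the conditional instead of argmax | `FALSE` | argmax maximises expected score against a stationary opponent; in the uniform-column case the two rules coincide |

## Randomness and determinism

Every stochastic object — each ensemble member and each opponent
instance — owns an independent deterministic stream: a saved RNG state
swapped in around each draw. Member streams are derived from
`(master_seed, order)` through a fixed 64-slot seed table, so a member's
draws depend only on the master seed and its own order — never on the
focus length or on which other orders are present. Two consequences are
tested as invariants: identical `(orders, focus, rounds, master_seed,
opponent)` reproduce a match bit-for-bit, and changing F changes only the
dominant choice (and hence the played move), never any member's
hypothetical move sequence.

## The synthetic opponents, and what they do and do not show

The human cohort the method was built for cannot ship with a package, so
all test inputs come from scripted strategies: constants, short cycles
(periods 2–5), biased i.i.d. players, win-stay-lose-shift, players who
counter their own last move, biased order-k Markov generators, and
mid-match switchers. The shipped 52-opponent default bank
(`default_population()`) deliberately contains only pattern-bearing
strategies — none plays uniform Nash — because its purpose is to exercise
the ensemble's reason for existing: different orders are blind to
different patterns (AI-1 cannot see a period-4 cycle; AI-4 can), and the
focus window must find the member that can see the current opponent.
Against this bank the multi-5AI wins at least 95% of 300-round matches,
which mirrors the shape of the human result without claiming it: real
humans are noisier, drift more idiosyncratically, and respond to the AI's
play in ways no fixed generator reproduces. Passing the synthetic suite
shows the machinery is correct and the adaptation works against known
pattern classes; it does not measure human exploitability.

Strategy parameters in the bank (bias vectors around 0.5–0.6 on one move,
generator self-transition probabilities 0.65–0.8, switch points at
100–150 rounds) were chosen once as plausible strengths of human-like
patterning — strong enough that a working predictor must find them, weak
enough that the uniform fallback and the focus window still matter.

```{r population}
pr <- population_run(default_population(), orders = 1:5, focus = 5,
                     rounds = 300, master_seed = 1)
glance(pr)
preference_table(pr)
```

## Numerical and design choices

* **Tie-breaks.** Dominant selection ties go to the lowest order (forced
  by the all-zero opening); argmax ties inside a member go to a uniform
  draw from that member's stream (keeping determinism confined to streams).
* **Counts are integers.** Normalisation — including the whole-table
  "fractions of 18" display after a 20-move match — is presentation only;
  prediction always conditions within a context column.
* **Context order.** Context strings read oldest to newest; exported
  tables order the `3^m` contexts lexicographically with R < P < S.
* **Degenerate inputs.** Zero-round matches yield empty, well-formed
  histories (score 0, reward = show-up fee). A one-member ensemble is
  exactly the bare single model; its focus length is irrelevant. A
  single-match population reports its score as the mean and flags the
  sample standard deviation as undefined rather than inventing a zero.
* **Standalone vs in-match model scores.** Per-order score tables
  (`model_score_table()`, `standalone_model_scores()`) come from
  *independent* matches — each single AI plays its own match against a
  fresh instance of the opponent — because reading hypothetical totals out
  of one ensemble match couples every member to the opponent's reactions
  to the *ensemble's* play. The in-match alternative is still exposed,
  clearly labelled, as `hypothetical_totals()`.
* **Replay modes.** A log whose header carries the master seed replays
  bit-for-bit (every column compared exactly). A foreign log without seed
  provenance is verified as far as determinism allows: forced member moves
  exactly, random draws distributionally (3-sigma binomial band), scores /
  dominant order / outcome by recomputation from the logged values. A
  column-mapping option adapts foreign tabular layouts rather than
  guessing them.

## Problem sizes used in the shipped checks

The test suite exercises: exhaustive incremental-vs-batch count
equivalence for all histories up to length 8 at orders 1–3; generator
recovery and Nash neutrality at 10^4 rounds; 300-round matches across
100-seed sweeps for the constant-opponent and period-3-cycle bounds; and
the 52-opponent population at 300 rounds for a few master seeds. These
sizes make every stochastic bound a multi-sigma event rather than a coin
flip while keeping a full run in minutes on one core.

## Known limitations

* The predictors model marginal sequential structure of the opponent's
  stream only; strategies conditioned on the AI's moves are exploited only
  through their footprint in that stream.
* No smoothing means early-match predictions lurch between uniform and
  hard argmax on one observation; that is the intended semantics, not an
  estimator of the opponent's true conditionals.
* High orders are data-starved in 300 rounds (3^10 contexts vs ~300
  observations); the focus window, not any regularisation, is what keeps
  them from dominating while ignorant.
* The synthetic population is an engineering stand-in; nothing in it is
  fitted to human data.
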