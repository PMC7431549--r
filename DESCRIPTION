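Package: rpsmarkov
Title: Markov-Chain Ensemble Opponent Modeling for Iterated Rock-Paper-Scissors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Plays and analyses iterated Rock-Paper-Scissors with an ensemble
    of fixed-memory Markov-chain predictors. Each order-m member predicts the
    opponent's next move from its previous m moves and plays the counter; a
    sliding "focus length" window over per-member hypothetical scores selects
    the dominant member each round. Ships synthetic opponent strategies, a
    tournament harness with match and population summaries, experimental
    payoff accounting (virtual points and cash reward), match-log replay
    verification, and a command-line interface for simulated and interactive
    play.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
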