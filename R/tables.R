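#' Move-preference summary across a population
#'
#' For each opponent the number of times it chose R, P and S over its match,
#' summarised across the population as the mean and sample (n-1) standard
#' deviation — the per-move preference table for a cohort. Per-opponent
#' counts always sum to the number of rounds.
#'
#' @param pop A `rps_population`.
#' @return A tibble with columns `move`, `mean`, `sd`.
#' @export
preference_table <- function(pop) {
  stopifnot(inherits(pop, "rps_population"))
  counts <- purrr::map_dfr(pop$matches, function(m) {
    p <- m$summary$preference_counts
    tibble::tibble(R = p[["R"]], P = p[["P"]], S = p[["S"]])
  })
  tidyr::pivot_longer(counts, dplyr::everything(), names_to = "move") |>
    dplyr::group_by(.data$move) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) stats::sd(.data$value) else NA_real_,
                     .groups = "drop") |>
    dplyr::arrange(match(.data$move, rps_moves()))
}

#' Per-model and ensemble score table across a population
#'
#' For every opponent: the standalone total score of each single AI (each
#' played alone against a fresh instance of that opponent), the average of
#' those single-model scores, and the totals of the multi-10AI
#' (orders 1..10, focus 10) and multi-5AI (orders 1..5, focus 5) ensembles.
#' Two summary rows (`MEAN`, `STDEVA`, sample standard deviation) close the
#' table. Standalone scores come from independent matches — the opponent is
#' re-instantiated per column — rather than from in-match hypothetical
#' bookkeeping; see [hypothetical_totals()] for the latter.
#'
#' @param population A list of seeded `rps_opponent` instances.
#' @param orders Single-model orders to tabulate (default 1..10).
#' @param rounds Rounds per match.
#' @param master_seed Master seed; every match gets a derived seed.
#' @param params Payoff parameters.
#' @return A tibble with one row per opponent plus MEAN and STDEVA rows;
#'   columns `player`, `AI<order>`..., `single_model_avg`, `multi10_score`,
#'   `multi5_score`.
#' @export
model_score_table <- function(population, orders = 1:10, rounds = 300,
                              master_seed = 0, params = payoff_params()) {
  stopifnot(length(population) > 0)
  seeds <- seed_table(master_seed, max(64L, length(population) * (length(orders) + 2L)))
  k <- 0L
  next_seed <- function() {
    k <<- k + 1L
    seeds[k]
  }
  rows <- purrr::imap_dfr(population, function(opp, i) {
    single <- vapply(orders, function(ord) {
      run_match(opp, orders = ord, focus = 1, rounds = rounds,
                master_seed = next_seed(), params = params)$summary$ai_score
    }, numeric(1))
    multi10 <- run_match(opp, orders = seq_len(max(orders)), focus = 10,
                         rounds = rounds, master_seed = next_seed(),
                         params = params)$summary$ai_score
    multi5 <- run_match(opp, orders = 1:5, focus = 5, rounds = rounds,
                        master_seed = next_seed(),
                        params = params)$summary$ai_score
    row <- tibble::tibble(player = sprintf("Player%d", i))
    for (j in seq_along(orders)) row[[paste0("AI", orders[j])]] <- single[j]
    row$single_model_avg <- mean(single)
    row$multi10_score <- multi10
    row$multi5_score <- multi5
    row
  })
  num_cols <- setdiff(names(rows), "player")
  mean_row <- dplyr::summarise(rows, player = "MEAN",
                               dplyr::across(dplyr::all_of(num_cols), mean))
  sd_row <- dplyr::summarise(
    rows, player = "STDEVA",
    dplyr::across(dplyr::all_of(num_cols),
                  ~ if (dplyr::n() > 1) stats::sd(.x) else NA_real_)
  )
  dplyr::bind_rows(rows, mean_row, sd_row)
}

#' Write a summary table as delimited text
#'
#' @param table A tibble (e.g. from [preference_table()],
#'   [model_score_table()] or [transition_table()]).
#' @param path Output path; tab-separated.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}
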