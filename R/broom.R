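#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for match, population and replay objects
#'
#' `tidy()` returns the per-unit records (rounds of a match, matches of a
#' population run, columns of a replay report, cells of a transition-count
#' table); `glance()` a one-row summary.
#'
#' @param x A `rps_match`, `rps_population`, `rps_replay` or `rps_counts`.
#' @param ... Unused.
#' @return A tibble.
#' @name rps_tidiers
NULL

#' @rdname rps_tidiers
#' @export
tidy.rps_match <- function(x, ...) x$history

#' @rdname rps_tidiers
#' @export
glance.rps_match <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    rounds = s$rounds,
    ai_wins = s$ai_wins, draws = s$draws, ai_losses = s$ai_losses,
    ai_score = s$ai_score,
    player_virtual_points = s$player_virtual_points,
    player_reward = s$player_reward,
    pref_R = s$preference_counts[["R"]],
    pref_P = s$preference_counts[["P"]],
    pref_S = s$preference_counts[["S"]]
  )
}

#' @rdname rps_tidiers
#' @export
tidy.rps_population <- function(x, ...) x$summaries

#' @rdname rps_tidiers
#' @export
glance.rps_population <- function(x, ...) {
  tibble::tibble(
    n_matches = nrow(x$summaries),
    rounds = x$config$rounds,
    mean_score = x$mean_score,
    sd_score = x$sd_score,
    single_match = x$single_match,
    fraction_won = x$fraction_won
  )
}

#' @rdname rps_tidiers
#' @export
tidy.rps_replay <- function(x, ...) x$per_column

#' @rdname rps_tidiers
#' @export
glance.rps_replay <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    rounds = x$rounds,
    n_columns_checked = nrow(x$per_column),
    n_mismatch = sum(x$per_column$n_mismatch),
    counts_ok = x$counts_ok,
    all_pass = all_pass(x)
  )
}

#' @rdname rps_tidiers
#' @export
tidy.rps_counts <- function(x, ...) {
  contexts <- ls(x$counts)
  if (length(contexts) == 0) {
    return(tibble::tibble(context = character(0), next_move = character(0),
                          count = integer(0)))
  }
  purrr::map_dfr(sort(contexts), function(ctx) {
    tibble::tibble(context = ctx, next_move = rps_moves(),
                   count = as.integer(x$counts[[ctx]][rps_moves()]))
  })
}

#' @rdname rps_tidiers
#' @export
glance.rps_counts <- function(x, ...) {
  tibble::tibble(m = x$m, n_obs = x$n_obs, total_counts = total_counts(x),
                 n_contexts_seen = length(ls(x$counts)))
}
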