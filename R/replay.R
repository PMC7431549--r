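#' Replay a match log and verify its internal consistency
#'
#' Re-feeds the logged human moves through a fresh ensemble and recomputes
#' everything that is recomputable, comparing against the logged columns.
#' Two modes:
#'
#' * **Seeded** (`master_seed` known, from the log header or the arguments):
#'   the whole match is re-simulated with the human moves forced, so every
#'   column — hypothetical moves and scores, dominant order, AI move,
#'   outcome — is compared exactly.
#' * **Unseeded** (`master_seed = NA`): random components cannot be
#'   reproduced bit-for-bit. Deterministically forced member moves (context
#'   seen, unique argmax) are still checked exactly; rounds where a member's
#'   move was a random draw are checked distributionally (each move's
#'   frequency within 3 binomial standard deviations of uniform). Dominant
#'   orders are recomputed from the logged hypothetical scores, hypothetical
#'   scores from the logged moves, and outcomes from the move pair.
#'
#' In both modes the transition-count conservation law (total counts =
#' `max(0, rounds - m)` for every member) is asserted.
#'
#' @param log A match-log file path (see [write_match_log()]) or a history
#'   tibble with at least a `human_move` column.
#' @param orders,focus Ensemble configuration; defaults come from the log
#'   header when replaying a file.
#' @param master_seed Master seed for seeded replay; `NA` forces unseeded
#'   mode. Defaults to the header value if present.
#' @param col_map Optional named character vector adapting a foreign tabular
#'   log, e.g. `c(human_move = "player_choice", ai_move = "robot")`: names
#'   are the standard column names, values the columns in `log`.
#' @return An object of class `rps_replay`: a list with `mode`
#'   (`"seeded"`/`"unseeded"`), `per_column` (tibble: `column`, `n_checked`,
#'   `n_mismatch`), `mismatches` (tibble: `t`, `column`, `expected`,
#'   `found`), `random_move_check` (unseeded mode: per-member uniformity of
#'   random draws) and `counts_ok`. `all_pass(report)` is `TRUE` when
#'   nothing mismatched.
#' @export
replay <- function(log, orders = NULL, focus = NULL, master_seed = NULL,
                   col_map = NULL) {
  if (is.character(log) && length(log) == 1) {
    parsed <- read_match_log(log)
    history <- parsed$history
    cfg <- parsed$config
  } else if (is.data.frame(log)) {
    history <- tibble::as_tibble(log)
    cfg <- list()
  } else {
    rlang::abort("`log` must be a file path or a data frame.")
  }
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (!col_map[[std]] %in% names(history)) {
        rlang::abort(sprintf("column `%s` not found in log.", col_map[[std]]))
      }
      names(history)[names(history) == col_map[[std]]] <- std
    }
  }
  if (!"human_move" %in% names(history)) {
    rlang::abort("log must contain a `human_move` column (see `col_map`).")
  }
  check_moves(history$human_move, "human_move")
  orders <- orders %||% cfg$orders %||% infer_orders(history) %||% 1:5
  focus <- focus %||% cfg$focus %||% 5
  if (is.null(master_seed)) master_seed <- cfg$master_seed %||% NA
  seeded <- !is.na(master_seed)
  rounds <- nrow(history)

  if (seeded) {
    rep_hist <- forced_replay(history$human_move, orders, focus, master_seed,
                              isTRUE(cfg$sample_prediction))
    comparable <- intersect(names(rep_hist), names(history))
    comparable <- setdiff(comparable, c("t", "human_move"))
    res <- compare_columns(history, rep_hist, comparable)
    random_check <- NULL
  } else {
    out <- unseeded_replay(history, orders, focus)
    res <- out$res
    random_check <- out$random_check
  }
  counts_ok <- verify_count_conservation(history$human_move, orders)
  structure(list(
    mode = if (seeded) "seeded" else "unseeded",
    per_column = res$per_column,
    mismatches = res$mismatches,
    random_move_check = random_check,
    counts_ok = counts_ok,
    rounds = rounds,
    orders = sort(as.integer(orders)), focus = focus
  ), class = "rps_replay")
}

#' @rdname replay
#' @param report A `rps_replay`.
#' @export
all_pass <- function(report) {
  stopifnot(inherits(report, "rps_replay"))
  ok <- sum(report$per_column$n_mismatch) == 0 && report$counts_ok
  if (!is.null(report$random_move_check) &&
      nrow(report$random_move_check) > 0) {
    ok <- ok && all(report$random_move_check$pass)
  }
  ok
}

#' @export
print.rps_replay <- function(x, ...) {
  cat(sprintf("<rps_replay> %s replay of %d rounds (orders %s, focus %d): %s\n",
              x$mode, x$rounds, paste(x$orders, collapse = ","), x$focus,
              if (all_pass(x)) "all checks passed"
              else sprintf("%d mismatches", sum(x$per_column$n_mismatch))))
  invisible(x)
}

infer_orders <- function(history) {
  cols <- grep("^hyp_move_", names(history), value = TRUE)
  if (length(cols) == 0) return(NULL)
  sort(as.integer(sub("^hyp_move_", "", cols)))
}

# Re-simulate with the human moves forced; returns a standard history tibble.
forced_replay <- function(human_moves, orders, focus, master_seed,
                          sample_prediction = FALSE) {
  ens <- multi_ai(orders, focus, master_seed, sample_prediction)
  rounds <- length(human_moves)
  ai_moves <- character(rounds)
  dominant <- integer(rounds)
  for (t in seq_len(rounds)) {
    mv <- ensemble_move(ens)
    ensemble_update(ens, human_moves[t], record = FALSE)
    ai_moves[t] <- mv$ai_move
    dominant[t] <- mv$dominant_order
  }
  assemble_history(ens, ai_moves, human_moves, dominant, rounds)
}

empty_per_column <- function() {
  tibble::tibble(column = character(0), n_checked = integer(0),
                 n_mismatch = integer(0))
}

compare_columns <- function(found, expected, columns) {
  if (length(columns) == 0) {
    return(list(per_column = empty_per_column(),
                mismatches = tibble::tibble(t = integer(0),
                                            column = character(0),
                                            expected = character(0),
                                            found = character(0))))
  }
  mism <- list()
  per_col <- purrr::map_dfr(columns, function(cc) {
    bad <- which(found[[cc]] != expected[[cc]])
    if (length(bad) > 0) {
      mism[[cc]] <<- tibble::tibble(
        t = found$t[bad], column = cc,
        expected = as.character(expected[[cc]][bad]),
        found = as.character(found[[cc]][bad])
      )
    }
    tibble::tibble(column = cc, n_checked = nrow(found),
                   n_mismatch = length(bad))
  })
  list(per_column = per_col,
       mismatches = if (length(mism)) dplyr::bind_rows(mism)
                    else tibble::tibble(t = integer(0), column = character(0),
                                        expected = character(0),
                                        found = character(0)))
}

# Unseeded verification: deterministic member moves exactly, random ones
# distributionally; scores, dominant order, ai_move and outcome recomputed
# from the logged values they must be consistent with.
unseeded_replay <- function(history, orders, focus) {
  orders <- sort(as.integer(orders))
  rounds <- nrow(history)
  human <- history$human_move
  models <- lapply(orders, transition_counts)
  have_moves <- paste0("hyp_move_", orders) %in% names(history)
  names(have_moves) <- as.character(orders)
  expected <- tibble::tibble(t = seq_len(rounds))
  det_flag <- matrix(FALSE, rounds, length(orders),
                     dimnames = list(NULL, as.character(orders)))
  det_move <- matrix(NA_character_, rounds, length(orders),
                     dimnames = list(NULL, as.character(orders)))
  for (t in seq_len(rounds)) {
    for (i in seq_along(orders)) {
      mdl <- models[[i]]
      m <- orders[i]
      if (t - 1 >= m) {
        ctx <- paste(human[(t - m):(t - 1)], collapse = "")
        col <- mdl$counts[[ctx]]
        if (!is.null(col) && sum(col) > 0) {
          top <- names(col)[col == max(col)]
          if (length(top) == 1) {
            det_flag[t, i] <- TRUE
            det_move[t, i] <- counter_move(top)
          }
        }
      }
      observe(mdl, human[t])
    }
  }
  per_col <- list()
  mismatches <- list()
  random_check <- list()
  for (i in seq_along(orders)) {
    ord <- as.character(orders[i])
    mv_col <- paste0("hyp_move_", ord)
    if (!mv_col %in% names(history)) next
    logged <- history[[mv_col]]
    det <- det_flag[, i]
    bad <- which(det & logged != det_move[, i])
    per_col[[mv_col]] <- tibble::tibble(
      column = mv_col, n_checked = sum(det), n_mismatch = length(bad)
    )
    if (length(bad) > 0) {
      mismatches[[mv_col]] <- tibble::tibble(
        t = bad, column = mv_col, expected = det_move[bad, i],
        found = logged[bad]
      )
    }
    rand_moves <- logged[!det]
    n <- length(rand_moves)
    if (n > 0) {
      freq <- vapply(rps_moves(), function(mv) sum(rand_moves == mv),
                     numeric(1))
      sigma <- sqrt(n * (1 / 3) * (2 / 3))
      max_dev <- max(abs(freq - n / 3))
      random_check[[ord]] <- tibble::tibble(
        order = orders[i], n_random = n,
        max_dev_sigma = if (sigma > 0) max_dev / sigma else 0,
        pass = max_dev <= 3 * sigma + 1 # +1: integer slack at tiny n
      )
    }
  }
  # recomputable columns from logged values
  recompute <- tibble::tibble(t = seq_len(rounds))
  score_cols <- paste0("hyp_score_", orders)
  move_cols <- paste0("hyp_move_", orders)
  if (all(move_cols %in% names(history))) {
    for (i in seq_along(orders)) {
      recompute[[score_cols[i]]] <- competitive_score(
        round_outcome(history[[move_cols[i]]], human)
      )
    }
    if (all(score_cols %in% names(history))) {
      smat <- as.matrix(history[score_cols])
      colnames(smat) <- as.character(orders)
      recompute$dominant_order <- vapply(seq_len(rounds), function(t) {
        select_dominant(windowed_scores(smat, t, focus), orders)
      }, integer(1))
      if ("dominant_order" %in% names(history)) {
        dom <- if ("dominant_order" %in% names(recompute)) {
          recompute$dominant_order
        } else history$dominant_order
        recompute$ai_move <- vapply(seq_len(rounds), function(t) {
          history[[paste0("hyp_move_", dom[t])]][t]
        }, character(1))
      }
    }
  }
  if ("ai_move" %in% names(history)) {
    recompute$outcome <- round_outcome(history$ai_move, human)
  }
  cols <- setdiff(intersect(names(recompute), names(history)), "t")
  res2 <- compare_columns(history, recompute, cols)
  per_column <- dplyr::bind_rows(dplyr::bind_rows(per_col), res2$per_column)
  mism <- dplyr::bind_rows(dplyr::bind_rows(mismatches), res2$mismatches)
  list(
    res = list(per_column = per_column, mismatches = mism),
    random_check = if (length(random_check)) dplyr::bind_rows(random_check)
                   else tibble::tibble(order = integer(0), n_random = integer(0),
                                       max_dev_sigma = numeric(0),
                                       pass = logical(0))
  )
}

verify_count_conservation <- function(human_moves, orders) {
  all(vapply(orders, function(m) {
    tc <- transition_counts(m)
    observe(tc, human_moves)
    total_counts(tc) == max(0L, length(human_moves) - m)
  }, logical(1)))
}
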