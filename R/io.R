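#' Write and read match logs
#'
#' Match logs are plain tab-delimited text: a commented provenance header
#' (`# key: value` lines carrying the package version, ensemble
#' configuration, seeds, opponent and a config hash — enough to reproduce
#' the match bit-for-bit) followed by one row per round in the standard
#' history layout of [run_match()].
#'
#' @param match A `rps_match` (or a history tibble plus a `config` list).
#' @param path File path to write to / read from.
#' @return `write_match_log()`: `path`, invisibly. `read_match_log()`: a
#'   list with `history` (tibble) and `config` (named list from the
#'   header).
#' @export
write_match_log <- function(match, path) {
  if (inherits(match, "rps_match")) {
    history <- match$history
    config <- match$config
  } else {
    history <- match$history
    config <- match$config %||% list()
  }
  header <- c(
    "# rpsmarkov match log v1",
    sprintf("# version: %s", as.character(utils::packageVersion("rpsmarkov"))),
    sprintf("# orders: %s", paste(config$orders, collapse = ",")),
    sprintf("# focus: %s", config$focus),
    sprintf("# rounds: %s", config$rounds),
    sprintf("# a: %s", config$a),
    sprintf("# master_seed: %s", config$master_seed),
    sprintf("# opponent: %s", config$opponent),
    sprintf("# opponent_seed: %s", config$opponent_seed),
    sprintf("# sample_prediction: %s", isTRUE(config$sample_prediction)),
    sprintf("# config_hash: %s", rlang::hash(config))
  )
  writeLines(header, path)
  readr::write_tsv(history, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_match_log
#' @export
read_match_log <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("no such file: %s", path))
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  config <- parse_log_header(header)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    rlang::abort(sprintf("malformed log %s: no column header row.", path))
  }
  history <- tryCatch(
    readr::read_tsv(I(paste(body, collapse = "\n")),
                    col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE),
    error = function(e) rlang::abort(sprintf("cannot parse log %s: %s",
                                             path, conditionMessage(e)))
  )
  expected_cols <- c("t", "human_move")
  missing <- setdiff(expected_cols, names(history))
  if (length(missing) > 0) {
    rlang::abort(sprintf("malformed log %s (line %d): missing column(s) %s.",
                         path, length(header) + 1L,
                         paste(missing, collapse = ", ")))
  }
  int_cols <- c("t", "dominant_order", "cum_score",
                grep("^hyp_score_", names(history), value = TRUE))
  for (cc in intersect(int_cols, names(history))) {
    parsed <- suppressWarnings(as.integer(history[[cc]]))
    if (anyNA(parsed) && !anyNA(history[[cc]])) {
      bad <- which(is.na(parsed))[1]
      rlang::abort(sprintf(
        "malformed log %s (data row %d): column `%s` is not integer.",
        path, bad, cc
      ))
    }
    history[[cc]] <- parsed
  }
  move_cols <- intersect(c("human_move", "ai_move",
                           grep("^hyp_move_", names(history), value = TRUE)),
                         names(history))
  for (cc in move_cols) {
    bad <- which(!history[[cc]] %in% rps_moves())
    if (length(bad) > 0) {
      rlang::abort(sprintf(
        "malformed log %s (data row %d): invalid move %s in column `%s`.",
        path, bad[1], dQuote(history[[cc]][bad[1]]), cc
      ))
    }
  }
  list(history = history, config = config)
}

parse_log_header <- function(header) {
  kv <- regmatches(header, regexec("^#\\s*([A-Za-z_]+):\\s*(.*)$", header))
  config <- list()
  for (entry in kv) {
    if (length(entry) != 3) next
    key <- entry[2]
    val <- trimws(entry[3])
    config[[key]] <- switch(key,
      orders = as.integer(strsplit(val, ",")[[1]]),
      focus = , rounds = , master_seed = , opponent_seed =
        if (val %in% c("NA", "")) NA_integer_ else as.integer(val),
      a = as.numeric(val),
      sample_prediction = identical(val, "TRUE"),
      val
    )
  }
  config
}

#' Run configurations
#'
#' A run configuration bundles everything needed to reproduce a simulated
#' session: member orders, focus length, number of rounds, payoff parameter,
#' master seed, the opponent, and output paths. `run_config()` validates;
#' the YAML read/write pair round-trips field-for-field.
#'
#' @param orders Distinct positive integer member orders.
#' @param focus Focus length, >= 1.
#' @param rounds Number of rounds, >= 0.
#' @param a Payoff parameter, > 0.
#' @param master_seed Integer master seed.
#' @param opponent A `rps_strategy`, or the string `"interactive"` for live
#'   play.
#' @param out Optional output path for the match log.
#' @param config A run configuration list.
#' @param path File path.
#' @return `run_config()` and `read_run_config()`: a validated list of class
#'   `rps_run_config`.
#' @export
run_config <- function(orders = 1:5, focus = 5, rounds = 300, a = 2,
                       master_seed = 0, opponent = opp_uniform(),
                       out = NULL) {
  orders <- as.integer(orders)
  if (length(orders) == 0 || any(orders < 1) || anyDuplicated(orders)) {
    rlang::abort("invalid config field `orders`: need distinct positive integers.")
  }
  if (!is.numeric(focus) || length(focus) != 1 || focus < 1) {
    rlang::abort("invalid config field `focus`: need a single value >= 1.")
  }
  if (!is.numeric(rounds) || length(rounds) != 1 || rounds < 0) {
    rlang::abort("invalid config field `rounds`: need a single value >= 0.")
  }
  if (!is.numeric(a) || length(a) != 1 || a <= 0) {
    rlang::abort("invalid config field `a`: need a single positive value.")
  }
  if (!inherits(opponent, "rps_strategy") && !identical(opponent, "interactive")) {
    rlang::abort("invalid config field `opponent`: need a rps_strategy or \"interactive\".")
  }
  structure(list(
    orders = sort(orders), focus = as.integer(focus),
    rounds = as.integer(rounds), a = a, master_seed = as.integer(master_seed),
    opponent = opponent, out = out
  ), class = "rps_run_config")
}

#' @rdname run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "rps_run_config"))
  ser <- list(
    orders = config$orders, focus = config$focus, rounds = config$rounds,
    a = config$a, master_seed = config$master_seed,
    opponent = if (identical(config$opponent, "interactive")) "interactive"
               else strategy_to_config(config$opponent),
    out = config$out
  )
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  ser <- yaml::read_yaml(path)
  opponent <- if (identical(ser$opponent, "interactive")) "interactive"
              else strategy_from_config(ser$opponent)
  run_config(orders = ser$orders, focus = ser$focus, rounds = ser$rounds,
             a = ser$a, master_seed = ser$master_seed, opponent = opponent,
             out = ser$out)
}

#' Serialise opponent strategies and population specs
#'
#' Strategies serialise to plain lists (`type` + `parameters`, nested for
#' switching schedules) and population specifications to YAML files with one
#' entry per strategy (`type`, `parameters`, `count`, `seed_base`). Both
#' round-trip: reading back a written spec yields instances emitting
#' identical move sequences.
#'
#' @param strategy A `rps_strategy`.
#' @param config A serialised strategy list.
#' @param spec A population spec: list of
#'   `list(strategy = <rps_strategy>, count, seed_base)` entries.
#' @param path File path.
#' @return `strategy_to_config()`: a plain list. `strategy_from_config()`:
#'   a `rps_strategy`. `read_population_spec()`: a population spec list
#'   ready for [generate_population()].
#' @export
strategy_to_config <- function(strategy) {
  stopifnot(inherits(strategy, "rps_strategy"))
  params <- switch(strategy$type,
    uniform = , wsls = , counter_own_last = list(),
    biased = list(prob = as.numeric(strategy$params$prob)),
    constant = list(move = strategy$params$move),
    cycle = list(sequence = paste(strategy$params$sequence, collapse = "")),
    markov_gen = list(
      k = strategy$params$k,
      trans = apply(strategy$params$trans, 1L, as.numeric, simplify = FALSE)
    ),
    switching = list(schedule = lapply(strategy$params$schedule, function(e) {
      list(strategy = strategy_to_config(e$strategy),
           rounds = as.integer(e$rounds))
    })),
    rlang::abort(sprintf("cannot serialise strategy type %s.", strategy$type))
  )
  list(type = strategy$type, parameters = params)
}

#' @rdname strategy_to_config
#' @export
strategy_from_config <- function(config) {
  p <- config$parameters %||% list()
  switch(config$type,
    uniform = opp_uniform(),
    wsls = opp_wsls(),
    counter_own_last = opp_counter_own_last(),
    biased = opp_biased(p$prob),
    constant = opp_constant(p$move),
    cycle = opp_cycle(p$sequence),
    markov_gen = opp_markov(p$k, do.call(rbind, p$trans)),
    switching = opp_switching(lapply(p$schedule, function(e) {
      list(strategy = strategy_from_config(e$strategy), rounds = e$rounds)
    })),
    rlang::abort(sprintf("unknown strategy type %s.", config$type))
  )
}

#' @rdname strategy_to_config
#' @export
write_population_spec <- function(spec, path) {
  ser <- lapply(spec, function(entry) {
    c(strategy_to_config(entry$strategy),
      list(count = as.integer(entry$count %||% 1L),
           seed_base = as.integer(entry$seed_base)))
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname strategy_to_config
#' @export
read_population_spec <- function(path) {
  ser <- yaml::read_yaml(path)
  lapply(ser, function(entry) {
    list(strategy = strategy_from_config(entry),
         count = entry$count %||% 1L,
         seed_base = entry$seed_base)
  })
}
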