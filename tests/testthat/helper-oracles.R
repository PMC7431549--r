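# Independent oracles used across the suite. These deliberately avoid the
# package's own counting/windowing code paths.

# Brute-force (context, next) pair counting by direct enumeration.
oracle_counts <- function(history, m) {
  out <- list()
  n <- length(history)
  if (n <= m) return(out)
  for (i in (m + 1):n) {
    ctx <- paste(history[(i - m):(i - 1)], collapse = "")
    nxt <- history[i]
    if (is.null(out[[ctx]])) out[[ctx]] <- c(R = 0L, P = 0L, S = 0L)
    out[[ctx]][[nxt]] <- out[[ctx]][[nxt]] + 1L
  }
  out[order(names(out))]
}

# Counts from a rps_counts object in the same plain-list shape.
counts_as_list <- function(tc) {
  keys <- sort(ls(tc$counts))
  out <- list()
  for (k in keys) {
    col <- tc$counts[[k]][c("R", "P", "S")]
    if (sum(col) > 0) out[[k]] <- col
  }
  out
}

# Brute-force windowed totals: re-sum the stored per-round scores directly.
oracle_windowed <- function(score_mat, t, focus) {
  lo <- max(1, t - focus)
  hi <- t - 1
  if (hi < lo) return(setNames(rep(0, ncol(score_mat)), colnames(score_mat)))
  sapply(seq_len(ncol(score_mat)), function(j) sum(score_mat[lo:hi, j])) |>
    setNames(colnames(score_mat))
}

# Brute-force max scan with lowest-order tie-break.
oracle_dominant <- function(totals, orders) {
  best <- -Inf
  who <- NA_integer_
  for (i in seq_along(totals)) {
    if (totals[i] > best) {
      best <- totals[i]
      who <- orders[i]
    }
  }
  who
}

# Drive an opponent instance for n rounds against a fixed dummy AI move.
gen_opponent_moves <- function(inst, n, ai_move = "R") {
  own <- character(n)
  ai <- rep(ai_move, n)
  for (t in seq_len(n)) {
    past <- seq_len(t - 1)
    own[t] <- inst$fn(inst, own[past], ai[past])
  }
  own
}

# All move histories of a given length, as a matrix of move characters.
all_histories <- function(len) {
  if (len == 0) return(matrix(character(0), nrow = 1, ncol = 0))
  grid <- expand.grid(rep(list(c("R", "P", "S")), len),
                      stringsAsFactors = FALSE)
  as.matrix(grid)
}
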