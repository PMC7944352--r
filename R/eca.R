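#' Elementary cellular automata
#'
#' One-dimensional binary automata in the Wolfram numbering: the update of a
#' cell depends on its left neighbour, itself and its right neighbour, and
#' the new state for neighbourhood `(l, c, r)` is bit `4l + 2c + r` of the
#' rule number.  The boundary is cyclic, which preserves shift equivariance.
#'
#' @param rule integer rule number in 0..255.
#' @return `eca_rule_table()` returns the 8 output bits of the rule, indexed
#'   by neighbourhood value 0..7.
#' @export
eca_rule_table <- function(rule) {
  rule <- as.integer(rule)
  stopifnot(length(rule) == 1L, rule >= 0L, rule <= 255L)
  as.integer(bitwAnd(bitwShiftR(rule, 0:7), 1L))
}

#' @rdname eca_rule_table
#' @param state integer 0/1 vector (or bit string) of length at least 3.
#' @export
eca_step <- function(state, rule) {
  s <- as_bits(state)
  n <- length(s)
  if (n < 3L) stop("state must have length >= 3")
  tab <- eca_rule_table(rule)
  l <- s[c(n, seq_len(n - 1L))]
  r <- s[c(seq_len(n - 1L) + 1L, 1L)]
  tab[4L * l + 2L * s + r + 1L]
}

#' Evolve an elementary cellular automaton
#'
#' @param init initial state, an integer 0/1 vector or bit string.
#' @param rule integer rule number in 0..255.
#' @param steps number of synchronous updates (>= 0).
#' @param include_init if `TRUE` (default) the first row of the returned
#'   matrix is the initial state, giving `steps + 1` rows; otherwise the
#'   initial row is dropped and the matrix has `steps` rows.
#' @return a 0/1 matrix, one row per recorded time step (earliest first).
#' @examples
#' eca_evolve("000100", 90, 1, include_init = FALSE)
#' @export
eca_evolve <- function(init, rule, steps, include_init = TRUE) {
  s <- as_bits(init)
  steps <- as.integer(steps)
  stopifnot(steps >= 0L)
  rows <- vector("list", steps + 1L)
  rows[[1L]] <- s
  for (t in seq_len(steps)) rows[[t + 1L]] <- eca_step(rows[[t]], rule)
  m <- do.call(rbind, rows)
  if (!include_init) m <- m[-1L, , drop = FALSE]
  m
}

# Vectorized step over many states at once: S is an m x w 0/1 matrix, one
# state per row.  Used by the table builders, where half a million
# evolutions are needed.
eca_step_matrix <- function(S, tab) {
  w <- ncol(S)
  L <- S[, c(w, seq_len(w - 1L)), drop = FALSE]
  R <- S[, c(seq_len(w - 1L) + 1L, 1L), drop = FALSE]
  idx <- 4L * L + 2L * S + R
  matrix(tab[idx + 1L], nrow = nrow(S))
}

# Evolve every row of S0 for `steps` steps under one rule; returns the
# m x (w * steps) matrix of the evolutions with the initial row removed,
# each row laid out row-major in time.
eca_evolve_matrix <- function(S0, rule, steps) {
  tab <- eca_rule_table(rule)
  S <- S0
  out <- vector("list", steps)
  for (t in seq_len(steps)) {
    S <- eca_step_matrix(S, tab)
    out[[t]] <- S
  }
  do.call(cbind, out)
}
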