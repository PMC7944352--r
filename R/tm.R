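#' Build a base CTM table by enumerating small Turing machines
#'
#' Exhaustively runs every `n`-state, 2-symbol Turing machine in the
#' Busy-Beaver-style formalism (each of the `2n` (state, symbol) slots takes
#' one of `4n + 2` instructions: write/move/next-state, or write-and-halt),
#' for a space of `(4n + 2)^(2n)` machines.  Machines start on a blank
#' (all-zero) tape; a machine that halts within `max_steps` contributes the
#' tape segment it visited as its output string.  The CTM value of an
#' output `x` is `-log2` of the fraction of halting machines producing it,
#' so shorter, simpler strings receive lower complexity - a small-machine
#' analogue of the published large-scale enumerations.
#'
#' @param states number of states `n` (at most 3; the n = 3 space has
#'   7,529,536 machines and takes correspondingly long).
#' @param max_steps step budget per machine (>= 1).
#' @return a [ctm_table()] over variable-length bit-string keys, with the
#'   enumeration parameters in `meta`.
#' @export
build_base_ctm_by_tm_enumeration <- function(states, max_steps = 100L) {
  n <- as.integer(states)
  if (n > 3L) stop("space too large; supply external table")
  stopifnot(n >= 1L, max_steps >= 1L)
  n_instr <- 4L * n + 2L
  n_slots <- 2L * n
  total <- n_instr^n_slots

  # Decode instruction codes 1..4n+2 once:
  # 1..4n: write in {0,1}, move in {-1,+1}, next state in 1..n
  # 4n+1, 4n+2: write 0 / write 1, then halt (state 0).
  code <- seq_len(n_instr)
  wr <- integer(n_instr); mv <- integer(n_instr); nx <- integer(n_instr)
  for (c0 in seq_len(4L * n)) {
    z <- c0 - 1L
    wr[c0] <- z %% 2L
    mv[c0] <- if ((z %/% 2L) %% 2L == 0L) -1L else 1L
    nx[c0] <- z %/% 4L + 1L
  }
  wr[4L * n + 1L] <- 0L; wr[4L * n + 2L] <- 1L
  nx[4L * n + 1L] <- 0L; nx[4L * n + 2L] <- 0L

  counts <- new.env(parent = emptyenv())
  halting <- 0L
  slots <- rep(1L, n_slots)  # odometer over instruction codes per slot
  tape_len <- 2L * max_steps + 3L
  origin <- max_steps + 2L
  for (m in seq_len(total)) {
    # slot index for (state q, symbol s): 2 * (q - 1) + s + 1
    tape <- integer(tape_len)
    pos <- origin; q <- 1L
    lo <- pos; hi <- pos
    steps <- 0L
    while (q > 0L && steps < max_steps) {
      c0 <- slots[2L * (q - 1L) + tape[pos] + 1L]
      tape[pos] <- wr[c0]
      q <- nx[c0]
      if (q > 0L) {
        pos <- pos + mv[c0]
        if (pos < lo) lo <- pos
        if (pos > hi) hi <- pos
      }
      steps <- steps + 1L
    }
    if (q == 0L) {
      halting <- halting + 1L
      key <- paste(tape[lo:hi], collapse = "")
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
    # advance odometer
    for (s in seq_len(n_slots)) {
      slots[s] <- slots[s] + 1L
      if (slots[s] <= n_instr) break
      slots[s] <- 1L
    }
  }
  keys <- ls(counts)
  vals <- vapply(keys, function(k) counts[[k]], integer(1))
  entries <- -log2(vals / halting)
  names(entries) <- keys
  ctm_table(entries, shape = NA_integer_,
            source = sprintf("enumeration of %d-state 2-symbol Turing machines",
                             n),
            meta = list(states = n, max_steps = as.integer(max_steps),
                        machines = total, halting = halting))
}
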