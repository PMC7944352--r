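#' Boolean NK (Kauffman) networks
#'
#' An NK network has `n` nodes, each driven by an unordered set of `k`
#' distinct source nodes (a node may drive itself) through a k-ary Boolean
#' function given as a truth table of `2^k` bits.  Updates are synchronous.
#' Truth tables are indexed with input bits most significant first: for a
#' node with inputs `(i, j)` and state `s`, the next bit is
#' `tt[2 * s[i] + s[j] + 1]`.
#'
#' @param inputs list of length `n`; element `i` is the integer vector of
#'   the `k` (distinct) source nodes of node `i`.
#' @param functions list of length `n`; element `i` is either a truth-table
#'   0/1 vector of length `2^k` or one of the named Boolean functions
#'   `"And"`, `"Or"`, `"Nand"`, `"XOr"` (k = 2 only).
#' @return an object of class `nk_network`.
#' @export
nk_network <- function(inputs, functions) {
  n <- length(inputs)
  stopifnot(n >= 1L, length(functions) == n)
  inputs <- lapply(inputs, function(v) {
    v <- as.integer(v)
    if (anyDuplicated(v)) stop("input nodes must be distinct")
    if (any(v < 1L) || any(v > n)) stop("input node index out of range")
    sort(v)
  })
  k <- length(inputs[[1L]])
  if (!all(vapply(inputs, length, integer(1)) == k)) {
    stop("every node must have exactly k inputs")
  }
  functions <- lapply(functions, function(f) {
    if (is.character(f)) f <- boolean_function_pool(k)[[f]]
    f <- as_bits(f)
    if (length(f) != 2^k) stop("truth-table arity does not match k")
    f
  })
  structure(list(n = n, k = k, inputs = inputs, functions = functions),
            class = "nk_network")
}

#' @rdname nk_network
#' @param k input degree; the default pool is the four symmetric binary
#'   connectives used by the rule-list classifiers (`k = 2`), and all
#'   `2^(2^k)` k-ary functions otherwise.
#' @export
boolean_function_pool <- function(k = 2L) {
  if (k == 2L) {
    # truth-table order: inputs (a, b) at index 2a + b + 1
    return(list(And = c(0L, 0L, 0L, 1L), Or = c(0L, 1L, 1L, 1L),
                Nand = c(1L, 1L, 1L, 0L), XOr = c(0L, 1L, 1L, 0L)))
  }
  nf <- 2^(2^k)
  stats::setNames(lapply(seq_len(nf) - 1L, int_to_bits, width = 2^k),
                  sprintf("f%d", seq_len(nf) - 1L))
}

#' @export
print.nk_network <- function(x, ...) {
  cat("NK network: n =", x$n, ", k =", x$k, "\n")
  invisible(x)
}

#' Evolve an NK network synchronously
#'
#' @param net an [nk_network()].
#' @param init initial state, a 0/1 vector of length `n`.
#' @param recorded_rows number of rows recorded, the initial state
#'   included; 10 recorded rows give the 40-bit (n = 4) and 240-bit
#'   (n = 24) evolution vectors used by the classifiers.
#' @return a `recorded_rows` x `n` 0/1 matrix, row 1 the initial state.
#' @export
nk_evolve <- function(net, init, recorded_rows) {
  s <- as_bits(init)
  if (length(s) != net$n) stop("initial state length must equal n")
  stopifnot(recorded_rows >= 1L)
  pw <- 2^((net$k - 1L):0)
  out <- matrix(0L, recorded_rows, net$n)
  out[1L, ] <- s
  for (t in seq_len(recorded_rows - 1L)) {
    s2 <- integer(net$n)
    for (i in seq_len(net$n)) {
      idx <- sum(s[net$inputs[[i]]] * pw) + 1L
      s2[i] <- net$functions[[i]][idx]
    }
    s <- s2
    out[t + 1L, ] <- s
  }
  out
}

#' Enumerate the full NK network space
#'
#' Every node independently takes one of the `choose(n, k)` input sets
#' (lexicographic order) crossed with one of the pool functions (pool
#' order), giving `(choose(n, k) * length(pool))^n` networks; for n = 4,
#' k = 2 and the four-function pool this is the complete 331,776-network
#' space from which the conditional CTM tables are compiled.  The iterator
#' walks a node-by-node odometer, input-set index major and function index
#' minor, node `n` fastest.
#'
#' @param n,k network size and input degree (`k <= n`).
#' @param pool named list of truth tables (default [boolean_function_pool()]).
#' @return a function that returns the next [nk_network()] on each call and
#'   `NULL` when exhausted, with the space size in attribute `"count"`.
#' @export
enumerate_nk_space <- function(n, k, pool = boolean_function_pool(k)) {
  if (k > n) stop("k must not exceed n")
  stopifnot(length(pool) >= 1L)
  sets <- input_set_matrix(n, k)
  nch <- nrow(sets) * length(pool)
  count <- nch^n
  state <- rep(1L, n)  # choice index per node
  done <- FALSE
  it <- function() {
    if (done) return(NULL)
    inputs <- lapply(state, function(c0) sets[(c0 - 1L) %/% length(pool) + 1L, ])
    funs <- lapply(state, function(c0) pool[[(c0 - 1L) %% length(pool) + 1L]])
    net <- nk_network(inputs, funs)
    for (i in n:1) {
      state[i] <<- state[i] + 1L
      if (state[i] <= nch) break
      state[i] <<- 1L
      if (i == 1L) done <<- TRUE
    }
    net
  }
  attr(it, "count") <- count
  it
}

# All k-subsets of 1..n, lexicographic, one per row.
input_set_matrix <- function(n, k) {
  m <- t(utils::combn(n, k))
  storage.mode(m) <- "integer"
  m
}

#' Draw a random NK network
#'
#' Input sets and functions are uniform over the admissible space; when
#' `required` names a pool function, draws are rejected until at least one
#' node carries it (uniform over the constrained space).
#'
#' @inheritParams enumerate_nk_space
#' @param required optional name of a pool function that must appear in at
#'   least one node.
#' @return an [nk_network()].
#' @export
random_nk <- function(n, k, pool = boolean_function_pool(k), required = NULL) {
  if (!is.null(required) && !(required %in% names(pool))) {
    stop("required function is not in the pool")
  }
  if (!is.null(required) && length(pool) == 0L) stop("impossible constraint")
  sets <- input_set_matrix(n, k)
  repeat {
    si <- sample.int(nrow(sets), n, replace = TRUE)
    fi <- sample.int(length(pool), n, replace = TRUE)
    if (is.null(required) || any(names(pool)[fi] == required)) break
  }
  nk_network(lapply(si, function(i) sets[i, ]), pool[fi])
}

# ---- vectorized full-space evolution (internal) ------------------------
#
# For n <= 4 the global state fits in an integer 0..2^n-1, so the whole
# 331,776-network space evolves in a handful of matrix operations: each of
# the choose(n,k)*|pool| per-node choices is precomputed as a 2^n-vector of
# next bits, and one synchronous step is four indexed lookups.

nk_choice_tables <- function(n, k, pool = boolean_function_pool(k)) {
  sets <- input_set_matrix(n, k)
  nstates <- 2^n
  states <- int_to_bits(0:(nstates - 1L), n)  # nstates x n, node 1 = MSB
  pw <- 2^((k - 1L):0)
  nch <- nrow(sets) * length(pool)
  M <- matrix(0L, nstates, nch)
  for (s in seq_len(nrow(sets))) {
    idx <- as.vector(states[, sets[s, ], drop = FALSE] %*% pw) + 1L
    for (f in seq_along(pool)) {
      M[, (s - 1L) * length(pool) + f] <- pool[[f]][idx]
    }
  }
  M
}

# Evolve many n<=4 networks at once.  choices: m x n matrix of per-node
# choice indices (1..nch); init: integer state index 0..2^n-1 (scalar or
# length m).  Returns m x rows matrix of state indices.
nk_evolve_indices <- function(choices, n, M, rows, init = 0L) {
  m <- nrow(choices)
  cur <- rep_len(as.integer(init), m)
  out <- matrix(0L, m, rows)
  out[, 1L] <- cur
  pw <- 2^((n - 1L):0)
  for (t in seq_len(rows - 1L)) {
    nxt <- integer(m)
    for (i in seq_len(n)) {
      nxt <- nxt + M[cbind(cur + 1L, choices[, i])] * pw[i]
    }
    cur <- nxt
    out[, t + 1L] <- cur
  }
  out
}

# Turn an m x rows matrix of state indices into 40-bit-style key strings.
nk_states_to_keys <- function(stateidx, n) {
  bits <- int_to_bits(0:(2^n - 1L), n)
  keys1 <- rows_to_keys(bits)  # per-state n-bit strings
  do.call(paste0, lapply(seq_len(ncol(stateidx)),
                         function(t) keys1[stateidx[, t] + 1L]))
}

#' Compile the enumerated NK pair relations
#'
#' Runs every network of the (n, k, pool) space from the given initial
#' state for `rows` recorded rows and returns the per-network rule-list
#' key, topology key and flattened evolution key - the raw material for
#' the conditional CTM tables of the rule-list and topology classifiers.
#'
#' @inheritParams enumerate_nk_space
#' @param rows recorded rows (initial state included).
#' @param init initial global state as an integer state index (default 0,
#'   the all-zeros state used by the 40-bit corpora).
#' @return a data.frame with columns `rule_key` (function indices by node),
#'   `topo_key` (input-set indices by node) and `evo_key` (the flattened
#'   evolution bit string).
#' @export
nk_space_table <- function(n = 4L, k = 2L, pool = boolean_function_pool(k),
                           rows = 10L, init = 0L) {
  sets <- input_set_matrix(n, k)
  nch <- nrow(sets) * length(pool)
  if (nch^n > 5e6) stop("space too large to tabulate")
  M <- nk_choice_tables(n, k, pool)
  grid <- as.matrix(rev(expand.grid(rev(lapply(seq_len(n),
                                               function(i) seq_len(nch))))))
  storage.mode(grid) <- "integer"
  colnames(grid) <- NULL
  stateidx <- nk_evolve_indices(grid, n, M, rows, init)
  fidx <- (grid - 1L) %% length(pool) + 1L
  sidx <- (grid - 1L) %/% length(pool) + 1L
  data.frame(rule_key = rows_to_keys(fidx),
             topo_key = rows_to_keys(sidx),
             evo_key = nk_states_to_keys(stateidx, n),
             stringsAsFactors = FALSE)
}
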