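#' Bit-vector utilities
#'
#' Binary objects are represented throughout the package as integer 0/1
#' vectors (most significant bit first) or 0/1 matrices whose first row is
#' the earliest time step.  `as_bits()` accepts either an integer vector or
#' a character string such as `"0101"` and returns the canonical integer
#' form; `bits_to_string()` is the inverse.
#'
#' @param x an integer 0/1 vector or a single character string over
#'   `{"0","1"}`.
#' @return `as_bits()` returns an integer vector of 0s and 1s.
#' @examples
#' as_bits("0101")
#' bits_to_string(c(1L, 0L, 1L))
#' @export
as_bits <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    b <- as.integer(strsplit(x, "", fixed = TRUE)[[1L]])
  } else {
    b <- as.integer(x)
  }
  if (anyNA(b) || (length(b) && !all(b == 0L | b == 1L))) {
    stop("bits must be 0/1")
  }
  b
}

#' @rdname as_bits
#' @param bits an integer 0/1 vector.
#' @export
bits_to_string <- function(bits) paste(as.integer(bits), collapse = "")

#' Fixed-width binary expansion of a nonnegative integer
#'
#' Most significant bit first, so `int_to_bits(704, 12)` gives the 12-bit
#' class string `001011000000`.
#'
#' @param n nonnegative integer (vectorized).
#' @param width number of bits; `n` must be `< 2^width`.
#' @return an integer 0/1 vector (or a matrix with one row per element of
#'   `n` when `length(n) > 1`).
#' @export
int_to_bits <- function(n, width) {
  n <- as.numeric(n)
  if (any(n < 0) || any(n >= 2^width)) stop("integer does not fit in width")
  m <- outer(n, 2^((width - 1L):0), function(a, b) (a %/% b) %% 2)
  storage.mode(m) <- "integer"
  if (length(n) == 1L) m[1L, ] else m
}

#' @rdname int_to_bits
#' @param bits an integer 0/1 vector, most significant bit first.
#' @export
bits_to_int <- function(bits) {
  bits <- as_bits(bits)
  sum(bits * 2^((length(bits) - 1L):0))
}

# Row-major flattening of a time x space matrix into one bit vector.
flatten_rows <- function(m) as.integer(t(m))

# One key string per row of a 0/1 matrix (vectorized paste across columns).
rows_to_keys <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  if (ncol(m) == 0L) return(rep("", nrow(m)))
  do.call(paste0, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

# Key of a whole binary matrix, row-major.
tensor_key <- function(x) {
  if (is.matrix(x)) paste(as.integer(t(x)), collapse = "") else bits_to_string(x)
}
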