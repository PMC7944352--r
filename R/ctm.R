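#' CTM tables
#'
#' A `ctm_table` is a finite map from base-object keys (bit strings,
#' row-major for matrices) to approximated algorithmic-complexity values in
#' bits; it plays the role of the precomputed Coding Theorem Method database
#' that the Block Decomposition Method consumes.
#'
#' @param entries named numeric vector of nonnegative, finite bit values;
#'   names are object keys.
#' @param shape integer vector describing the base-object shape, e.g.
#'   `c(4, 4)` for 4x4 blocks or `8` for 8-bit strings.
#' @param source free-text description of how the table was produced.
#' @param meta optional list of additional metadata (recorded verbatim).
#' @return an object of class `ctm_table`.
#' @export
ctm_table <- function(entries, shape, source = "", meta = list()) {
  stopifnot(is.numeric(entries), !is.null(names(entries)))
  if (any(!is.finite(entries)) || any(entries < 0)) {
    stop("CTM values must be finite and nonnegative")
  }
  entries <- entries[order(names(entries), method = "radix")]
  structure(
    list(entries = entries, shape = as.integer(shape), source = source,
         meta = meta),
    class = "ctm_table"
  )
}

#' @export
print.ctm_table <- function(x, ...) {
  cat("CTM table:", length(x$entries), "objects, shape",
      paste(x$shape, collapse = "x"), "\n")
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' Fallback information value for pairs absent from a conditional CTM table
#'
#' A pair never produced by the enumerated generative space carries more
#' information than any tabulated pair; the penalty `floor(log2(|P|)) + 1`
#' is the smallest integer number of bits strictly above the largest
#' tabulated value `-log2(1/|P|)`.  For the 528,384-pair cellular-automaton
#' relation this gives 20 bits, and 19 bits for the 331,776-network relation.
#'
#' @param pair_count total number of pairs `|P|` in the relation, counted
#'   with repeats.
#' @return integer number of bits.
#' @export
fallback_bits <- function(pair_count) {
  stopifnot(pair_count >= 1)
  as.integer(floor(log2(pair_count)) + 1)
}

# Internal fast constructor from parallel key vectors (one element per pair
# occurrence, repeats included).
new_cond_ctm_table <- function(cond_keys, out_keys, crop = NULL,
                               source = "", meta = list()) {
  stopifnot(length(cond_keys) == length(out_keys), length(cond_keys) > 0L)
  key <- paste(cond_keys, out_keys, sep = "|")
  P <- length(key)
  o <- order(key, method = "radix")
  r <- rle(key[o])
  entries <- -log2(r$lengths / P)
  names(entries) <- r$values
  structure(
    list(entries = entries, pair_count = P,
         fallback_bits = fallback_bits(P),
         crop = crop,
         cond_len = nchar(cond_keys[[1L]]), out_len = nchar(out_keys[[1L]]),
         source = source, meta = meta),
    class = "cond_ctm_table"
  )
}

#' Build a conditional CTM table from an enumerated pair relation
#'
#' Given the multiset of (condition, outcome) pairs produced by exhaustively
#' running a generative space, the conditional CTM value of a pair seen
#' `m` times is `-log2(m / |P|)`, where `|P|` counts pair occurrences with
#' repeats.  Pairs absent from the relation are later charged
#' [fallback_bits()] bits at lookup time.  An optional crop is applied to
#' both members of every pair before keying (used to discard boundary cells
#' of finite-width automata).
#'
#' @param pairs a list of two-element lists `list(condition, outcome)`;
#'   conditions and outcomes may be 0/1 vectors, bit strings or 0/1
#'   matrices.
#' @param crop optional list with elements `cond` and/or `out`, each either
#'   an index vector (for vector objects) or a list `list(rows=, cols=)`
#'   (for matrices), selecting the window kept before keying.
#' @param source free-text provenance note.
#' @return an object of class `cond_ctm_table`.  Tabulated probabilities
#'   sum to one: `sum(2^-entries) == 1`.
#' @examples
#' tab <- build_conditional_ctm(list(
#'   list("00", "0000"), list("00", "0000"),
#'   list("01", "1111"), list("10", "0110")))
#' ctm_lookup(tab, "0000", "00")  # 1 bit: seen twice among four pairs
#' @export
build_conditional_ctm <- function(pairs, crop = NULL, source = "") {
  if (length(pairs) == 0L) stop("empty relation")
  crop_one <- function(obj, spec) {
    if (is.null(spec)) return(obj)
    if (is.matrix(obj)) {
      if (max(spec$rows) > nrow(obj) || max(spec$cols) > ncol(obj)) {
        stop("crop larger than object")
      }
      obj[spec$rows, spec$cols, drop = FALSE]
    } else {
      obj <- as_bits(obj)
      if (max(spec) > length(obj)) stop("crop larger than object")
      obj[spec]
    }
  }
  cond_keys <- vapply(pairs, function(p)
    tensor_key(crop_one(if (is.matrix(p[[1L]])) p[[1L]] else as_bits(p[[1L]]),
                        crop$cond)), character(1))
  out_keys <- vapply(pairs, function(p)
    tensor_key(crop_one(if (is.matrix(p[[2L]])) p[[2L]] else as_bits(p[[2L]]),
                        crop$out)), character(1))
  new_cond_ctm_table(cond_keys, out_keys, crop = crop, source = source)
}

#' @export
print.cond_ctm_table <- function(x, ...) {
  cat("Conditional CTM table: |P| =", format(x$pair_count, big.mark = ","),
      "pairs,", length(x$entries), "distinct;",
      "fallback", x$fallback_bits, "bits\n")
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' Conditional CTM lookup
#'
#' Returns the tabulated `-log2` value for the pair `(condition, outcome)`,
#' or the table's fallback penalty when the pair was never produced by the
#' enumerated space.  The table's crop (if any) is applied to both
#' arguments, so callers pass uncropped objects.
#'
#' @param table a `cond_ctm_table`.
#' @param x outcome object (0/1 vector, matrix, or key string).
#' @param s condition object.
#' @return complexity approximation in bits.
#' @export
ctm_lookup <- function(table, x, s) {
  ck <- cropped_key(table, s, "cond")
  ok <- cropped_key(table, x, "out")
  if (nchar(ck) != table$cond_len || nchar(ok) != table$out_len) {
    stop("object shape does not match table metadata")
  }
  cond_ctm_lookup(table, ck, ok)
}

# Key an object for table lookup, applying the table's crop window only
# when the object is larger than the keyed shape (so pre-cropped blocks
# pass through untouched).
cropped_key <- function(table, obj, which) {
  expected <- if (which == "cond") table$cond_len else table$out_len
  spec <- table$crop[[which]]
  if (is.character(obj) && length(obj) == 1L) return(obj)
  if (is.matrix(obj)) {
    if (length(obj) > expected && !is.null(spec)) {
      obj <- obj[spec$rows, spec$cols, drop = FALSE]
    }
    tensor_key(obj)
  } else {
    obj <- as_bits(obj)
    if (length(obj) > expected && !is.null(spec)) obj <- obj[spec]
    bits_to_string(obj)
  }
}

# Vectorized key-level lookup; used by the classifiers, where thousands of
# lookups are batched into one subscript operation.
cond_ctm_lookup <- function(table, cond_keys, out_keys) {
  v <- unname(table$entries[paste(cond_keys, out_keys, sep = "|")])
  v[is.na(v)] <- table$fallback_bits
  v
}
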