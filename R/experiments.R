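# End-to-end experiment pipelines: these wire the simulators, the
# conditional CTM tables and the classifiers together exactly as the
# corpus generators define the tasks.  The heavy artifacts (the cellular
# automaton pair table and the NK enumeration tables) are deterministic,
# seed-free, and memoised in a package-local cache.

.apml_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, .apml_cache, inherits = FALSE)) {
    assign(key, builder(), envir = .apml_cache)
  }
  get(key, .apml_cache)
}

#' Conditional CTM table for the initial-condition tasks
#'
#' Evolves every `width`-bit string for `steps` steps under every rule in
#' `rules` and tabulates the (condition, outcome) relation after cropping
#' to the inner six bits of the string and the inner 6 x `steps` window of
#' the evolution (the crop removes the frontier cells whose light cone
#' wraps the finite lattice).  With the defaults this is the
#' 524,288-pair relation between 6-bit conditions and 6 x 4 outcomes; by
#' the shift invariance of cyclic automata over uniform strings the window
#' statistics are position-free, so the same table scores any co-located
#' (6-bit, 6 x 4) block pair.
#'
#' @param rules ECA rules enumerated (default 0:127; `0:128` reproduces
#'   the alternative pair count).
#' @param width string width (the table is built from 12-bit dynamics).
#' @param steps evolution steps.
#' @param inner index window kept, centred by default.
#' @param cache reuse the memoised table if already built this session.
#' @return a `cond_ctm_table` with 6-bit conditions and `6 * steps`-bit
#'   outcomes.
#' @export
initcond_ctm_table <- function(rules = 0:127, width = 12L, steps = 4L,
                               inner = 4:9, cache = TRUE) {
  build <- function() {
    S0 <- int_to_bits(0:(2^width - 1L), width)
    out_cols <- as.vector(vapply(seq_len(steps),
                                 function(t) (t - 1L) * width + inner,
                                 integer(length(inner))))
    conds <- rows_to_keys(S0[, inner, drop = FALSE])
    cond_keys <- vector("list", length(rules))
    out_keys <- vector("list", length(rules))
    for (i in seq_along(rules)) {
      evo <- eca_evolve_matrix(S0, rules[i], steps)
      cond_keys[[i]] <- conds
      out_keys[[i]] <- rows_to_keys(evo[, out_cols, drop = FALSE])
    }
    new_cond_ctm_table(
      unlist(cond_keys), unlist(out_keys),
      crop = list(cond = inner,
                  out = list(rows = seq_len(steps), cols = inner)),
      source = sprintf("ECA rules %d..%d over all %d-bit strings, %d steps",
                       min(rules), max(rules), width, steps))
  }
  if (!cache) return(build())
  key <- paste0("initcond_", min(rules), "_", max(rules), "_", width, "_",
                steps)
  cache_get(key, build)
}

#' Conditional CTM tables from the full NK enumeration
#'
#' Compiles the two pair relations of the n = 4, k = 2 network space
#' (331,776 networks evolved 10 rows from the zero state): rule-list vs
#' evolution and topology vs evolution.  Both share the fallback penalty
#' `floor(log2(331776)) + 1 = 19` bits.
#'
#' @param cache reuse the memoised tables.
#' @return list with `cond_ctm_table`s `rules` and `topology`.
#' @export
nk_ctm_tables <- function(cache = TRUE) {
  build <- function() {
    tab <- nk_space_table(4L, 2L)
    list(rules = new_cond_ctm_table(
           tab$rule_key, tab$evo_key,
           source = "all n=4,k=2 NK networks; condition = rule list"),
         topology = new_cond_ctm_table(
           tab$topo_key, tab$evo_key,
           source = "all n=4,k=2 NK networks; condition = topology"))
  }
  if (!cache) return(build())
  cache_get("nk_tables", build)
}

#' Initial-condition classification experiment
#'
#' The full pipeline behind the strong-conditional-BDM accuracy numbers:
#' generate the train/validation/test splits, train one centroid bit
#' string per class by greedy block optimization (6-bit blocks) against
#' the conditional CTM table, and evaluate on the test split.
#'
#' @param table the [initcond_ctm_table()].
#' @param seed dataset seed.
#' @param ... passed to [gen_initcond_dataset()] (e.g. `classes = NULL,
#'   width = 24` for the 24-bit transfer variant).
#' @return list with the fitted `model`, the `datasets`, the test
#'   `evaluation` and its `accuracy`.
#' @export
initcond_experiment <- function(table, seed, ...) {
  ds <- gen_initcond_dataset(seed, ...)
  width <- ds$train$manifest$width
  spec <- ap_distance("strong-bdm", table = table, block_width = 6L)
  model <- apclassifier(ds$train, spec, centroid_length = width,
                        classes = ds$train$manifest$class_keys)
  ev <- evaluate_classifier(model, ds$test)
  list(model = model, datasets = ds, evaluation = ev,
       accuracy = ev$accuracy)
}

#' @rdname initcond_experiment
#' @param rules rule range scanned by the exact-reproduction search.
#' @export
exhaustive_initcond_experiment <- function(table, seed, rules = 0:127, ...) {
  ds <- gen_initcond_dataset(seed, rules = rules, ...)
  class_keys <- ds$train$manifest$class_keys
  steps <- ds$train$manifest$steps
  idx <- build_evolution_index(class_keys, rules, steps)
  spec <- ap_distance("strong-bdm", table = table, block_width = 6L)
  fallback <- apclassifier(ds$train, spec,
                           centroid_length = ds$train$manifest$width,
                           classes = class_keys)
  pred <- vapply(ds$test$samples, exhaustive_search_classify,
                 character(1), class_strings = class_keys, rules = rules,
                 steps = steps, index = idx, fallback = fallback)
  acc <- mean(pred == ds$test$labels)
  list(datasets = ds, predictions = pred, accuracy = acc)
}

#' ECA rule classification experiment (coarse conditional BDM)
#'
#' The 11-class generative-rule task: 32x32 evolution images classified
#' against 16x16 centroid matrices under coarse conditional BDM over 4x4
#' blocks, with centroids trained by greedy quadrant optimization (the
#' four 8x8 quadrants in reading order; 64-bit blocks are optimized by
#' coordinate descent).  Requires an unconditional base CTM table covering
#' 4x4 blocks - in practice a converted copy of the published
#' two-dimensional CTM database, loaded with [load_ctm_table()]; the
#' package does not bundle it.
#'
#' @param base a [ctm_table()] over 4x4 block keys.
#' @param seed dataset seed.
#' @param surrogate use the entropy surrogate for blocks missing from
#'   `base` (exploratory only).
#' @return list with `model`, `datasets`, `evaluation`, `accuracy`.
#' @export
eca_rule_experiment <- function(base, seed, surrogate = FALSE) {
  ds <- gen_eca_rule_dataset(seed)
  spec <- ap_distance("coarse-bdm", base = base,
                      partition = partition_spec(c(4L, 4L)),
                      surrogate = surrogate)
  quad <- function(r0, c0) {
    as.vector(vapply(r0 + 0:7, function(r) (r - 1L) * 16L + c0 + 0:7,
                     integer(8)))
  }
  blocks <- list(quad(1L, 1L), quad(1L, 9L), quad(9L, 1L), quad(9L, 9L))
  model <- apclassifier(ds$train, spec, centroid_shape = c(16L, 16L),
                        blocks = blocks,
                        classes = unique(ds$train$labels))
  ev <- evaluate_classifier(model, ds$test)
  list(model = model, datasets = ds, evaluation = ev,
       accuracy = ev$accuracy)
}

#' NK rule-list / topology classification experiment
#'
#' Generates the 40-bit evolution corpus for the given mode and classifies
#' each test vector by direct conditional CTM against the ten class keys.
#'
#' @param tables the [nk_ctm_tables()] pair.
#' @param mode `"rules"` or `"topology"`.
#' @param seed dataset seed.
#' @param ... passed to [gen_nk_class_datasets()].
#' @return list with `model`, `datasets`, `evaluation`, `accuracy`.
#' @export
nk_experiment <- function(tables, mode = c("rules", "topology"), seed, ...) {
  mode <- match.arg(mode)
  ds <- gen_nk_class_datasets(mode, seed, ...)
  class_keys <- ds$train$manifest$class_keys
  spec <- ap_distance("cond-ctm", table = tables[[mode]])
  model <- apclassifier(distance = spec, centroids = class_keys,
                        classes = class_keys)
  ev <- evaluate_classifier(model, ds$test)
  list(model = model, datasets = ds, evaluation = ev,
       accuracy = ev$accuracy)
}
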