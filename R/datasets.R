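#' Labeled datasets
#'
#' The light-weight container produced by every corpus generator: a list of
#' binary samples (matrices or bit vectors), parallel class labels, the
#' split tag, and a manifest recording the generator, its parameters and
#' the seed, sufficient to regenerate the dataset bit-for-bit.
#'
#' @param samples list of 0/1 matrices or integer 0/1 vectors.
#' @param labels character vector of class labels, one per sample.
#' @param split one of `"train"`, `"validation"`, `"test"`.
#' @param manifest list of provenance fields (generator, parameters, seed).
#' @return an object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(samples, labels, split, manifest = list()) {
  stopifnot(length(samples) == length(labels))
  structure(list(samples = samples, labels = as.character(labels),
                 split = split, manifest = manifest),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("Labeled dataset (", x$split, "): ", length(x$samples), " samples, ",
      length(unique(x$labels)), " classes\n", sep = "")
  invisible(x)
}

#' @export
length.labeled_dataset <- function(x) length(x$samples)

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Named substream seeds derived from one top-level seed; kept below 2^31.
substream_seeds <- function(seed, names) {
  stats::setNames((as.numeric(seed) * 101 + 1000 * seq_along(names)) %%
                    2147483647, names)
}

#' Generate the ECA rule-classification corpus
#'
#' 32x32 black-and-white images, each the evolution (initial row included)
#' of one of eleven elementary cellular automata from a uniform random
#' 32-bit initialization; 25 samples per class in the train and validation
#' splits and 125 per class (1,375 total) in the test split.
#'
#' @param seed top-level seed; substream seeds per split are derived from
#'   it and recorded in the manifests.
#' @param rules the eleven class rules.
#' @param width image width (and height, as `width - 1` steps are taken).
#' @param per_class named counts per split.
#' @return list of three [labeled_dataset()]s: `train`, `validation`,
#'   `test`.
#' @export
gen_eca_rule_dataset <- function(seed,
                                 rules = c(167, 11, 129, 215, 88, 32, 237,
                                           156, 173, 236, 110),
                                 width = 32L,
                                 per_class = c(train = 25L, validation = 25L,
                                               test = 125L)) {
  seeds <- substream_seeds(seed, names(per_class))
  out <- lapply(names(per_class), function(sp) {
    with_seed(seeds[[sp]], {
      n <- per_class[[sp]]
      samples <- vector("list", n * length(rules))
      labels <- character(n * length(rules))
      i <- 0L
      for (r in rules) for (j in seq_len(n)) {
        i <- i + 1L
        init <- sample(0:1, width, replace = TRUE)
        samples[[i]] <- eca_evolve(init, r, width - 1L, include_init = TRUE)
        labels[i] <- as.character(r)
      }
      labeled_dataset(samples, labels, sp,
                      manifest = list(generator = "eca-rules", seed = seed,
                                      split_seed = seeds[[sp]],
                                      rules = rules, width = width))
    })
  })
  stats::setNames(out, names(per_class))
}

#' Generate the initial-condition classification corpus
#'
#' Each class is a fixed binary initialization string; a sample is the
#' 4-step evolution of that string under a uniformly random elementary
#' cellular automaton rule (rules 0-127 by default, avoiding trivially
#' symmetric cases) with the initialization row removed, so the classifier
#' must recover the initial condition from the downstream dynamics alone.
#' The default classes are the 12-bit expansions of ten fixed integers;
#' passing `classes = NULL` draws `n_random_classes` distinct random
#' strings of the given width instead (the 24-bit transfer variant).
#'
#' @param seed top-level seed.
#' @param classes integer class values, expanded to `width` bits, or `NULL`
#'   for random class strings.
#' @param width class-string width.
#' @param n_random_classes number of random classes when `classes = NULL`.
#' @param rules candidate ECA rules.
#' @param steps evolution steps (rows of each sample).
#' @param per_class samples per class per split.
#' @return list of three [labeled_dataset()]s; the class bit strings are in
#'   each manifest as `class_keys`.
#' @export
gen_initcond_dataset <- function(seed,
                                 classes = c(704, 3572, 3067, 3184, 1939,
                                             2386, 2896, 205, 828, 3935),
                                 width = 12L, n_random_classes = 20L,
                                 rules = 0:127, steps = 4L,
                                 per_class = 20L) {
  splits <- c("classes", "train", "validation", "test")
  seeds <- substream_seeds(seed, splits)
  if (is.null(classes)) {
    class_keys <- with_seed(seeds[["classes"]], {
      k <- character(0)
      while (length(k) < n_random_classes) {
        k <- unique(c(k, bits_to_string(sample(0:1, width, replace = TRUE))))
      }
      k
    })
  } else {
    class_keys <- rows_to_keys(int_to_bits(classes, width))
  }
  if (anyDuplicated(class_keys)) stop("duplicate class strings")
  class_bits <- lapply(class_keys, as_bits)
  out <- lapply(c("train", "validation", "test"), function(sp) {
    with_seed(seeds[[sp]], {
      n <- per_class * length(class_keys)
      samples <- vector("list", n)
      labels <- character(n)
      i <- 0L
      for (ci in seq_along(class_keys)) for (j in seq_len(per_class)) {
        i <- i + 1L
        r <- sample(rules, 1L)
        samples[[i]] <- eca_evolve(class_bits[[ci]], r, steps,
                                   include_init = FALSE)
        labels[i] <- class_keys[ci]
      }
      labeled_dataset(samples, labels, sp,
                      manifest = list(generator = "init-cond", seed = seed,
                                      split_seed = seeds[[sp]],
                                      class_keys = class_keys,
                                      rules = range(rules), steps = steps,
                                      width = width))
    })
  })
  stats::setNames(out, c("train", "validation", "test"))
}

#' Generate the NK rule-list / topology classification corpora
#'
#' 40-bit evolution vectors of n = 4, k = 2 Boolean networks started from
#' the all-zeros state and recorded for 10 rows.  In `"rules"` mode the
#' classes are 10 random ordered 4-function lists over {And, Or, Nand,
#' XOr}, each containing Nand (the only pool function mapping (0,0) to 1,
#' without which the zero start yields forty 0s), and each sample draws a
#' fresh random topology; in `"topology"` mode the classes are 10 random
#' k = 2 input-set assignments and each sample draws a fresh
#' Nand-containing function list.
#'
#' @param mode `"rules"` or `"topology"`.
#' @param seed top-level seed.
#' @param n_classes number of classes.
#' @param per_class train/validation samples per class.
#' @param n_test total test samples (balanced across classes).
#' @param required pool function that must appear in every function list;
#'   set to `"XOr"` to restore the literal corpus description.
#' @return list of three [labeled_dataset()]s; `class_keys` in the
#'   manifests give each class's function-index (or input-set-index) key.
#' @export
gen_nk_class_datasets <- function(mode = c("rules", "topology"), seed,
                                  n_classes = 10L, per_class = 20L,
                                  n_test = 2000L, required = "Nand") {
  mode <- match.arg(mode)
  pool <- boolean_function_pool(2L)
  req_idx <- if (is.null(required)) NULL else match(required, names(pool))
  n <- 4L
  splits <- c("classes", "train", "validation", "test")
  seeds <- substream_seeds(seed, splits)
  draw_rule_list <- function() {
    repeat {
      f <- sample.int(4L, n, replace = TRUE)
      if (is.null(req_idx) || any(f == req_idx)) return(f)
    }
  }
  class_rows <- with_seed(seeds[["classes"]], {
    keys <- character(0); rowsl <- list()
    while (length(rowsl) < n_classes) {
      v <- if (mode == "rules") draw_rule_list() else
        sample.int(6L, n, replace = TRUE)
      k <- paste(v, collapse = "")
      if (!k %in% keys) { keys <- c(keys, k); rowsl[[length(rowsl) + 1L]] <- v }
    }
    rowsl
  })
  class_keys <- vapply(class_rows, paste, character(1), collapse = "")
  M <- nk_choice_tables(n, 2L, pool)
  gen_split <- function(sp, per_cls) {
    with_seed(seeds[[sp]], {
      total <- per_cls * n_classes
      labs <- rep(seq_len(n_classes), each = per_cls)
      if (mode == "rules") {
        fidx <- do.call(rbind, class_rows)[labs, , drop = FALSE]
        sidx <- matrix(sample.int(6L, total * n, replace = TRUE), total, n)
      } else {
        sidx <- do.call(rbind, class_rows)[labs, , drop = FALSE]
        fidx <- t(vapply(seq_len(total), function(i) draw_rule_list(),
                         integer(n)))
      }
      choices <- (sidx - 1L) * 4L + fidx
      stateidx <- nk_evolve_indices(choices, n, M, rows = 10L, init = 0L)
      keys <- nk_states_to_keys(stateidx, n)
      samples <- lapply(keys, as_bits)
      labeled_dataset(samples, class_keys[labs], sp,
                      manifest = list(generator = paste0("nk-", mode),
                                      seed = seed, split_seed = seeds[[sp]],
                                      class_keys = class_keys,
                                      required = required))
    })
  }
  list(train = gen_split("train", per_class),
       validation = gen_split("validation", per_class),
       test = gen_split("test", as.integer(n_test / n_classes)))
}

#' Generate the Kauffman connectivity (k) corpus
#'
#' 240-bit evolution vectors of n = 24 Boolean networks recorded for 10
#' rows from a uniform random initial state, labelled by the in-degree
#' k in {1, 2, 3} (frozen / critical / chaotic regimes).  Node functions
#' are uniform over all `2^(2^k)` k-ary Boolean functions.
#'
#' @param seed top-level seed.
#' @param n nodes per network.
#' @param ks class in-degrees.
#' @param per_class samples per class per split.
#' @param rows recorded rows per evolution.
#' @return list of three [labeled_dataset()]s.
#' @export
gen_kauffman_k_dataset <- function(seed, n = 24L, ks = 1:3, per_class = 100L,
                                   rows = 10L) {
  splits <- c("train", "validation", "test")
  seeds <- substream_seeds(seed, splits)
  out <- lapply(splits, function(sp) {
    with_seed(seeds[[sp]], {
      total <- per_class * length(ks)
      samples <- vector("list", total)
      labels <- character(total)
      i <- 0L
      for (k in ks) for (j in seq_len(per_class)) {
        i <- i + 1L
        inputs <- lapply(seq_len(n), function(.) sample.int(n, k))
        funs <- lapply(seq_len(n), function(.)
          sample(0:1, 2^k, replace = TRUE))
        net <- nk_network(inputs, funs)
        init <- sample(0:1, n, replace = TRUE)
        samples[[i]] <- flatten_rows(nk_evolve(net, init, rows))
        labels[i] <- as.character(k)
      }
      labeled_dataset(samples, labels, sp,
                      manifest = list(generator = "kauffman-k", seed = seed,
                                      split_seed = seeds[[sp]], n = n,
                                      ks = ks, rows = rows))
    })
  })
  stats::setNames(out, splits)
}
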