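#' Algorithmic distance specifications
#'
#' A distance spec binds a conditional-complexity estimator to the shapes
#' the classifier works with.  Three kinds are provided:
#' \describe{
#'   \item{`"strong-bdm"`}{strong conditional BDM with positional pairing:
#'     the sample (a time x width matrix) is cut into `block_width`-column
#'     blocks, the centroid bit string into `block_width`-bit blocks, and
#'     co-located pairs are scored by the conditional CTM table.}
#'   \item{`"cond-ctm"`}{direct conditional CTM: the centroid is a
#'     structured class key (e.g. an NK rule-list) and the whole flattened
#'     sample is the outcome.}
#'   \item{`"coarse-bdm"`}{coarse conditional BDM between the sample and a
#'     centroid matrix over a common partition with an unconditional base
#'     table.}
#' }
#'
#' @param kind one of `"strong-bdm"`, `"cond-ctm"`, `"coarse-bdm"`.
#' @param table a `cond_ctm_table` (for the first two kinds).
#' @param block_width column/bit block width for `"strong-bdm"`.
#' @param base,partition base [ctm_table()] and [partition_spec()] for
#'   `"coarse-bdm"`.
#' @param surrogate entropy-surrogate flag passed to the coarse estimator.
#' @return an object of class `ap_distance`.
#' @export
ap_distance <- function(kind = c("strong-bdm", "cond-ctm", "coarse-bdm"),
                        table = NULL, block_width = 6L, base = NULL,
                        partition = NULL, surrogate = FALSE) {
  kind <- match.arg(kind)
  if (kind %in% c("strong-bdm", "cond-ctm") && is.null(table)) {
    stop("a conditional CTM table is required for this distance kind")
  }
  if (kind == "coarse-bdm" && (is.null(base) || is.null(partition))) {
    stop("coarse-bdm distance requires a base table and a partition")
  }
  structure(list(kind = kind, table = table,
                 block_width = as.integer(block_width), base = base,
                 partition = partition, surrogate = surrogate),
            class = "ap_distance")
}

# Precompute the per-sample representation a distance kind needs so that
# repeated centroid sweeps reuse it.
prepare_samples <- function(spec, samples) {
  switch(spec$kind,
    "strong-bdm" = {
      nb <- ncol(samples[[1L]]) %/% spec$block_width
      keys <- vapply(samples, function(m) {
        if (!is.matrix(m)) stop("strong-bdm distance expects matrix samples")
        vapply(seq_len(nb), function(b) {
          tensor_key(m[, ((b - 1L) * spec$block_width + 1L):
                         (b * spec$block_width), drop = FALSE])
        }, character(1))
      }, character(nb))
      # one row per sample, one column per block
      if (nb == 1L) matrix(keys, ncol = 1L) else t(keys)
    },
    "cond-ctm" = vapply(samples, tensor_key, character(1)),
    "coarse-bdm" = lapply(samples, block_multiset, spec = spec$partition)
  )
}

# Reshape a stored centroid bit vector into the matrix form a 2D distance
# expects (row-major), leaving key strings and matrices untouched.
shape_centroid <- function(centroid, shape) {
  if (is.null(shape) || is.character(centroid) || is.matrix(centroid)) {
    return(centroid)
  }
  matrix(as_bits(centroid), shape[1L], shape[2L], byrow = TRUE)
}

# Distance of every prepared sample to one centroid.  Centroid form depends
# on the kind: a bit vector for strong-bdm, a key string for cond-ctm, a
# matrix for coarse-bdm.
centroid_distances <- function(spec, prepared, centroid) {
  switch(spec$kind,
    "strong-bdm" = {
      bw <- spec$block_width
      cb <- as_bits(centroid)
      nb <- length(cb) %/% bw
      ckeys <- vapply(seq_len(nb), function(b)
        bits_to_string(cb[((b - 1L) * bw + 1L):(b * bw)]), character(1))
      n <- nrow(prepared)
      v <- cond_ctm_lookup(spec$table,
                           rep(ckeys, each = n), as.vector(prepared))
      rowSums(matrix(v, nrow = n))
    },
    "cond-ctm" = cond_ctm_lookup(spec$table,
                                 rep(as.character(centroid),
                                     length(prepared)), prepared),
    "coarse-bdm" = {
      my <- block_multiset(centroid, spec$partition)
      vapply(prepared, function(mx) {
        shared <- intersect(names(mx), names(my))
        only_x <- setdiff(names(mx), shared)
        v <- 0
        if (length(only_x)) {
          v <- v + sum(base_ctm_values(only_x, spec$base, spec$surrogate) +
                         log2(mx[only_x]))
        }
        if (length(shared)) {
          v <- v + sum(ifelse(mx[shared] == my[shared], 0, log2(mx[shared])))
        }
        v
      }, numeric(1))
    }
  )
}

#' Fit an algorithmic-probability classifier
#'
#' The package's central model: a nearest-centroid classifier under an
#' algorithmic (conditional-complexity) distance.  Three behaviours,
#' chosen by `type`:
#' \describe{
#'   \item{`"centroid"` with `centroids` supplied}{the centroids are fixed
#'     class representatives (e.g. the NK rule-list keys) and no training
#'     is needed.}
#'   \item{`"centroid"` without `centroids`}{bit-string centroids are
#'     learned by greedy block optimization ([greedy_block_train()])
#'     starting from all-zero strings.}
#'   \item{`"scalar"`}{each class is summarized by the mean of a scalar
#'     complexity score over its training samples and prediction picks the
#'     nearest center ([scalar_center_train()]).}
#' }
#'
#' @param train a [labeled_dataset()] (required unless fixed `centroids`
#'   are given with explicit `classes`).
#' @param distance an [ap_distance()] (centroid types).
#' @param type `"centroid"` or `"scalar"`.
#' @param centroids optional named list (or character vector) of fixed
#'   centroids, one per class, in class order.
#' @param centroid_length length of the learned centroid bit strings.
#' @param centroid_shape optional `c(rows, cols)` shape for matrix-valued
#'   centroids (stored row-major as bit vectors).
#' @param blocks training schedule: list of index vectors into the
#'   centroid bits; default consecutive `distance$block_width`-bit blocks.
#' @param scorer scalar complexity function (for `type = "scalar"`).
#' @param classes class labels in declared order (ties in prediction go to
#'   the earliest class).
#' @return an object of class `apclassifier`.
#' @seealso [predict.apclassifier()], [evaluate_classifier()],
#'   [one_pixel_attack_scan()]
#' @export
apclassifier <- function(train = NULL, distance = NULL,
                         type = c("centroid", "scalar"),
                         centroids = NULL, centroid_length = NULL,
                         centroid_shape = NULL, blocks = NULL,
                         scorer = NULL, classes = NULL) {
  type <- match.arg(type)
  cl <- match.call()
  if (is.null(classes)) {
    if (is.null(train)) stop("either `train` or `classes` must be given")
    classes <- unique(train$labels)
  }
  if (type == "scalar") {
    stopifnot(!is.null(scorer), !is.null(train))
    centers <- scalar_center_train(train, scorer)
    centers <- centers[as.character(classes)]
    if (anyNA(centers)) {
      stop("empty class in training set: ",
           paste(classes[is.na(centers)], collapse = ", "))
    }
    names(centers) <- as.character(classes)
    return(structure(list(type = "scalar", classes = as.character(classes),
                          centers = centers, scorer = scorer, call = cl),
                     class = "apclassifier"))
  }
  stopifnot(inherits(distance, "ap_distance"))
  if (!is.null(centroid_shape) && is.null(centroid_length)) {
    centroid_length <- prod(centroid_shape)
  }
  if (is.null(centroids)) {
    stopifnot(!is.null(train), !is.null(centroid_length))
    centroids <- stats::setNames(
      lapply(classes, function(.) rep(0L, centroid_length)), classes)
    model <- structure(list(type = "centroid",
                            classes = as.character(classes),
                            centroids = centroids, distance = distance,
                            centroid_shape = centroid_shape, call = cl),
                       class = "apclassifier")
    model <- greedy_block_train(model, train, blocks = blocks)
  } else {
    if (is.character(centroids)) centroids <- as.list(centroids)
    centroids <- stats::setNames(centroids, classes)
    model <- structure(list(type = "centroid",
                            classes = as.character(classes),
                            centroids = centroids, distance = distance,
                            centroid_shape = centroid_shape, call = cl),
                       class = "apclassifier")
  }
  model
}

#' Greedy block training of centroid bit strings
#'
#' For each class, the centroid's bit blocks are optimized in schedule
#' order against the aggregate training cost (the sum of algorithmic
#' distances from the class's training samples to the centroid).  Blocks
#' of at most 16 bits are searched exhaustively over all `2^b` candidates,
#' accepting a candidate only when it strictly lowers the cost (so the
#' first minimum, i.e. the lexicographically smallest, wins ties); larger
#' blocks fall back to single-bit coordinate descent passes until no flip
#' improves the cost.  The aggregate cost is non-increasing across
#' accepted updates.
#'
#' @param model an `apclassifier` with bit-vector centroids.
#' @param train a [labeled_dataset()].
#' @param blocks list of index vectors into the centroid bits; the default
#'   schedule covers the bits in consecutive `block_width`-bit windows.
#' @param max_passes coordinate-descent pass budget for blocks wider than
#'   16 bits.
#' @return the model with trained centroids; per-class final costs in
#'   attribute `"training_cost"`.
#' @export
greedy_block_train <- function(model, train, blocks = NULL, max_passes = 3L) {
  spec <- model$distance
  len <- length(as_bits(model$centroids[[1L]]))
  if (is.null(blocks)) {
    bw <- if (spec$kind == "strong-bdm") spec$block_width else 8L
    starts <- seq(1L, len, by = bw)
    blocks <- lapply(starts, function(s) s:min(s + bw - 1L, len))
  }
  if (!setequal(unlist(blocks), seq_len(len))) {
    stop("schedule must cover every centroid coordinate")
  }
  costs <- numeric(length(model$classes))
  names(costs) <- model$classes
  for (ci in seq_along(model$classes)) {
    cls <- model$classes[ci]
    idx <- which(train$labels == cls)
    if (length(idx) == 0L) stop("empty class in training set: ", cls)
    prepared <- prepare_samples(spec, train$samples[idx])
    eval_cost <- function(bits) {
      sum(centroid_distances(spec, prepared,
                             shape_centroid(bits, model$centroid_shape)))
    }
    cb <- as_bits(model$centroids[[ci]])
    cost <- eval_cost(cb)
    for (blk in blocks) {
      b <- length(blk)
      if (b <= 16L) {
        for (cand in 0:(2^b - 1L)) {
          trial <- cb
          trial[blk] <- int_to_bits(cand, b)
          v <- eval_cost(trial)
          if (v < cost) { cost <- v; cb <- trial }
        }
      } else {
        for (pass in seq_len(max_passes)) {
          improved <- FALSE
          for (p in blk) {
            trial <- cb
            trial[p] <- 1L - trial[p]
            v <- eval_cost(trial)
            if (v < cost) { cost <- v; cb <- trial; improved <- TRUE }
          }
          if (!improved) break
        }
      }
    }
    model$centroids[[ci]] <- cb
    costs[ci] <- cost
  }
  attr(model, "training_cost") <- costs
  model
}

#' @export
print.apclassifier <- function(x, ...) {
  cat("Algorithmic-probability classifier (", x$type, "), ",
      length(x$classes), " classes\n", sep = "")
  if (x$type == "centroid") {
    cat("  distance:", x$distance$kind, "\n")
  } else {
    cat("  class centers:",
        paste(sprintf("%s=%.2f", x$classes, x$centers), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
summary.apclassifier <- function(object, ...) {
  print(object)
  if (object$type == "centroid") {
    for (cls in object$classes) {
      c0 <- object$centroids[[cls]]
      cat(sprintf("  %s: %s\n", cls,
                  if (is.character(c0)) c0 else bits_to_string(as_bits(c0))))
    }
  }
  invisible(object)
}

#' @export
coef.apclassifier <- function(object, ...) {
  if (object$type == "scalar") return(object$centers)
  vapply(object$centroids, function(c0)
    if (is.character(c0)) c0 else bits_to_string(as_bits(c0)), character(1))
}

#' Predict class labels
#'
#' Assigns each sample to the class whose centroid minimizes the
#' algorithmic distance (or whose scalar center is nearest); ties go to
#' the earliest class in the model's declared order.
#'
#' @param object an `apclassifier`.
#' @param newdata a [labeled_dataset()] or a list of samples (a single
#'   matrix/vector is also accepted).
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.apclassifier <- function(object, newdata, ...) {
  samples <- if (inherits(newdata, "labeled_dataset")) newdata$samples
             else if (is.list(newdata)) newdata else list(newdata)
  if (object$type == "scalar") {
    return(vapply(samples, function(x)
      scalar_center_predict(object$centers, x, object$scorer), character(1)))
  }
  spec <- object$distance
  prepared <- prepare_samples(spec, samples)
  D <- vapply(object$classes, function(cls) {
    c0 <- shape_centroid(object$centroids[[cls]], object$centroid_shape)
    tryCatch(centroid_distances(spec, prepared, c0),
             error = function(e) stop("distance failed for centroid ", cls,
                                      ": ", conditionMessage(e)))
  }, numeric(length(samples)))
  if (is.null(dim(D))) D <- matrix(D, nrow = length(samples))
  object$classes[apply(D, 1L, which.min)]
}

#' Scalar complexity class centers
#'
#' Summarizes each class by the mean of a scalar complexity score (BDM or
#' block entropy) over its training samples; prediction assigns a sample
#' to the class with the nearest center, breaking exact midpoint ties
#' toward the smaller class key.
#'
#' @param train a [labeled_dataset()].
#' @param scorer function mapping a sample to a numeric score.
#' @return named numeric vector of per-class centers.
#' @export
scalar_center_train <- function(train, scorer) {
  classes <- unique(train$labels)
  scores <- vapply(train$samples, scorer, numeric(1))
  centers <- vapply(classes, function(cls) {
    i <- train$labels == cls
    if (!any(i)) stop("empty class: ", cls)
    mean(scores[i])
  }, numeric(1))
  names(centers) <- classes
  centers[order(names(centers), method = "radix")]
}

#' @rdname scalar_center_train
#' @param centers named numeric vector from `scalar_center_train()`.
#' @param x one sample.
#' @export
scalar_center_predict <- function(centers, x, scorer) {
  stopifnot(length(centers) >= 1L)
  d <- abs(scorer(x) - centers)
  names(centers)[which.min(d)]  # which.min takes the first, i.e. smaller key
}

#' Evaluate a classifier on a labelled dataset
#'
#' @param model an `apclassifier` (or any object with a `predict` method
#'   returning labels).
#' @param dataset a [labeled_dataset()].
#' @return an `ap_evaluation`: accuracy, confusion matrix (true x
#'   predicted) and per-class accuracy.
#' @export
evaluate_classifier <- function(model, dataset) {
  pred <- predict(model, dataset)
  truth <- dataset$labels
  lev <- unique(c(truth, pred))
  confusion <- table(factor(truth, lev), factor(pred, lev),
                     dnn = c("true", "predicted"))
  per_class <- diag(confusion) / rowSums(confusion)
  structure(list(accuracy = mean(pred == truth), confusion = confusion,
                 per_class = per_class, n = length(truth)),
            class = "ap_evaluation")
}

#' @export
print.ap_evaluation <- function(x, ...) {
  cat(sprintf("Accuracy: %.4f (%d samples)\n", x$accuracy, x$n))
  invisible(x)
}

#' One-pixel attack scan
#'
#' Exhaustive single-bit robustness audit: every pixel of every sample is
#' flipped in turn, the sample re-predicted, and the flip counted as a
#' vulnerability when the predicted label changes from the unperturbed
#' prediction.  Reported as in the robustness comparisons: total count,
#' mean per sample, and the percentage of (sample, pixel) flips that
#' change the label.
#'
#' @param model an `apclassifier`.
#' @param dataset a [labeled_dataset()] of matrix samples.
#' @return an `ap_attack_report` with fields `total`, `per_sample`,
#'   `percentage` and the per-sample count vector `counts`.
#' @export
one_pixel_attack_scan <- function(model, dataset) {
  samples <- dataset$samples
  stopifnot(all(vapply(samples, is.matrix, logical(1))))
  base_pred <- predict(model, dataset)
  npix <- length(samples[[1L]])
  counts <- integer(length(samples))
  for (p in seq_len(npix)) {
    flipped <- lapply(samples, function(m) { m[p] <- 1L - m[p]; m })
    pred <- predict(model, flipped)
    counts <- counts + (pred != base_pred)
  }
  total <- sum(counts)
  structure(list(total = total, per_sample = total / length(samples),
                 percentage = 100 * total / (length(samples) * npix),
                 counts = counts, n_pixels = npix),
            class = "ap_attack_report")
}

#' @export
print.ap_attack_report <- function(x, ...) {
  cat(sprintf("One-pixel attack: %d vulnerabilities, %.2f per sample, %.2f%% of pixels\n",
              x$total, x$per_sample, x$percentage))
  invisible(x)
}

#' Exhaustive-search initial-condition classifier
#'
#' Classifies an evolution image by scanning (rule, class string) pairs in
#' ascending (rule, class index) order for an exact reproduction of the
#' image (initialization row removed); the first matching pair's class
#' wins.  A precomputed evolution index built by
#' [build_evolution_index()] gives identical answers in constant time.
#' Images that match no pair are routed to the fallback classifier.
#'
#' @param x a steps x width 0/1 matrix.
#' @param class_strings character vector of class bit strings.
#' @param rules rule range scanned.
#' @param steps evolution steps (must equal `nrow(x)`).
#' @param index optional precomputed index environment.
#' @param fallback optional `apclassifier` used when no pair matches.
#' @return predicted class string, or `NA_character_` when nothing matches
#'   and no fallback is given.
#' @export
exhaustive_search_classify <- function(x, class_strings, rules = 0:127,
                                       steps = 4L, index = NULL,
                                       fallback = NULL) {
  stopifnot(is.matrix(x), nrow(x) == steps)
  key <- tensor_key(x)
  hit <- if (!is.null(index)) {
    if (exists(key, index, inherits = FALSE)) get(key, index) else NA_character_
  } else {
    found <- NA_character_
    for (r in rules) {
      for (ci in seq_along(class_strings)) {
        ev <- eca_evolve(class_strings[ci], r, steps, include_init = FALSE)
        if (tensor_key(ev) == key) { found <- class_strings[ci]; break }
      }
      if (!is.na(found)) break
    }
    found
  }
  if (!is.na(hit)) return(hit)
  if (!is.null(fallback)) return(predict(fallback, list(x))[1L])
  NA_character_
}

#' @rdname exhaustive_search_classify
#' @export
build_evolution_index <- function(class_strings, rules = 0:127, steps = 4L) {
  idx <- new.env(parent = emptyenv())
  S0 <- do.call(rbind, lapply(class_strings, as_bits))
  for (r in rules) {
    keys <- rows_to_keys(eca_evolve_matrix(S0, r, steps))
    for (ci in seq_along(class_strings)) {
      if (!exists(keys[ci], idx, inherits = FALSE)) {
        assign(keys[ci], class_strings[ci], envir = idx)
      }
    }
  }
  idx
}
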