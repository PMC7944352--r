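#' Algorithmic-probability sample weighting
#'
#' Assigns each training sample a weight from its estimated algorithmic
#' complexity relative to its own class: brackets are scanned from the
#' largest percentile down, and the first bracket whose class-internal
#' nearest-rank percentile threshold the sample's complexity reaches
#' (`K >= threshold`) supplies the weight.  The canonical scheme
#' down-weights the most complex (most likely corrupted) quarter of each
#' class to 0.01, the next quarter to 0.5, and doubles the rest - steering
#' the fit toward algorithmically plausible samples.  Weights depend only
#' on within-class complexity ranks, so any monotone rescaling of the
#' complexity estimator leaves them unchanged.
#'
#' @param samples list of samples.
#' @param labels class labels, one per sample (at least one sample per
#'   class).
#' @param complexity_fn function mapping a sample to a numeric complexity.
#' @param scheme a data.frame with columns `phi` (percentiles, strictly
#'   decreasing) and `gamma` (positive weights); default [eq5_scheme()].
#' @return numeric weight vector, one per sample.
#' @export
algorithmic_weights <- function(samples, labels, complexity_fn,
                                scheme = eq5_scheme()) {
  stopifnot(length(samples) == length(labels))
  if (length(samples) == 0L) stop("at least one sample per class required")
  stopifnot(all(diff(scheme$phi) < 0), all(scheme$gamma > 0))
  k <- vapply(samples, complexity_fn, numeric(1))
  w <- numeric(length(samples))
  for (cls in unique(labels)) {
    i <- which(labels == cls)
    if (length(i) == 0L) stop("empty class: ", cls)
    ks <- sort(k[i])
    thr <- vapply(scheme$phi, function(phi) {
      if (phi <= 0) -Inf else ks[ceiling(phi / 100 * length(ks))]
    }, numeric(1))
    for (j in i) {
      w[j] <- scheme$gamma[which(k[j] >= thr)[1L]]
    }
  }
  w
}

#' @rdname algorithmic_weights
#' @export
eq5_scheme <- function() {
  data.frame(phi = c(75, 50, 0), gamma = c(0.01, 0.5, 2))
}

#' Weighted aggregate cost
#'
#' Applies per-sample weights to per-sample losses and aggregates; with
#' unit weights this is the unweighted cost for any aggregator.
#'
#' @param losses numeric per-sample losses.
#' @param weights numeric weights of the same length.
#' @param aggregator aggregation function (default `sum`).
#' @return aggregated cost.
#' @export
weighted_cost <- function(losses, weights, aggregator = sum) {
  if (length(losses) != length(weights)) stop("length mismatch")
  aggregator(weights * losses)
}

#' Algorithmically regularized cost
#'
#' `J + lambda * K(M)`: penalizes model complexity so that, at equal fit,
#' the algorithmically simpler (more probable) model wins for any
#' `lambda > 0`; `lambda = 0` recovers the base cost.
#'
#' @param J_value base cost.
#' @param lambda nonnegative regularization strength.
#' @param model_complexity estimated complexity of the model, in bits.
#' @return regularized cost.
#' @export
regularized_cost <- function(J_value, lambda, model_complexity) {
  stopifnot(lambda >= 0)
  J_value + lambda * model_complexity
}

#' Salt (corrupt) a fraction of binary images
#'
#' For a uniformly chosen `sample_fraction` of the images, permutes a
#' uniformly chosen `pixel_fraction` of pixel positions among themselves,
#' destroying structure while preserving each image's pixel-value
#' multiset - the corruption design behind the weighting experiments
#' (40% of samples, 30% of pixels).
#'
#' @param images list of 0/1 matrices.
#' @param sample_fraction fraction of images corrupted.
#' @param pixel_fraction fraction of pixel positions shuffled within each
#'   corrupted image.
#' @return list with `images` (corrupted copies) and `salted` (logical
#'   mask of which images were corrupted).
#' @export
salt_samples <- function(images, sample_fraction = 0.4,
                         pixel_fraction = 0.3) {
  stopifnot(sample_fraction >= 0, sample_fraction <= 1,
            pixel_fraction >= 0, pixel_fraction <= 1)
  n <- length(images)
  salted <- logical(n)
  if (n > 0L && sample_fraction > 0) {
    salted[sample.int(n, round(sample_fraction * n))] <- TRUE
  }
  out <- images
  for (i in which(salted)) {
    m <- out[[i]]
    npix <- length(m)
    npick <- round(pixel_fraction * npix)
    if (npick >= 2L) {
      pos <- sample.int(npix, npick)
      m[pos] <- m[pos][sample.int(npick)]
      out[[i]] <- m
    }
  }
  list(images = out, salted = salted)
}
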