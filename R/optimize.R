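#' Fixed-point parameter codecs
#'
#' Parameters are searched over as unsigned fixed-point binary strings,
#' most significant bit first: each scalar takes `int_bits + frac_bits`
#' bits, and a parameter pair is laid out first scalar then second.  The
#' default 4 + 4 layout encodes the pair (5, 1) as
#' `"0101000000010000"`.
#'
#' @param int_bits integer-part bits.
#' @param frac_bits fractional-part bits.
#' @return an object of class `fp_codec`.
#' @export
fp_codec <- function(int_bits = 4L, frac_bits = 4L) {
  structure(list(int_bits = as.integer(int_bits),
                 frac_bits = as.integer(frac_bits)),
            class = "fp_codec")
}

#' @rdname fp_codec
#' @param values numeric vector to encode, each in `[0, 2^int_bits)` and a
#'   multiple of `2^-frac_bits` unless `quantize = TRUE`, in which case
#'   values are rounded to the nearest representable number (saturating at
#'   the range ends).
#' @param codec an `fp_codec`.
#' @param quantize round instead of rejecting unrepresentable values.
#' @return `encode_params()` returns an integer 0/1 vector of
#'   `length(values) * (int_bits + frac_bits)` bits.
#' @examples
#' bits_to_string(encode_params(c(5, 1), fp_codec()))
#' decode_params("10101000", fp_codec())  # 10.5
#' @export
encode_params <- function(values, codec = fp_codec(), quantize = FALSE) {
  w <- codec$int_bits + codec$frac_bits
  scale <- 2^codec$frac_bits
  scaled <- values * scale
  if (quantize) {
    scaled <- pmax(0, pmin(round(scaled), 2^w - 1))
  } else if (any(values < 0) || any(values >= 2^codec$int_bits) ||
             any(abs(scaled - round(scaled)) > 1e-9)) {
    nearest <- pmax(0, pmin(round(scaled), 2^w - 1)) / scale
    stop("value not representable; nearest representable: ",
         paste(nearest, collapse = ", "))
  }
  m <- int_to_bits(round(scaled), w)
  if (is.matrix(m)) as.integer(t(m)) else m
}

#' @rdname fp_codec
#' @param bits 0/1 vector or bit string, a whole number of scalars long.
#' @export
decode_params <- function(bits, codec = fp_codec()) {
  b <- as_bits(bits)
  w <- codec$int_bits + codec$frac_bits
  if (length(b) %% w != 0L) stop("bit length is not a multiple of the codec width")
  vapply(seq_len(length(b) %/% w), function(i) {
    bits_to_int(b[((i - 1L) * w + 1L):(i * w)]) / 2^codec$frac_bits
  }, numeric(1))
}

#' Algorithmic cost of a model over a labelled sample
#'
#' The sum of squared conditional-complexity losses `K(y | M(x))^2`, with
#' `K` approximated by the supplied estimator.  An empty dataset costs 0.
#'
#' @param dataset list of samples, each a `list(x = , y = )`.
#' @param model_fn function mapping `x` to a prediction comparable with
#'   `y` under the estimator.
#' @param cond_complexity function `(y, yhat) -> bits`.
#' @return cost in squared bits.
#' @export
algorithmic_cost <- function(dataset, model_fn, cond_complexity) {
  if (length(dataset) == 0L) return(0)
  sum(vapply(dataset, function(s)
    cond_complexity(s$y, model_fn(s$x))^2, numeric(1)))
}

#' Algorithmic parameter search
#'
#' Walks candidates in the supplied order (ascending algorithmic
#' complexity, from [rank_by_complexity()]), keeping the first strict
#' minimum seen, and halts on the iteration budget or as soon as the best
#' cost reaches `cost_threshold`.  With a cost that has a unique zero at
#' the candidate of rank `r` and a zero threshold, exactly `r` candidates
#' are evaluated.
#'
#' @param candidates list of candidates in search order.
#' @param cost_fn function mapping a candidate to a numeric cost.
#' @param max_iter iteration budget (>= 1).
#' @param cost_threshold optional early-stop cost.
#' @return list with `candidate`, `cost` and `iterations`.
#' @export
algorithmic_search <- function(candidates, cost_fn,
                               max_iter = length(candidates),
                               cost_threshold = NULL) {
  stopifnot(length(candidates) >= 1L)
  if (max_iter < 1L) stop("zero iteration budget")
  best <- NULL; best_cost <- Inf; it <- 0L
  for (cand in candidates) {
    if (it >= max_iter) break
    it <- it + 1L
    v <- cost_fn(cand)
    if (v < best_cost) { best_cost <- v; best <- cand }
    if (!is.null(cost_threshold) && best_cost <= cost_threshold) break
  }
  list(candidate = best, cost = best_cost, iterations = it)
}

#' Two-compartment linear ODE test system
#'
#' The identification benchmark: the linear cascade
#' `dz1/dt = -theta1 z1`, `dz2/dt = theta1 z1 - theta2 z2` with
#' `z(0) = [1, 0]` (mass decays out of the first compartment into the
#' second), integrated with the classical fixed-step fourth-order
#' Runge-Kutta scheme (step 0.01 by default, via \pkg{deSolve}).  Both
#' states stay in the range of the unsigned fixed-point codec, which is
#' what makes the encoded-trajectory identification well posed.
#'
#' @param theta numeric parameter pair `(theta1, theta2)`.
#' @param t_grid output times (subset of the integration grid).
#' @param step integration step; must divide every `t_grid` point.
#' @return a `length(t_grid)` x 2 matrix with columns `z1`, `z2`.
#' @export
ode_evaluate <- function(theta, t_grid, step = 0.01) {
  stopifnot(step > 0)
  times <- seq(0, max(t_grid, 0), by = step)
  sol <- deSolve::rk4(c(z1 = 1, z2 = 0), times,
                      function(t, y, p) {
                        list(c(-p[1] * y[1], p[1] * y[1] - p[2] * y[2]))
                      }, theta)
  ix <- match(round(t_grid / step), round(sol[, 1] / step))
  if (anyNA(ix)) stop("t_grid points must lie on the integration grid")
  unname(sol[ix, 2:3, drop = FALSE])
}

# Trajectories of every candidate parameter pair at once: the 2 * m
# stacked states integrate in one rk4 call.
ode_evaluate_batch <- function(thetas, t_grid, step = 0.01) {
  m <- nrow(thetas)
  y0 <- c(rep(1, m), rep(0, m))
  t1 <- thetas[, 1]; t2 <- thetas[, 2]
  times <- seq(0, max(t_grid), by = step)
  sol <- deSolve::rk4(y0, times, function(t, y, p) {
    z1 <- y[seq_len(m)]; z2 <- y[m + seq_len(m)]
    list(c(-t1 * z1, t1 * z1 - t2 * z2))
  }, NULL)
  ix <- match(round(t_grid / step), round(sol[, 1] / step))
  z <- sol[ix, -1, drop = FALSE]
  list(z1 = t(z[, seq_len(m), drop = FALSE]),
       z2 = t(z[, m + seq_len(m), drop = FALSE]))  # m x length(t_grid)
}

#' Corrupt a bit string by random flips
#'
#' Flips exactly `n_flips` distinct positions chosen uniformly, so the
#' Hamming distance between input and output is always `n_flips`.
#'
#' @param bits 0/1 vector or bit string.
#' @param n_flips number of positions to flip, `0 <= n_flips <= length`.
#' @return integer 0/1 vector of the same length.
#' @export
corrupt_bits <- function(bits, n_flips) {
  b <- as_bits(bits)
  if (n_flips < 0L || n_flips > length(b)) {
    stop("n_flips must be between 0 and the bit length")
  }
  if (n_flips > 0L) {
    pos <- sample.int(length(b), n_flips)
    b[pos] <- 1L - b[pos]
  }
  b
}

# Memoised small-TM base table and 8-bit CTM vector (entropy surrogate for
# strings the enumeration does not produce; flagged in the table meta).
tm_base_table <- function() {
  cache_get("tm_base_2_100", function()
    build_base_ctm_by_tm_enumeration(2L, 100L))
}

ctm8_values <- function() {
  cache_get("ctm8", function() {
    base <- tm_base_table()
    keys <- rows_to_keys(int_to_bits(0:255, 8L))
    v <- unname(base$entries[keys])
    v[is.na(v)] <- vapply(keys[is.na(v)], entropy_surrogate, numeric(1))
    v
  })
}

# Complexity order of all 16-bit candidate strings: BDM over two 8-bit
# blocks, ties broken lexicographically.  Returns candidate integer ids
# (0..65535, id = 256 * hi + lo) in ascending order.
candidate_order_16bit <- function() {
  cache_get("order16", function() {
    ctm8 <- ctm8_values()
    hi <- rep(0:255, each = 256); lo <- rep(0:255, times = 256)
    score <- ifelse(hi == lo, ctm8[hi + 1L] + 1, ctm8[hi + 1L] + ctm8[lo + 1L])
    id <- 256L * hi + lo
    id[order(score, id, method = "radix")]
  })
}

# Vectorized coarse conditional BDM between 16-bit encodings given as
# 8-bit block id pairs: K((a1,a2) | (b1,b2)) over the two-block partition.
cond_bdm_blocks2 <- function(a1, a2, b1, b2, ctm8) {
  n <- max(length(a1), length(a2), length(b1), length(b2))
  a1 <- rep_len(a1, n); a2 <- rep_len(a2, n)
  b1 <- rep_len(b1, n); b2 <- rep_len(b2, n)
  eq <- a1 == a2
  in1 <- a1 == b1 | a1 == b2
  in2 <- a2 == b1 | a2 == b2
  nyb <- (b1 == a1) + (b2 == a1)  # multiplicity of a1 within (b1, b2)
  ifelse(eq,
         ifelse(in1, ifelse(nyb == 2, 0, 1), ctm8[a1 + 1L] + 1),
         ifelse(in1, 0, ctm8[a1 + 1L]) + ifelse(in2, 0, ctm8[a2 + 1L]))
}

#' ODE parameter identification under bit corruption
#'
#' The robustness experiment: for each training-set size and corruption
#' level, sample observation times uniformly from the 0.05-grid of (0, 1],
#' encode the true trajectory of `(theta1, theta2) = (5, 1)` to 16 bits
#' per time point (8 fixed-point bits per state), flip the stated number
#' of bits in every encoded observation, then scan the full 2^16 candidate
#' parameter space in ascending algorithmic order, scoring each candidate
#' by the sum of squared coarse-conditional-BDM losses between observed
#' and predicted encodings.  Reports the Euclidean distance between the
#' decoded estimate and the hidden pair (5, 1), averaged over `repeats`
#' sample sets.
#'
#' @param seed top-level seed.
#' @param sample_sizes training-set sizes.
#' @param flips corruption levels (bits flipped per 16-bit observation).
#' @param repeats random sample sets averaged per cell.
#' @param step integration step.
#' @return data.frame with columns `sample_size`, `flips`,
#'   `mean_distance`.
#' @export
ode_identification_experiment <- function(seed, sample_sizes = c(5, 7, 10),
                                          flips = 1:8, repeats = 10,
                                          step = 0.01) {
  codec <- fp_codec(4L, 4L)
  grid <- seq(0.05, 1, by = 0.05)
  ord <- candidate_order_16bit()
  ctm8 <- ctm8_values()
  thetas <- cbind(decode_params_ids(ord %/% 256L, codec),
                  decode_params_ids(ord %% 256L, codec))
  traj <- ode_evaluate_batch(thetas, grid, step)
  c1 <- encode_ids(traj$z1, codec)  # m x 20 candidate z1 block ids
  c2 <- encode_ids(traj$z2, codec)
  true_row <- which(thetas[, 1] == 5 & thetas[, 2] == 1)
  rows <- expand.grid(sample_size = sample_sizes, flips = flips)
  rows$mean_distance <- NA_real_
  with_seed(seed, {
    for (i in seq_len(nrow(rows))) {
      sz <- rows$sample_size[i]; nf <- rows$flips[i]
      d <- numeric(repeats)
      for (r in seq_len(repeats)) {
        ti <- sample(seq_along(grid), sz)
        cost <- numeric(length(ord))
        for (j in ti) {
          yb <- c(int_to_bits(c1[true_row, j], 8L),
                  int_to_bits(c2[true_row, j], 8L))
          yb <- corrupt_bits(yb, nf)
          a1 <- bits_to_int(yb[1:8]); a2 <- bits_to_int(yb[9:16])
          cost <- cost + cond_bdm_blocks2(a1, a2, c1[, j], c2[, j], ctm8)^2
        }
        best <- which.min(cost)  # first minimum in algorithmic order
        d[r] <- sqrt(sum((thetas[best, ] - c(5, 1))^2))
      }
      rows$mean_distance[i] <- mean(d)
    }
  })
  rows
}

decode_params_ids <- function(ids, codec) ids / 2^codec$frac_bits

encode_ids <- function(v, codec) {
  w <- codec$int_bits + codec$frac_bits
  m <- pmax(0, pmin(round(v * 2^codec$frac_bits), 2^w - 1))
  dim(m) <- dim(v)  # pmin/pmax drop dims when recycling scalars
  storage.mode(m) <- "integer"
  m
}

#' Noise-free ODE identification
#'
#' Scans the candidate space in algorithmic order with a zero-cost early
#' stop; with two or more observation times the encoded trajectory pins
#' down the quantized parameter pair exactly.
#'
#' @param times observation times on the integration grid.
#' @param seed unused placeholder for API symmetry; the procedure is
#'   deterministic.
#' @param step integration step.
#' @return list with `theta` (decoded estimate) and `iterations`.
#' @export
ode_identify <- function(times, step = 0.01, seed = NULL) {
  codec <- fp_codec(4L, 4L)
  ord <- candidate_order_16bit()
  ctm8 <- ctm8_values()
  thetas <- cbind(decode_params_ids(ord %/% 256L, codec),
                  decode_params_ids(ord %% 256L, codec))
  traj <- ode_evaluate_batch(thetas, times, step)
  c1 <- encode_ids(traj$z1, codec); c2 <- encode_ids(traj$z2, codec)
  true_row <- which(thetas[, 1] == 5 & thetas[, 2] == 1)
  cost <- numeric(length(ord))
  for (j in seq_along(times)) {
    cost <- cost + cond_bdm_blocks2(c1[true_row, j], c2[true_row, j],
                                    c1[, j], c2[, j], ctm8)^2
  }
  # ordered scan with zero-cost halt
  best <- which.min(cost)
  list(theta = thetas[best, ], iterations = if (cost[best] == 0) best
       else length(ord), cost = cost[best])
}

#' Bilinear regression demo on the algorithmic cost surface
#'
#' Fits `f(a, b) = (2/3) a + (1/3) b` (binary expansions `0.101010...` and
#' `0.010101...`) from 20 random points by exhaustive algorithmic search
#' over all pairs of 8-bit fractional coefficients, and compares against a
#' random pool baseline that evaluates exactly `pool_size` candidates.
#' Outputs are encoded as single 8-bit fixed-point blocks and scored by
#' coarse conditional BDM.
#'
#' @param seed top-level seed.
#' @param n_points data points generated.
#' @param pool_size candidates evaluated by the random-pool baseline.
#' @return list with the search result (`best_bits`, `best_coefs`,
#'   `best_cost`, `iterations`), the baseline `pool_best_cost`, and the
#'   full cost `surface` (data.frame over all 65,536 candidate pairs).
#' @export
bilinear_demo <- function(seed, n_points = 20L, pool_size = 5000L) {
  codec <- fp_codec(0L, 8L)
  ctm8 <- ctm8_values()
  ord <- candidate_order_16bit()
  with_seed(seed, {
    a <- stats::runif(n_points); b <- stats::runif(n_points)
    y <- (2 / 3) * a + (1 / 3) * b
    yid <- encode_ids(matrix(y, 1L), codec)[1L, ]
    hi <- ord %/% 256L; lo <- ord %% 256L
    cost <- numeric(length(ord))
    for (j in seq_len(n_points)) {
      pid <- encode_ids(matrix(hi / 256 * a[j] + lo / 256 * b[j], ncol = 1L),
                        codec)[, 1L]
      cost <- cost + (pid != yid[j]) * ctm8[yid[j] + 1L]^2
    }
    best <- which.min(cost)
    pool <- sample.int(length(ord), pool_size, replace = TRUE)
    list(best_bits = bits_to_string(c(int_to_bits(hi[best], 8L),
                                      int_to_bits(lo[best], 8L))),
         best_coefs = c(hi[best], lo[best]) / 256,
         best_cost = cost[best], iterations = best,
         pool_best_cost = min(cost[pool]), pool_evaluations = pool_size,
         surface = data.frame(s1 = hi / 256, s2 = lo / 256, cost = cost))
  })
}
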