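# A tiny conditional table over (2-bit condition, 2x2 outcome) pairs used
# as a controllable distance for the classifier unit tests.
toy_table <- function() {
  mk <- function(bits) matrix(as_bits(bits), 2L, 2L, byrow = TRUE)
  build_conditional_ctm(list(
    list("00", mk("0000")), list("00", mk("0000")), list("00", mk("0011")),
    list("11", mk("1111")), list("11", mk("1111")), list("11", mk("1100")),
    list("01", mk("0101")), list("10", mk("1010"))))
}

test_that("prediction is the arg-min centroid with earliest-class ties", {
  tab <- toy_table()
  spec <- ap_distance("strong-bdm", table = tab, block_width = 2L)
  model <- apclassifier(distance = spec, centroids = list(c(0L, 0L), c(1L, 1L)),
                        classes = c("A", "B"))
  zero <- matrix(0L, 2L, 2L)
  ones <- matrix(1L, 2L, 2L)
  expect_equal(predict(model, zero), "A")
  expect_equal(predict(model, ones), "B")
  # a sample at equal distance from both centroids: earliest class wins
  unseen <- matrix(c(1L, 0L, 0L, 1L), 2L, 2L)
  expect_equal(predict(model, unseen), "A")
  # permuting class order only changes tie-broken outcomes
  model_rev <- apclassifier(distance = spec,
                            centroids = list(c(1L, 1L), c(0L, 0L)),
                            classes = c("B", "A"))
  expect_equal(predict(model_rev, zero), "A")
  expect_equal(predict(model_rev, unseen), "B")
})

test_that("greedy block training matches brute force and lowers cost", {
  tab <- fx_initcond_table()
  spec <- ap_distance("strong-bdm", table = tab, block_width = 6L)
  ds <- fx("ic_ds1", function() gen_initcond_dataset(1))
  cls <- ds$train$manifest$class_keys[3L]
  idx <- which(ds$train$labels == cls)
  sub <- labeled_dataset(ds$train$samples[idx], ds$train$labels[idx],
                         "train", ds$train$manifest)
  model <- apclassifier(sub, spec, centroid_length = 12L, classes = cls)
  trained <- as_bits(coef(model)[[1L]])
  prepared <- apml:::prepare_samples(spec, sub$samples)
  cost_of <- function(bits) sum(apml:::centroid_distances(spec, prepared,
                                                          bits))
  tcost <- cost_of(trained)
  expect_equal(attr(model, "training_cost")[[1L]], tcost)
  # oracle equivalence per 6-bit block: the trained half is the brute-force
  # minimum over all 64 candidates with the other half held fixed
  for (half in list(1:6, 7:12)) {
    for (v in 0:63) {
      cand <- trained; cand[half] <- int_to_bits(v, 6L)
      expect_gte(cost_of(cand), tcost)
    }
  }
  # and no random full candidate beats it (schedule-local optimum check)
  set.seed(14)
  for (rep in 1:50) {
    expect_gte(cost_of(sample(0:1, 12, replace = TRUE)), tcost - 1e-9)
  }
  # accepted updates never raise the aggregate training cost
  expect_lte(tcost, cost_of(rep(0L, 12L)))
  expect_error(
    greedy_block_train(apclassifier(distance = spec,
                                    centroids = list(rep(0L, 12L)),
                                    classes = "Z"), sub),
    "empty class")
})

test_that("one-bit blocks pick the lower-cost candidate", {
  # CTM("1111" | s) falls with every extra 1 in the condition, so each
  # single-bit flip improves the cost on its own
  mk <- function(bits) matrix(as_bits(bits), 2L, 2L, byrow = TRUE)
  pairs <- c(rep(list(list("11", mk("1111"))), 4L),
             rep(list(list("10", mk("1111"))), 2L),
             rep(list(list("01", mk("1111"))), 2L),
             list(list("00", mk("0000"))))
  tab <- build_conditional_ctm(pairs)
  spec <- ap_distance("strong-bdm", table = tab, block_width = 2L)
  train <- labeled_dataset(list(mk("1111"), mk("1111")), c("B", "B"),
                           "train")
  model <- apclassifier(train, spec, centroid_length = 2L,
                        blocks = list(1L, 2L), classes = "B")
  expect_equal(coef(model)[["B"]], "11")
})

test_that("matrix centroids train under coarse conditional BDM", {
  keys <- rows_to_keys(int_to_bits(0:15, 4L))
  set.seed(30)
  base <- ctm_table(stats::setNames(runif(16, 4, 12), keys), shape = c(2L, 2L))
  spec <- ap_distance("coarse-bdm", base = base,
                      partition = partition_spec(c(2L, 2L)))
  mk <- function(fill, noise) {
    m <- matrix(fill, 4L, 4L)
    m[noise] <- 1L - m[noise]
    m
  }
  train <- labeled_dataset(
    c(lapply(c(2L, 7L, 11L), function(p) mk(0L, p)),
      lapply(c(3L, 8L, 13L), function(p) mk(1L, p))),
    rep(c("lo", "hi"), each = 3L), "train")
  model <- apclassifier(train, spec, centroid_shape = c(4L, 4L),
                        blocks = list(1:8, 9:16))
  expect_equal(evaluate_classifier(model, train)$accuracy, 1)
  expect_equal(nchar(coef(model)[["lo"]]), 16L)
})

test_that("scalar centers average scores and classify by proximity", {
  # the three-regime center form: printed-style model values
  centers <- c("1" = 2671.46, "2" = 4937.35, "3" = 6837.64)
  expect_equal(scalar_center_predict(centers, 3900, identity), "2")
  expect_equal(scalar_center_predict(centers, 2671.46, identity), "1")
  # exact midpoint: smaller class key
  mid <- c("1" = 2, "2" = 4)
  expect_equal(scalar_center_predict(mid, 3, identity), "1")
  train <- labeled_dataset(list(4, 6, 10), c("a", "a", "b"), "train")
  centers2 <- scalar_center_train(train, identity)
  expect_equal(unname(centers2["a"]), 5)
  expect_equal(unname(centers2["b"]), 10)
  expect_error(apclassifier(train, type = "scalar", scorer = identity,
                            classes = c("a", "b", "c")), "empty class")
  model <- apclassifier(train, type = "scalar", scorer = identity)
  expect_equal(predict(model, list(5.4, 9)), c("a", "b"))
})

test_that("evaluation conserves counts and computes accuracy", {
  tab <- toy_table()
  spec <- ap_distance("strong-bdm", table = tab, block_width = 2L)
  model <- apclassifier(distance = spec,
                        centroids = list(c(0L, 0L), c(1L, 1L)),
                        classes = c("A", "B"))
  mk <- function(bits) matrix(as_bits(bits), 2L, 2L, byrow = TRUE)
  ds <- labeled_dataset(list(mk("0000"), mk("0011"), mk("1111"), mk("1111")),
                        c("A", "B", "B", "B"), "test")
  ev <- evaluate_classifier(model, ds)
  expect_equal(ev$accuracy, 0.75)   # "0011" sits closer to the A centroid
  expect_equal(sum(ev$confusion), 4L)
  expect_equal(unname(ev$per_class["A"]), 1)
  # constant predictor on balanced data scores 1 / #classes
  const <- structure(list(type = "scalar", classes = "1",
                          centers = c("1" = 0), scorer = function(s) 0),
                     class = "apclassifier")
  bal <- labeled_dataset(as.list(1:10), as.character(rep(1:10)), "test")
  expect_equal(evaluate_classifier(const, bal)$accuracy, 0.1)
})

test_that("one-pixel scanning counts exactly the label-changing flips", {
  tab <- toy_table()
  spec <- ap_distance("strong-bdm", table = tab, block_width = 2L)
  model <- apclassifier(distance = spec,
                        centroids = list(c(0L, 0L), c(1L, 1L)),
                        classes = c("A", "B"))
  mk <- function(bits) matrix(as_bits(bits), 2L, 2L, byrow = TRUE)
  ds <- labeled_dataset(list(mk("0000"), mk("1111"), mk("0011")),
                        c("A", "B", "A"), "test")
  rep <- one_pixel_attack_scan(model, ds)
  # brute-force oracle over every (sample, pixel) flip
  want <- 0L
  for (i in 1:3) for (p in 1:4) {
    m <- ds$samples[[i]]; m[p] <- 1L - m[p]
    want <- want + (predict(model, m) != predict(model, ds$samples[[i]]))
  }
  expect_equal(rep$total, want)
  expect_equal(rep$per_sample, want / 3)
  expect_gte(rep$percentage, 0); expect_lte(rep$percentage, 100)
  expect_equal(sum(rep$counts), rep$total)
  # a constant classifier has no vulnerabilities
  const <- structure(list(type = "scalar", classes = "x",
                          centers = c(x = 0), scorer = function(s) 0),
                     class = "apclassifier")
  expect_equal(one_pixel_attack_scan(const, ds)$total, 0L)
})

test_that("exhaustive search finds the generating string or falls back", {
  classes <- c("101011000001", "010011010110", "111000111000")
  idx <- build_evolution_index(classes, 0:63, 4L)
  set.seed(6)
  for (rep in 1:10) {
    ci <- sample(3L, 1L); r <- sample(0:63, 1)
    img <- eca_evolve(classes[ci], r, 4L, include_init = FALSE)
    got <- exhaustive_search_classify(img, classes, 0:63, 4L, index = idx)
    # first match in ascending (rule, class index) order
    want <- NA_character_
    for (rr in 0:63) {
      for (cj in seq_along(classes)) {
        if (identical(eca_evolve(classes[cj], rr, 4L, include_init = FALSE),
                      img)) { want <- classes[cj]; break }
      }
      if (!is.na(want)) break
    }
    expect_equal(got, want)
  }
  # index-free scan agrees with the index
  img <- eca_evolve(classes[2L], 5L, 4L, include_init = FALSE)
  expect_equal(exhaustive_search_classify(img, classes, 0:63, 4L),
               exhaustive_search_classify(img, classes, 0:63, 4L,
                                          index = idx))
  # non-matching image routes to the fallback classifier
  tab <- fx_initcond_table()
  spec <- ap_distance("strong-bdm", table = tab, block_width = 6L)
  fb <- apclassifier(distance = spec,
                     centroids = lapply(classes, as_bits),
                     classes = classes)
  junk <- matrix(rep(c(1L, 0L), 24L), 4L, 12L)
  if (is.na(exhaustive_search_classify(junk, classes, 0:63, 4L,
                                       index = idx))) {
    got <- exhaustive_search_classify(junk, classes, 0:63, 4L, index = idx,
                                      fallback = fb)
    expect_true(got %in% classes)
  }
})
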