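test_that("partitions cover all items in clusters of the requested size", {
  ids <- sprintf("i%02d", 1:40)
  parts <- make_partitions(ids, cluster_size = 10, n_partitions = 5, seed = 2)
  expect_length(parts, 5)
  for (p in parts) {
    expect_length(p, 4)
    expect_setequal(unlist(p), ids)
    expect_true(all(lengths(p) == 10))
  }
  # remainder rule
  p43 <- make_partitions(sprintf("i%02d", 1:43), 10, 1, seed = 1)[[1]]
  expect_identical(unname(sort(lengths(p43), decreasing = TRUE)), c(10L, 10L, 10L, 10L, 3L))
  # canonical singleton partition, regardless of seed and n_partitions
  p1a <- make_partitions(ids, 1, n_partitions = 7, seed = 1)
  p1b <- make_partitions(ids, 1, n_partitions = 3, seed = 99)
  expect_length(p1a, 1)
  expect_identical(unclass(p1a)[[1]], unclass(p1b)[[1]])
  expect_error(make_partitions(character(0), 5), "empty")
})

test_that("pattern probabilities are smoothed empirical frequencies", {
  cat <- va_catalog("i1", "adult")
  d <- va_dataset(matrix(c(1, 1, 0, 1, 0), 5, 1), cat, c("A", "B"),
                  gold_cause = c("A", "A", "A", "A", "B"))
  parts <- make_partitions("i1", 1)
  # alpha = 0: raw counting, P(yes | A) = 3/4
  t0 <- estimate_pattern_probabilities(d, parts, alpha = 0)
  pr <- pattern_prob_matrix(t0)
  expect_equal(pr[2, "A"], 0.75)  # pattern "1"
  expect_equal(pr[1, "A"], 0.25)
  # alpha = 1: (3 + 1) / (4 + 2)
  t1 <- estimate_pattern_probabilities(d, parts, alpha = 1)
  expect_equal(pattern_prob_matrix(t1)[2, "A"], 2 / 3)
  # smoothing gives unseen patterns strictly positive mass
  expect_gt(pattern_prob_matrix(t1)[1, "B"], 0)
})

test_that("probabilities sum to one over each cluster's pattern space", {
  for (seed in c(5, 6)) {
    d <- random_dataset(seed, n = 40, p = 9, n_causes = 3)
    parts <- make_partitions(d$catalog$item_id, 3, n_partitions = 4,
                             seed = seed)
    tab <- estimate_pattern_probabilities(d, parts, alpha = 0.001)
    for (r in 1:4) for (k in 1:3) {
      pr <- pattern_prob_matrix(tab, r, k)
      expect_equal(unname(colSums(pr)), rep(1, 3), tolerance = 1e-9)
      expect_true(all(pr > 0))
    }
  }
})

test_that("increasing alpha shrinks every pattern toward the uniform", {
  d <- random_dataset(7, n = 30, p = 4, n_causes = 2)
  parts <- make_partitions(d$catalog$item_id, 4, n_partitions = 1, seed = 1)
  alphas <- c(0.001, 0.1, 10, 1e6)
  u <- 1 / 16
  prev <- NULL
  for (a in alphas) {
    pr <- pattern_prob_matrix(
      estimate_pattern_probabilities(d, parts, alpha = a))
    if (!is.null(prev)) expect_true(all(abs(pr - u) <= abs(prev - u) + 1e-12))
    prev <- pr
  }
  expect_equal(max(abs(prev - u)), 0, tolerance = 1e-4)
})

test_that("cluster size 1 reproduces the naive-Bayes product exactly", {
  # two independent items with P(yes|cause1) = 0.75 and 0.25; record (yes, yes)
  p <- matrix(c(0.75, 0.25, 0.5, 0.5), 2, 2)
  d <- exact_product_train(p)
  parts <- make_partitions(d$catalog$item_id, 1)
  tab <- estimate_pattern_probabilities(d, parts, alpha = 0)
  rec <- c(it01 = 1L, it02 = 1L)
  expect_equal(record_log_likelihood(rec, tab, "cause1"), log(0.75 * 0.25))
  expect_equal(record_log_likelihood(rec, tab, "cause2"), log(0.5 * 0.5))
  # general oracle equivalence on a larger random instance
  d2 <- random_dataset(11, n = 80, p = 7, n_causes = 2, missing_rate = 0)
  parts2 <- make_partitions(d2$catalog$item_id, 1)
  tab2 <- estimate_pattern_probabilities(d2, parts2, alpha = 0)
  freq <- sapply(d2$cause_list, function(cs)
    colMeans(d2$responses[d2$gold_cause == cs, , drop = FALSE]))
  rec <- d2$responses[1, ]
  for (cs in d2$cause_list) {
    oracle <- sum(log(ifelse(rec == 1, freq[, cs], 1 - freq[, cs])))
    expect_equal(record_log_likelihood(rec, tab2, cs), oracle,
                 tolerance = 1e-12)
  }
})

test_that("alpha = 0 signals unseen patterns as -Inf instead of crashing", {
  cat <- va_catalog(c("i1", "i2"), "adult")
  d <- va_dataset(rbind(c(1, 1), c(1, 1), c(0, 0)), cat, c("A", "B"),
                  gold_cause = c("A", "A", "B"))
  parts <- make_partitions(cat$item_id, 2)
  tab <- estimate_pattern_probabilities(d, parts, alpha = 0)
  expect_identical(record_log_likelihood(c(i1 = 0L, i2 = 1L), tab, "A"), -Inf)
})

test_that("the modal-pattern record maximizes the likelihood", {
  # enumerate all 2^6 response vectors; the record matching every cluster's
  # modal pattern must rank first
  d <- random_dataset(13, n = 50, p = 6, n_causes = 2, missing_rate = 0)
  parts <- make_partitions(d$catalog$item_id, 3, n_partitions = 1, seed = 3)
  tab <- estimate_pattern_probabilities(d, parts, alpha = 0.001)
  grid <- as.matrix(expand.grid(rep(list(0:1), 6)))
  colnames(grid) <- d$catalog$item_id
  ll <- apply(grid, 1, function(r) record_log_likelihood(r, tab, "cause1"))
  # assemble the modal record cluster by cluster
  modal <- integer(6); names(modal) <- d$catalog$item_id
  for (k in 1:2) {
    pr <- pattern_prob_matrix(tab, 1, k)
    best <- which.max(pr[, "cause1"]) - 1L
    cols <- unclass(parts)[[1]][[k]]
    modal[cols] <- as.integer(intToBits(best))[seq_along(cols)]
  }
  expect_equal(max(ll), record_log_likelihood(modal, tab, "cause1"))
})

test_that("averaging over identical partitions changes nothing", {
  d <- random_dataset(17, n = 40, p = 8, n_causes = 2)
  p1 <- make_partitions(d$catalog$item_id, 4, n_partitions = 1, seed = 5)
  p5 <- p1[c(1, 1, 1, 1, 1)]
  attributes(p5) <- attributes(p1)
  t1 <- estimate_pattern_probabilities(d, p1, alpha = 0.001)
  t5 <- estimate_pattern_probabilities(d, p5, alpha = 0.001)
  rec <- d$responses[3, ]
  expect_equal(record_log_likelihood(rec, t1, "cause1"),
               record_log_likelihood(rec, t5, "cause1"), tolerance = 1e-12)
})

test_that("single-cause tables pool the complement class", {
  d <- tiny_dataset()
  parts <- make_partitions(d$catalog$item_id, 2, n_partitions = 1, seed = 1)
  tab <- estimate_pattern_probabilities(d, parts, mode = "single",
                                        cause = "A", alpha = 0.5)
  expect_identical(tab$classes, c("A", "not:A"))
  expect_identical(unname(tab$class_n), c(2L, 4L))
})

test_that("missing responses can be kept as a third pattern symbol", {
  cat <- va_catalog(c("i1", "i2"), "adult")
  d <- va_dataset(rbind(c(1, NA), c(1, NA), c(0, 1)), cat, c("A", "B"),
                  gold_cause = c("A", "A", "B"))
  parts <- make_partitions(cat$item_id, 2)
  tab <- estimate_pattern_probabilities(d, parts, alpha = 0,
                                        missing = "third")
  pr <- pattern_prob_matrix(tab)
  expect_identical(nrow(pr), 9L)             # 3^2 patterns
  expect_equal(pr[1L + 1L + 3L * 2L, "A"], 1)  # pattern (yes, missing)
})
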