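test_that("the variant space is validated and enumerates 12 configurations", {
  expect_error(ssp_config(cause_mode = "multiple", item_set = "top_k"),
               "single-cause")
  vars <- ssp_variants()
  expect_length(vars, 12)
  expect_length(unique(names(vars)), 12)
  # cluster size 1 has a single canonical partition
  expect_identical(ssp_config(cluster_size = 1)$n_partitions, 1L)
})

test_that("multiple-mode posteriors match hand-computed Bayes on counts", {
  # exact product-Bernoulli training set, two items, two causes
  p <- matrix(c(0.75, 0.25, 0.25, 0.75), 2, 2)
  d <- exact_product_train(p)
  model <- ssp(d, ssp_config(cluster_size = 1, cause_mode = "multiple",
                             alpha = 0))
  rec <- d[1]
  rec$responses[1, ] <- c(1L, 1L)
  sc <- predict(model, rec, type = "posterior")
  l1 <- 0.75 * 0.25; l2 <- 0.25 * 0.75
  expect_equal(unname(sc[1, "cause1"]), l1 / (l1 + l2), tolerance = 1e-12)
  rec$responses[1, ] <- c(1L, 0L)
  sc <- predict(model, rec, type = "posterior")
  l1 <- 0.75 * 0.75; l2 <- 0.25 * 0.25
  expect_equal(unname(sc[1, "cause1"]), l1 / (l1 + l2), tolerance = 1e-12)
  expect_equal(unname(rowSums(sc)), 1, tolerance = 1e-9)
})

test_that("fits are deterministic given the seed", {
  d <- random_dataset(19, n = 80, p = 12, n_causes = 3, missing_rate = 0.1)
  cfg <- ssp_config(cluster_size = 4, n_partitions = 3, seed = 42)
  m1 <- ssp(d, cfg); m2 <- ssp(d, cfg)
  te <- random_dataset(20, n = 30, p = 12, n_causes = 3)
  expect_identical(predict(m1, te, type = "posterior"),
                   predict(m2, te, type = "posterior"))
})

test_that("single-mode scores are per-model posteriors, not renormalized", {
  d <- random_dataset(23, n = 100, p = 10, n_causes = 4, missing_rate = 0)
  m <- ssp(d, ssp_config(cluster_size = 2, n_partitions = 3, seed = 7))
  sc <- predict(m, d[1:20], type = "posterior")
  expect_true(all(sc >= 0 & sc <= 1))
  expect_false(isTRUE(all.equal(unname(rowSums(sc)), rep(1, 20))))
  # shared-table path agrees with explicitly fitted per-cause binary models
  parts <- m$table$partitions
  for (cs in d$cause_list) {
    tab <- estimate_pattern_probabilities(d, parts, mode = "single",
                                          cause = cs, alpha = 0.001)
    llj <- record_log_likelihood(d[1:20], tab, cs)
    lln <- record_log_likelihood(d[1:20], tab, paste0("not:", cs))
    oracle <- 1 / (1 + exp(lln - llj))  # 50/50 class prior
    expect_equal(unname(sc[, cs]), oracle, tolerance = 1e-9)
  }
})

test_that("multiple-mode posteriors are equivariant to cause relabeling", {
  d <- random_dataset(29, n = 90, p = 8, n_causes = 3, missing_rate = 0)
  m <- ssp(d, ssp_config(cluster_size = 2, cause_mode = "multiple",
                         n_partitions = 2, seed = 3))
  sc <- predict(m, d[1:10], type = "posterior")
  perm <- c(2, 3, 1)
  d2 <- d
  d2$cause_list <- d$cause_list[perm]
  m2 <- ssp(d2, ssp_config(cluster_size = 2, cause_mode = "multiple",
                           n_partitions = 2, seed = 3))
  sc2 <- predict(m2, d2[1:10], type = "posterior")
  expect_equal(sc2, sc[, perm], tolerance = 1e-9)
})

test_that("assignment uses descending score with cause-order tie-break", {
  sc <- rbind(c(0.7, 0.2, 0.1), c(0.4, 0.4, 0.4))
  colnames(sc) <- c("A", "B", "C")
  a2 <- assign_causes(sc, 2)
  expect_identical(a2[1, ], c("A", "B"))
  expect_identical(a2[2, ], c("A", "B"))  # full tie: cause-list order
  expect_identical(unname(assign_causes(sc, 1)[, 1]), c("A", "A"))
  expect_error(assign_causes(sc, 4), "more causes")
})

test_that("a concentrated prior dominates when its likelihood is positive", {
  d <- random_dataset(31, n = 60, p = 6, n_causes = 3, missing_rate = 0)
  m <- ssp(d, ssp_config(cluster_size = 1, cause_mode = "multiple",
                         prior = "kinglu", alpha = 0.01),
           prior_csmf = c(0.0001, 0.9998, 0.0001))
  sc <- predict(m, d[1:15], type = "posterior")
  expect_true(all(assign_causes(sc, 1) == d$cause_list[2]))
})

test_that("causes absent from training stay on the list, prior-driven", {
  d <- random_dataset(37, n = 50, p = 6, n_causes = 3)
  d$cause_list <- c(d$cause_list, "never_seen")
  expect_warning(m <- ssp(d, ssp_config(cluster_size = 2, n_partitions = 2)),
                 "zero training deaths")
  csmf <- predict(m, d[1:30], type = "csmf")
  expect_length(csmf, 4)
  expect_equal(sum(csmf), 1, tolerance = 1e-9)
  sc <- predict(m, d[1:30], type = "posterior")
  expect_true(all(is.finite(sc)))
})

test_that("the estimated CSMF is the assignment composition and sums to 1", {
  d <- random_dataset(41, n = 120, p = 10, n_causes = 4, missing_rate = 0.1)
  m <- ssp(d, ssp_config(cluster_size = 2, n_partitions = 3))
  te <- d[81:120]
  full <- predict(m, te, type = "full")
  expect_equal(sum(full$csmf), 1, tolerance = 1e-12)
  comp <- table(factor(full$assignment, d$cause_list)) / 40
  expect_equal(unname(full$csmf), as.numeric(comp))
  expect_identical(full$ranking[, 1], unname(full$assignment))
})

test_that("posterior_for_record returns ranked per-cause scores", {
  d <- random_dataset(43, n = 60, p = 8, n_causes = 3)
  m <- ssp(d, ssp_config(cluster_size = 2, n_partitions = 2))
  pr <- posterior_for_record(d[5], m)
  expect_named(pr$score, d$cause_list)
  expect_identical(pr$ranked_causes[1], unname(pr$score) |> which.max() |>
                     (\(i) d$cause_list[i])())
})

test_that("top-k models restrict each cause model to its own items", {
  d <- random_dataset(47, n = 150, p = 12, n_causes = 3, missing_rate = 0)
  m <- ssp(d, ssp_config(cluster_size = 2, item_set = "top_k", top_k = 5,
                         n_partitions = 2, seed = 5))
  expect_length(m$tables, 3)
  for (j in 1:3) {
    expect_setequal(m$tables[[j]]$item_ids, m$top_item_sets[[j]])
    expect_length(m$top_item_sets[[j]], 5)
  }
  sc <- predict(m, d[1:10], type = "posterior")
  expect_true(all(sc >= 0 & sc <= 1))
})

test_that("a well-separated synthetic population is recovered accurately", {
  spec <- phmrc_like_spec("adult", n_causes = 5, separation = 0.7, seed = 77,
                          n_deaths = 1500, true_csmf = c(0.35, 0.25, 0.2,
                                                         0.15, 0.05))
  ds <- generate_population(spec)
  train <- ds[1:1000]; test <- ds[1001:1500]
  m <- ssp(train, ssp_config())
  est <- predict(m, test, type = "csmf")
  truth <- table(factor(test$gold_cause, ds$cause_list)) / 500
  expect_true(all(abs(est - as.numeric(truth)) <= 0.05))
})
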