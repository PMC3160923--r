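test_that("chance-corrected concordance matches hand-computed values", {
  causes <- c("A", "B", "C")
  perfect <- chance_corrected_concordance(c("A", "B", "C", "A"),
                                          c("A", "B", "C", "A"), causes)
  expect_equal(unname(perfect$per_cause), rep(100, 3))
  expect_equal(perfect$mean, 100)
  # worked example: C_A = 0.5 with N = 3 -> (0.5 - 1/3)/(2/3) = 25%
  r <- chance_corrected_concordance(c("A", "A", "B", "C"),
                                    c("A", "B", "B", "C"), causes)
  expect_equal(unname(r$per_cause["A"]), 25)
  # chance-level sensitivity scores exactly zero
  n <- 3
  truth <- rep("A", n * 4)
  pred <- c(rep("A", 4), rep("B", 8))  # C_A = 1/3 = 1/N
  r0 <- chance_corrected_concordance(truth, pred, causes)
  expect_equal(unname(r0$per_cause["A"]), 0)
  # causes with zero true deaths are excluded from the average
  expect_true(is.na(r0$per_cause["C"]))
  expect_error(chance_corrected_concordance(c("A", "D"), c("A", "A"), causes),
               "not on cause list")
  expect_error(chance_corrected_concordance(character(0), character(0),
                                            causes), "nonempty")
})

test_that("uniform-random assignment centers average CCC at zero", {
  set.seed(202)
  causes <- paste0("c", 1:5)
  meds <- replicate(200, {
    truth <- sample(causes, 500, replace = TRUE,
                    prob = c(0.4, 0.25, 0.2, 0.1, 0.05))
    pred <- sample(causes, 500, replace = TRUE)
    chance_corrected_concordance(truth, pred, causes)$mean
  })
  expect_lt(abs(stats::median(meds)), 2)  # percent scale
})

test_that("CSMF accuracy matches its closed form and bounds", {
  expect_equal(csmf_accuracy(c(0.5, 0.3, 0.2), c(0.5, 0.3, 0.2)), 1.0)
  expect_equal(csmf_accuracy(c(0.5, 0.3, 0.2), c(0.3, 0.5, 0.2)), 0.75)
  # worst case: everything on the rarest true cause scores exactly 0
  expect_equal(csmf_accuracy(c(0.5, 0.3, 0.2), c(0, 0, 1)), 0)
  # brute-force check at N = 3 that no estimate scores below the worst case
  set.seed(7)
  truth <- c(0.5, 0.3, 0.2)
  worst <- min(replicate(2000, {
    e <- stats::rgamma(3, 0.2); csmf_accuracy(truth, e / sum(e))
  }))
  expect_gte(worst, 0)
  # invariant to cause relabeling; bounded in [0, 1]
  for (i in 1:20) {
    t <- stats::rgamma(4, 1); t <- t / sum(t)
    e <- stats::rgamma(4, 1); e <- e / sum(e)
    a <- csmf_accuracy(t, e)
    expect_gte(a, 0); expect_lte(a, 1)
    perm <- sample(4)
    expect_equal(csmf_accuracy(t[perm], e[perm]), a)
  }
})

test_that("CCC and CSMF accuracy are independent performance axes", {
  # a quota predictor reproduces the marginal composition exactly (CSMF
  # accuracy 1) while assigning individuals at chance (average CCC ~ 0)
  set.seed(99)
  causes <- paste0("c", 1:4)
  truth <- rep(causes, times = c(400, 300, 200, 100))
  quota <- sample(truth)  # same composition, random individuals
  est <- table(factor(quota, causes)) / length(quota)
  tru <- table(factor(truth, causes)) / length(truth)
  expect_equal(csmf_accuracy(as.numeric(tru), as.numeric(est)), 1.0)
  ccc <- chance_corrected_concordance(truth, quota, causes)
  expect_lt(abs(ccc$mean), 8)  # percent scale, single realization
})

test_that("Lin's concordance correlation matches direct evaluation", {
  tser <- cbind(a = c(0.1, 0.2, 0.3))
  eser <- cbind(a = c(0.1, 0.3, 0.2))
  expect_equal(unname(concordance_correlation_by_cause(tser, eser)), 0.5)
  # identical series with variance -> 1
  expect_equal(unname(concordance_correlation_by_cause(tser, tser)), 1.0)
  # anticorrelated through the means -> negative
  anti <- cbind(a = 0.4 - tser[, 1])
  expect_lt(unname(concordance_correlation_by_cause(tser, anti)), 0)
  # both series constant -> undefined
  const <- cbind(a = rep(0.2, 3))
  expect_true(is.na(concordance_correlation_by_cause(const, const)))
})

test_that("the CSMF regression recovers exact and planted relationships", {
  set.seed(31)
  x <- matrix(stats::runif(60, 0, 0.3), 60, 1, dimnames = list(NULL, "a"))
  fit <- fit_csmf_regression(x, x)
  expect_equal(fit$slope, 1, tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(fit$rmse, 0, tolerance = 1e-10)
  y <- 0.5 * x + 0.02
  fit2 <- fit_csmf_regression(x, y)
  expect_equal(fit2$slope, 0.5, tolerance = 1e-10)
  expect_equal(fit2$intercept, 0.02, tolerance = 1e-10)
  expect_equal(fit2$rmse, 0, tolerance = 1e-10)
  # noisy recovery within standard-error bounds
  noisy <- y + matrix(stats::rnorm(60, 0, 0.01), 60, 1)
  fit3 <- fit_csmf_regression(x, noisy)
  lmfit <- stats::lm(noisy[, 1] ~ x[, 1])
  se <- summary(lmfit)$coefficients[, "Std. Error"]
  expect_lt(abs(fit3$slope - 0.5), 3 * se[2])
  expect_lt(abs(fit3$intercept - 0.02), 3 * se[1])
  # constant truth -> undefined slope, rmse still reported
  const <- matrix(0.1, 60, 1, dimnames = list(NULL, "a"))
  fitc <- fit_csmf_regression(const, noisy)
  expect_true(is.na(fitc$slope))
  expect_gte(fitc$rmse, 0)
})

test_that("split summaries use median and 95% percentile interval", {
  s <- summarize_over_splits(rep(0.4, 10))
  expect_equal(c(s$median, s$ui_low, s$ui_high), rep(0.4, 3))
  s2 <- summarize_over_splits(1:100)
  expect_equal(s2$median, 50.5)
  expect_equal(s2$ui_low, stats::quantile(1:100, 0.025, names = FALSE))
  set.seed(5)
  v <- stats::rnorm(50)
  expect_identical(summarize_over_splits(v), summarize_over_splits(rev(v)))
  expect_identical(summarize_over_splits(v), summarize_over_splits(sample(v)))
  expect_true(s2$ui_low <= s2$median && s2$median <= s2$ui_high)
})
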