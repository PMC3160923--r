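# Shared fixture builders: everything is generated in code.

# a tiny handmade dataset: 5 items (2 HCE), 3 causes, 6 deaths
tiny_dataset <- function() {
  cat <- va_catalog(paste0("s", 1:5), module = "adult",
                    hce_flag = c(FALSE, TRUE, FALSE, FALSE, TRUE))
  resp <- rbind(c(1, 0, 1, NA, 0),
                c(0, 0, 1, 1, 1),
                c(1, 1, 0, 0, NA),
                c(0, NA, 0, 1, 1),
                c(1, 0, 1, 0, 0),
                c(0, 1, NA, 1, 1))
  va_dataset(resp, cat, cause_list = c("A", "B", "C"),
             death_id = paste0("d", 1:6),
             gold_cause = c("A", "B", "A", "C", "B", "C"))
}

# a random valid dataset for property tests
random_dataset <- function(seed, n = 20, p = 8, n_causes = 4,
                           missing_rate = 0.15) {
  set.seed(seed)
  cat <- va_catalog(sprintf("it%02d", 1:p), module = "child",
                    hce_flag = seq_len(p) %% 4 == 0)
  resp <- matrix(rbinom(n * p, 1, 0.4), n, p)
  resp[matrix(runif(n * p) < missing_rate, n, p)] <- NA
  causes <- paste0("cause", seq_len(n_causes))
  va_dataset(resp, cat, causes,
             gold_cause = sample(causes, n, replace = TRUE))
}

# training data whose per-item endorsement frequencies are exactly the
# product-Bernoulli probabilities in p (items x causes); every probability
# must be a multiple of 1/4 so pattern counts at n = 4^n_items are integral
exact_product_train <- function(p, module = "adult") {
  n_items <- nrow(p); n_causes <- ncol(p)
  n_per_cause <- 4^n_items
  patterns <- as.matrix(expand.grid(rep(list(0:1), n_items)))
  resp <- NULL; gold <- character(0)
  for (j in seq_len(n_causes)) {
    cnt <- apply(patterns, 1, function(s)
      round(n_per_cause * prod(ifelse(s == 1, p[, j], 1 - p[, j]))))
    stopifnot(sum(cnt) == n_per_cause)
    resp <- rbind(resp, patterns[rep(seq_len(nrow(patterns)), cnt), ,
                                 drop = FALSE])
    gold <- c(gold, rep(paste0("cause", j), n_per_cause))
  }
  cat <- va_catalog(sprintf("it%02d", seq_len(n_items)), module = module)
  colnames(resp) <- cat$item_id
  va_dataset(resp, cat, paste0("cause", seq_len(n_causes)), gold_cause = gold)
}
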