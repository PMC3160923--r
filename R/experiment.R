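# Validation protocol: Dirichlet-composition train/test splits and the
# variant grid.
#
# Each split stratifies the labeled deaths by cause into a candidate-train
# and candidate-test pool, draws a test cause composition from an
# uninformative Dirichlet(1, ..., 1), and resamples the candidate-test pool
# with replacement to realize that composition.  The training composition
# therefore always differs from the test composition, and no source death
# appears on both sides of a split, so metrics measure genuine
# generalization rather than memorized composition.

#' Generate Dirichlet-composition train/test splits
#'
#' @param dataset a labeled [va_dataset()].
#' @param n_splits number of splits (default 500).
#' @param train_fraction fraction of each cause's deaths placed in the
#'   candidate-train pool (default 0.75, stratified by cause).
#' @param test_size deaths per test set; defaults to the candidate-test
#'   pool size.
#' @param seed base seed; each split derives its own stream from it.
#' @return A list of class `split_list`; each element (class `va_split`)
#'   has `split_id`, `train_idx`, `test_idx` (indices into `dataset`, test
#'   indices drawn with replacement), `dirichlet_csmf`, `seed`.
#' @export
generate_splits <- function(dataset, n_splits = 500L, train_fraction = 0.75,
                            test_size = NULL, seed = 1L) {
  stopifnot(inherits(dataset, "va_dataset"), n_splits >= 1,
            train_fraction > 0, train_fraction < 1)
  causes <- dataset$cause_list
  N <- length(causes)
  labeled <- which(!is.na(dataset$gold_cause))
  if (!length(labeled)) stop("dataset has no gold causes")
  by_cause <- split(labeled, factor(dataset$gold_cause[labeled],
                                    levels = causes))
  thin <- names(by_cause)[vapply(by_cause, length, 1L) < 2]
  if (length(thin))
    warning("cause(s) with fewer than 2 deaths cannot populate both pools: ",
            paste(thin, collapse = ", "))
  lapply(seq_len(n_splits), function(s) {
    sseed <- derive_seed(seed, s)
    with_seed(sseed, {
      tr_pool <- integer(0); te_pool_by_cause <- vector("list", N)
      for (j in seq_len(N)) {
        idx <- by_cause[[j]]
        n_tr <- round(train_fraction * length(idx))
        n_tr <- max(min(n_tr, length(idx) - 1L), if (length(idx) > 1) 1L else 0L)
        pick <- if (length(idx)) sample(idx, n_tr) else integer(0)
        tr_pool <- c(tr_pool, pick)
        te_pool_by_cause[[j]] <- setdiff(idx, pick)
      }
      csmf <- stats::rgamma(N, 1)
      csmf <- csmf / sum(csmf)
      avail <- vapply(te_pool_by_cause, length, 1L) > 0
      draw <- csmf
      if (!all(avail)) {
        warning(sprintf("split %d: %d cause(s) absent from the test pool; %s",
                        s, sum(!avail),
                        "composition renormalized over available causes"))
        draw[!avail] <- 0
        draw <- draw / sum(draw)
      }
      n_test <- if (is.null(test_size)) sum(vapply(te_pool_by_cause, length, 1L))
                else as.integer(test_size)
      counts <- as.integer(stats::rmultinom(1, n_test, draw))
      te <- unlist(lapply(seq_len(N), function(j) {
        if (counts[j] == 0) return(integer(0))
        pool <- te_pool_by_cause[[j]]
        pool[sample.int(length(pool), counts[j], replace = TRUE)]
      }))
      structure(list(split_id = s, train_idx = sort(tr_pool), test_idx = te,
                     dirichlet_csmf = stats::setNames(csmf, causes),
                     seed = sseed),
                class = "va_split")
    })
  }) -> splits
  class(splits) <- "split_list"
  splits
}

## the gold-standard composition actually realized in a test set
realized_csmf <- function(test) {
  causes <- test$cause_list
  cnt <- tabulate(match(test$gold_cause, causes), nbins = length(causes))
  stats::setNames(cnt / sum(cnt), causes)
}

#' Run one SSP variant on one split
#'
#' Applies the HCE filter, fits the variant on the split's training deaths
#' (computing the tariff top-K sets from training only and, for King-Lu
#' variants, the prior from this split's training data and unlabeled test
#' patterns), predicts the test set and scores it.
#'
#' @param dataset a labeled [va_dataset()].
#' @param split one element of [generate_splits()].
#' @param variant an [ssp_config()].
#' @param include_hce keep health-care experience items? (default TRUE)
#' @return List: `split_id`, `csmf_accuracy`, `ccc_mean`, `ccc_per_cause`,
#'   `true_csmf`, `est_csmf`.
#' @export
run_variant <- function(dataset, split, variant, include_hce = TRUE) {
  stopifnot(inherits(split, "va_split"), inherits(variant, "ssp_config"))
  ds <- apply_hce_filter(dataset, include_hce)
  train <- ds[split$train_idx]
  test <- ds[split$test_idx]
  prior <- NULL
  if (variant$prior == "kinglu")
    prior <- split_kinglu_prior(train, test, split)
  cfg <- variant
  cfg$seed <- derive_seed(variant$seed, split$split_id)
  model <- ssp(train, cfg, prior_csmf = prior)
  score_split(model, test, split$split_id)
}

## King-Lu prior for a split: reads the test side stripped of labels, and
## derives its seed from the split only, so every variant of a split shares
## the same prior
split_kinglu_prior <- function(train, test, split) {
  unlab <- test
  unlab$gold_cause <- rep(NA_character_, n_deaths(test))
  kinglu_csmf(train, unlab, seed = derive_seed(split$seed, 7L))
}

score_split <- function(model, test, split_id) {
  pred <- predict(model, test, type = "full")
  truth <- test$gold_cause
  ccc <- chance_corrected_concordance(truth, pred$assignment,
                                      test$cause_list)
  tcs <- realized_csmf(test)
  list(split_id = split_id,
       csmf_accuracy = csmf_accuracy(tcs, pred$csmf),
       ccc_mean = ccc$mean, ccc_per_cause = ccc$per_cause,
       true_csmf = tcs, est_csmf = pred$csmf)
}

## fit signature shared by variants that differ only in cause mode / prior
fit_key <- function(cfg) {
  paste(cfg$cluster_size, cfg$item_set, cfg$top_k, cfg$n_partitions,
        cfg$alpha, cfg$missing, cfg$seed,
        if (cfg$item_set == "top_k") cfg$cause_mode else "shared", sep = "|")
}

#' Run a grid of SSP variants over many splits
#'
#' Executes every variant on every split and summarizes each metric with
#' the median and 95% uncertainty interval over splits.  Within a split,
#' work shared between variants is computed once: the King-Lu prior, the
#' tariff top-K sets, and the pattern-count fit shared by variants that
#' differ only in cause mode or prior.  Results are identical to running
#' [run_variant()] per variant.
#'
#' @param dataset a labeled [va_dataset()].
#' @param variants named list of [ssp_config()]s (default: all 12 legal
#'   variants via [ssp_variants()]).
#' @param splits a [generate_splits()] result, or NULL to generate
#'   `n_splits` splits from `seed`.
#' @param n_splits,seed,test_size used only when `splits` is NULL.
#' @param include_hce keep health-care experience items? (default TRUE)
#' @param verbose print per-split progress.
#' @return An object of class `ssp_grid`: `table` (one row per variant with
#'   median and UI of CSMF accuracy and mean CCC), plus per-split metric
#'   arrays (`accuracy`, `ccc`) and per-variant true/estimated CSMF series
#'   for regression and concordance analyses.
#' @export
run_variant_grid <- function(dataset, variants = ssp_variants(),
                             splits = NULL, n_splits = 100L, seed = 1L,
                             test_size = NULL, include_hce = TRUE,
                             verbose = FALSE) {
  stopifnot(length(variants) >= 1)
  if (is.null(splits))
    splits <- generate_splits(dataset, n_splits = n_splits, seed = seed,
                              test_size = test_size)
  ds <- apply_hce_filter(dataset, include_hce)
  V <- length(variants); S <- length(splits)
  vnames <- names(variants)
  if (is.null(vnames)) vnames <- sprintf("variant_%02d", seq_len(V))
  acc <- matrix(NA_real_, S, V, dimnames = list(NULL, vnames))
  ccc <- matrix(NA_real_, S, V, dimnames = list(NULL, vnames))
  causes <- dataset$cause_list
  tser <- array(NA_real_, c(S, length(causes), V),
                dimnames = list(NULL, causes, vnames))
  eser <- tser
  ccc_pc <- tser
  for (s in seq_len(S)) {
    split <- splits[[s]]
    train <- ds[split$train_idx]
    test <- ds[split$test_idx]
    kl <- NULL
    fits <- new.env(parent = emptyenv())
    if (verbose) message(sprintf("split %d/%d", s, S))
    for (v in seq_len(V)) {
      cfg <- variants[[v]]
      cfg$seed <- derive_seed(variants[[v]]$seed, split$split_id)
      if (cfg$prior == "kinglu" && is.null(kl))
        kl <- split_kinglu_prior(train, test, split)
      key <- fit_key(cfg)
      base <- fits[[key]]
      if (is.null(base)) {
        bcfg <- cfg
        bcfg$prior <- "uniform"
        base <- ssp(train, bcfg)
        fits[[key]] <- base
      }
      model <- reprior_ssp(base, cfg, kl)
      res <- score_split(model, test, split$split_id)
      acc[s, v] <- res$csmf_accuracy
      ccc[s, v] <- res$ccc_mean
      tser[s, , v] <- res$true_csmf
      eser[s, , v] <- res$est_csmf
      ccc_pc[s, , v] <- res$ccc_per_cause
    }
  }
  tab <- do.call(rbind, lapply(seq_len(V), function(v) {
    cfg <- variants[[v]]
    a <- summarize_over_splits(acc[, v]); cc <- summarize_over_splits(ccc[, v])
    data.frame(variant = vnames[v], cluster = cfg$cluster_size,
               cause_mode = cfg$cause_mode,
               symptoms = if (cfg$item_set == "top_k")
                 paste0("top", cfg$top_k) else "all",
               prior = cfg$prior,
               csmf_accuracy = a$median, csmf_accuracy_lo = a$ui_low,
               csmf_accuracy_hi = a$ui_high,
               ccc = cc$median, ccc_lo = cc$ui_low, ccc_hi = cc$ui_high,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(table = tab, accuracy = acc, ccc = ccc,
                 true_csmf = tser, est_csmf = eser, ccc_per_cause = ccc_pc,
                 n_splits = S, include_hce = include_hce),
            class = "ssp_grid")
}

#' Per-cause performance summary for one variant of a grid
#'
#' The cause-level view of a variant's results over the splits: median (95%
#' UI) chance-corrected concordance per cause, the slope, intercept and
#' RMSE of the estimated-on-true CSMF regression, and Lin's concordance
#' correlation between estimated and true fractions.
#'
#' @param grid a [run_variant_grid()] result.
#' @param variant name (or index) of a variant in the grid.
#' @return A `data.frame`, one row per cause.
#' @export
per_cause_summary <- function(grid, variant = 1L) {
  stopifnot(inherits(grid, "ssp_grid"))
  causes <- colnames(grid$true_csmf)
  tser <- grid$true_csmf[, , variant, drop = TRUE]
  eser <- grid$est_csmf[, , variant, drop = TRUE]
  reg <- fit_csmf_regression(tser, eser)
  lin <- concordance_correlation_by_cause(tser, eser)
  ccc <- grid$ccc_per_cause[, , variant, drop = TRUE]
  s <- apply(ccc, 2, function(v) {
    if (all(is.na(v))) c(median = NA_real_, ui_low = NA_real_,
                         ui_high = NA_real_)
    else unlist(summarize_over_splits(v))
  })
  data.frame(cause = causes, ccc_median = s["median", ],
             ccc_lo = s["ui_low", ], ccc_hi = s["ui_high", ],
             slope = reg$slope, intercept = reg$intercept, rmse = reg$rmse,
             lin_ccc = unname(lin), row.names = NULL,
             stringsAsFactors = FALSE)
}

## re-derive a fitted model under a different cause mode / prior without
## re-estimating the pattern tables (they do not depend on either axis)
reprior_ssp <- function(base, cfg, kl) {
  model <- base
  model$config <- cfg
  N <- length(model$cause_list)
  model$prior <-
    if (cfg$prior == "kinglu") stats::setNames(kl$csmf, model$cause_list)
    else if (cfg$cause_mode == "single")
      stats::setNames(rep(0.5, N), model$cause_list)
    else stats::setNames(rep(1 / N, N), model$cause_list)
  model
}

#' @export
print.ssp_grid <- function(x, digits = 3, ...) {
  cat(sprintf("SSP variant grid over %d splits (%s HCE)\n", x$n_splits,
              if (x$include_hce) "with" else "without"))
  tab <- x$table
  tab$csmf_accuracy <- sprintf(paste0("%.", digits, "f (%.", digits,
                                      "f, %.", digits, "f)"),
                               tab$csmf_accuracy, tab$csmf_accuracy_lo,
                               tab$csmf_accuracy_hi)
  tab$ccc <- sprintf("%.1f (%.1f, %.1f)", tab$ccc, tab$ccc_lo, tab$ccc_hi)
  print(tab[, c("cluster", "cause_mode", "symptoms", "prior",
                "csmf_accuracy", "ccc")], row.names = FALSE)
  invisible(x)
}

#' Write a variant-grid results table to CSV
#'
#' One row per variant with the design-axis keys and the median (95% UI)
#' of CSMF accuracy and mean chance-corrected concordance.
#'
#' @param grid an [run_variant_grid()] result.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(grid, path) {
  utils::write.csv(grid$table, path, row.names = FALSE)
  invisible(path)
}
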