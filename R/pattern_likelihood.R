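# Symptom-cluster pattern likelihoods.
#
# Items are partitioned into clusters of size c; the joint response pattern
# of a cluster is one likelihood factor, so c = 1 reduces to independent
# per-item (naive Bayes) factors while c > 1 lets the model exploit
# inter-item dependence.  Pattern probabilities conditional on a class
# (a cause, or the pooled "not this cause" complement) are estimated from
# training counts with additive smoothing:
#
#   P(pattern | class) = (count + alpha) / (n_class + alpha * n_patterns)
#
# where n_patterns is the pattern-space size of the cluster (2^size under
# the default missing-as-no rule, 3^size when missing is kept as a third
# symbol).  With alpha > 0 every pattern has positive probability and a
# class with zero training deaths falls back to the uniform 1/n_patterns.
# Several random partitions are drawn and the per-partition likelihoods are
# averaged on the probability scale (a mixture over partitions), computed
# stably from logs.

#' Random partitions of items into clusters
#'
#' Draws `n_partitions` independent uniformly random partitions of the item
#' set into clusters of `cluster_size` (plus one remainder cluster when the
#' item count is not a multiple).  `cluster_size = 1` has a single canonical
#' partition into singletons, so `n_partitions` is forced to 1.
#'
#' @param item_ids character vector of item ids.
#' @param cluster_size items per cluster (c).
#' @param n_partitions number of random partitions (R).
#' @param seed integer seed.
#' @return A list of class `cluster_partitions`; each element is a list of
#'   character vectors (the clusters of one partition).
#' @export
make_partitions <- function(item_ids, cluster_size, n_partitions = 50L,
                            seed = 1L) {
  item_ids <- as.character(item_ids)
  p <- length(item_ids)
  if (p == 0) stop("empty item list")
  stopifnot(cluster_size >= 1, n_partitions >= 1)
  if (cluster_size == 1) {
    parts <- list(as.list(item_ids))
  } else {
    sizes <- rep(cluster_size, p %/% cluster_size)
    if (p %% cluster_size) sizes <- c(sizes, p %% cluster_size)
    parts <- with_seed(seed, lapply(seq_len(n_partitions), function(r) {
      perm <- sample(item_ids)
      split(perm, rep(seq_along(sizes), sizes))
    }))
  }
  structure(parts, item_ids = item_ids,
            cluster_size = as.integer(cluster_size), seed = as.integer(seed),
            class = "cluster_partitions")
}

## ---- internal pattern machinery ------------------------------------------

## Map a response matrix (0/1/NA) to integer pattern ids for one partition.
## Returns a list: ids (n x n_clusters, values in 0..n_patterns-1) and
## n_patterns per cluster.  missing = "no" folds NA to 0 (base-2 patterns);
## missing = "third" keeps NA as symbol 2 (base-3 patterns).
partition_pattern_ids <- function(resp, clusters, missing = "no") {
  base <- if (missing == "third") 3L else 2L
  n <- nrow(resp)
  ids <- matrix(0L, n, length(clusters))
  np <- integer(length(clusters))
  for (k in seq_along(clusters)) {
    cols <- clusters[[k]]
    m <- resp[, cols, drop = FALSE]
    if (missing == "third") m[is.na(m)] <- 2L else m[is.na(m)] <- 0L
    ids[, k] <- as.integer(m %*% base^(seq_along(cols) - 1L))
    np[k] <- base^length(cols)
  }
  list(ids = ids, n_patterns = np)
}

## Per-cluster pattern counts by class via a single tabulate() pass.
## pat: vector of pattern ids (0-based); cls: class index 1..K (NA dropped).
class_pattern_counts <- function(pat, cls, n_classes, n_patterns) {
  keep <- !is.na(cls)
  cnt <- tabulate(pat[keep] + 1L + n_patterns * (cls[keep] - 1L),
                  nbins = n_patterns * n_classes)
  matrix(cnt, n_patterns, n_classes)
}

## ---- pattern probability tables ------------------------------------------

#' Estimate cluster-pattern probabilities from training data
#'
#' In `"multiple"` mode one table covers every cause on the cause list.  In
#' `"single"` mode the table has two classes: the chosen cause and the
#' pooled complement of all other labeled deaths.
#'
#' @param train a labeled [va_dataset()].
#' @param partitions a [make_partitions()] result over (a subset of) the
#'   dataset's items.
#' @param mode `"multiple"` or `"single"`.
#' @param cause the target cause (required in single mode).
#' @param alpha additive smoothing per pattern cell (default 0.001);
#'   `alpha = 0` keeps raw frequencies and permits zero probabilities.
#' @param missing `"no"` (fold missing responses to "no" when forming
#'   patterns; default) or `"third"` (treat missing as a third symbol).
#' @return An object of class `pattern_table` holding per-partition,
#'   per-cluster count matrices, class sizes, and the smoothing settings.
#' @export
estimate_pattern_probabilities <- function(train, partitions,
                                           mode = c("multiple", "single"),
                                           cause = NULL, alpha = 0.001,
                                           missing = c("no", "third")) {
  mode <- match.arg(mode)
  missing <- match.arg(missing)
  stopifnot(inherits(train, "va_dataset"),
            inherits(partitions, "cluster_partitions"), alpha >= 0)
  item_ids <- attr(partitions, "item_ids")
  if (!all(item_ids %in% colnames(train$responses)))
    stop("partition items not present in training data")
  if (mode == "single") {
    if (is.null(cause) || !(cause %in% train$cause_list))
      stop("single mode needs a cause from the cause list")
    classes <- c(cause, paste0("not:", cause))
    cls <- ifelse(is.na(train$gold_cause), NA_integer_,
                  ifelse(train$gold_cause == cause, 1L, 2L))
  } else {
    classes <- train$cause_list
    cls <- match(train$gold_cause, classes)
  }
  if (all(is.na(cls))) stop("training data has no gold causes")
  class_n <- tabulate(cls, nbins = length(classes))
  if (alpha == 0 && any(class_n == 0))
    stop("class with zero training deaths and alpha = 0: ",
         paste(classes[class_n == 0], collapse = ", "))
  resp <- train$responses
  tabs <- lapply(partitions, function(part) {
    pid <- partition_pattern_ids(resp, part, missing)
    counts <- lapply(seq_along(part), function(k)
      class_pattern_counts(pid$ids[, k], cls, length(classes),
                           pid$n_patterns[k]))
    list(counts = counts, n_patterns = pid$n_patterns)
  })
  structure(list(partitions = partitions, classes = classes,
                 class_n = class_n, tables = tabs, alpha = alpha,
                 missing = missing, item_ids = item_ids),
            class = "pattern_table")
}

#' Smoothed pattern probabilities for one cluster
#'
#' Expands the stored counts of one (partition, cluster) pair into the full
#' matrix of smoothed probabilities over the cluster's pattern space; each
#' column sums to 1 when `alpha > 0`.
#'
#' @param table a [estimate_pattern_probabilities()] result.
#' @param partition,cluster indices.
#' @return Matrix `n_patterns x n_classes`.
#' @export
pattern_prob_matrix <- function(table, partition = 1L, cluster = 1L) {
  tab <- table$tables[[partition]]
  cnt <- tab$counts[[cluster]]
  np <- tab$n_patterns[cluster]
  denom <- table$class_n + table$alpha * np
  pr <- sweep(cnt + table$alpha, 2, denom, `/`)
  # a class with no training deaths falls back to the uniform distribution
  empty <- table$class_n == 0
  if (any(empty)) pr[, empty] <- 1 / np
  dimnames(pr) <- list(as.character(seq_len(np) - 1L), table$classes)
  pr
}

## log pattern-probability lookup matrix for one (partition, cluster);
## columns restricted to class indices `j`
log_prob_lookup <- function(table, r, k, j = seq_along(table$classes)) {
  tab <- table$tables[[r]]
  np <- tab$n_patterns[k]
  cnt <- tab$counts[[k]][, j, drop = FALSE]
  n <- table$class_n[j]
  lp <- log(cnt + table$alpha) -
    rep(log(n + table$alpha * np), each = np)
  empty <- n == 0
  if (any(empty)) lp[, empty] <- -log(np)
  lp
}

## stable log of row means of exp(M): log( (1/R) * sum_r exp(M[, r]) )
log_row_mean_exp <- function(M) {
  if (ncol(M) == 1L) return(M[, 1L])
  mx <- apply(M, 1, max)
  mx[!is.finite(mx)] <- 0  # all -Inf rows stay -Inf
  mx + log(rowMeans(exp(M - mx)))
}

## Vectorized log-likelihood of every record in a response matrix under one
## class of a pattern table: average over partitions on the probability
## scale, returned on the log scale.  Returns n x length(j) matrix.
dataset_log_likelihood <- function(resp, table, j = seq_along(table$classes)) {
  R <- length(table$partitions)
  n <- nrow(resp)
  acc <- array(0, c(n, length(j), R))
  for (r in seq_len(R)) {
    part <- table$partitions[[r]]
    pid <- partition_pattern_ids(resp, part, table$missing)
    for (k in seq_along(part)) {
      lp <- log_prob_lookup(table, r, k, j)
      acc[, , r] <- acc[, , r] + lp[pid$ids[, k] + 1L, , drop = FALSE]
    }
  }
  out <- matrix(0, n, length(j))
  for (m in seq_along(j)) {
    M <- acc[, m, , drop = FALSE]
    dim(M) <- c(n, R)
    out[, m] <- log_row_mean_exp(M)
  }
  colnames(out) <- table$classes[j]
  out
}

#' Log-likelihood of a record's response pattern under a class
#'
#' For each random partition, the log-likelihood is the sum over clusters of
#' the log pattern probability; the per-partition likelihoods are then
#' averaged on the probability scale (computed stably from logs) and
#' returned as a log.  With `alpha = 0` an unseen pattern yields `-Inf`.
#'
#' @param record a single-record [va_dataset()], or a named 0/1/NA vector
#'   over (at least) the table's items.
#' @param table a [estimate_pattern_probabilities()] result.
#' @param target class label (a cause, or `"not:<cause>"` in single mode).
#' @return Log-likelihood (scalar; or vector if `record` is a multi-record
#'   dataset).
#' @export
record_log_likelihood <- function(record, table, target) {
  j <- match(target, table$classes)
  if (is.na(j)) stop("unknown target class: ", target)
  resp <- if (inherits(record, "va_dataset")) record$responses
          else matrix(record, 1, dimnames = list(NULL, names(record)))
  miss <- setdiff(table$item_ids, colnames(resp))
  if (length(miss)) stop("record does not cover the table's item set")
  storage.mode(resp) <- "integer"
  out <- dataset_log_likelihood(resp, table, j)
  unname(drop(out))
}
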