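# King-Lu-style direct CSMF estimation.
#
# The observed frequency of symptom patterns in an unlabeled test
# population is a mixture of the cause-conditional pattern frequencies with
# the population CSMF as the mixture weights:
#
#   q = M %*% pi        q: 2^B test pattern frequencies on an item subset,
#                       M: 2^B x N train pattern frequencies by cause.
#
# Solving min ||q - M pi||^2 subject to pi >= 0, sum(pi) = 1 on many random
# item subsets and averaging the solutions yields a direct CSMF estimate
# without assigning individual deaths.  With many causes (more than about
# 7-10) the systems become badly underdetermined and the estimate degrades,
# which is exactly why the uniform prior outperforms the King-Lu prior in
# large-cause-list SSP variants.

#' King-Lu direct CSMF estimation
#'
#' For each of `n_subsets` random item subsets of size `subset_size`, builds
#' the test pattern-frequency vector and the train cause-conditional
#' pattern-frequency matrix, solves the simplex-constrained least-squares
#' problem (nonnegative least squares with a weighted sum-to-one row,
#' followed by renormalization), and averages the per-subset solutions.
#' Missing responses are folded to "no" before pattern formation, matching
#' the pattern-likelihood default.
#'
#' @param train a labeled [va_dataset()].
#' @param test a [va_dataset()] over the same items; labels are not read.
#' @param subset_size items per subset, B (default 4, so 16 patterns per
#'   system).
#' @param n_subsets number of random subsets averaged (default 300).
#' @param seed integer seed.
#' @return An object of class `kinglu_estimate`: `csmf` (named simplex),
#'   `per_subset` (matrix of per-subset solutions), `subset_size`,
#'   `n_subsets`.
#' @export
kinglu_csmf <- function(train, test, subset_size = 4L, n_subsets = 300L,
                        seed = 1L) {
  stopifnot(inherits(train, "va_dataset"), inherits(test, "va_dataset"))
  causes <- train$cause_list
  N <- length(causes)
  if (N == 1) {
    csmf <- stats::setNames(1, causes)
    return(structure(list(csmf = csmf, per_subset = matrix(1, 1, 1),
                          subset_size = subset_size, n_subsets = 0L),
                     class = "kinglu_estimate"))
  }
  B <- as.integer(subset_size)
  stopifnot(B >= 1, n_subsets >= 1)
  if (N > 2^B)
    warning(sprintf(paste0("%d causes exceed the %d patterns per subset; ",
                           "the systems are underdetermined and the ",
                           "estimate may be poor"), N, 2^B))
  items <- intersect(train$catalog$item_id, test$catalog$item_id)
  if (length(items) < B) stop("fewer shared items than subset_size")
  cls <- match(train$gold_cause, causes)
  if (all(is.na(cls))) stop("training data has no gold causes")
  n_by_cause <- tabulate(cls, nbins = N)
  tr <- train$responses[, items, drop = FALSE]
  te <- test$responses[, items, drop = FALSE]
  tr[is.na(tr)] <- 0L
  te[is.na(te)] <- 0L
  pow <- 2^(seq_len(B) - 1L)
  sols <- with_seed(seed, {
    vapply(seq_len(n_subsets), function(s) {
      sub <- sample.int(length(items), B)
      pat_tr <- as.integer(tr[, sub, drop = FALSE] %*% pow)
      pat_te <- as.integer(te[, sub, drop = FALSE] %*% pow)
      q <- tabulate(pat_te + 1L, nbins = 2^B) / nrow(te)
      M <- class_pattern_counts(pat_tr, cls, N, 2^B)
      M <- sweep(M, 2, pmax(n_by_cause, 1L), `/`)
      # a cause with no training deaths contributes an uninformative
      # uniform pattern column rather than an all-zero one
      if (any(n_by_cause == 0)) M[, n_by_cause == 0] <- 1 / 2^B
      solve_simplex_ls(M, q)
    }, numeric(N))
  })
  sols <- matrix(sols, nrow = N)
  csmf <- rowMeans(sols)
  csmf <- pmax(csmf, 0)
  csmf <- csmf / sum(csmf)
  names(csmf) <- causes
  structure(list(csmf = csmf, per_subset = t(sols), subset_size = B,
                 n_subsets = as.integer(n_subsets)),
            class = "kinglu_estimate")
}

## min ||q - M pi||^2, pi >= 0, sum(pi) = 1: Lawson-Hanson NNLS on the
## system augmented with a heavily weighted sum-to-one row, then
## renormalized onto the simplex.
solve_simplex_ls <- function(M, q, weight = 100) {
  A <- rbind(M, rep(weight, ncol(M)))
  b <- c(q, weight)
  x <- tryCatch(pracma::lsqnonneg(A, b)$x, error = function(e) NULL)
  if (is.null(x) || all(x <= 0) || any(!is.finite(x)))
    return(rep(1 / ncol(M), ncol(M)))
  x / sum(x)
}

#' @export
print.kinglu_estimate <- function(x, ...) {
  cat(sprintf("King-Lu direct CSMF estimate (B = %d, %d subsets)\n",
              x$subset_size, x$n_subsets))
  print(round(x$csmf, 4))
  invisible(x)
}
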