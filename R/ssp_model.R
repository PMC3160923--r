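# The Simplified Symptom Pattern (SSP) classifier.
#
# Bayes' theorem applied to cause-of-death analysis:
#
#   P(D = j | S) = P(S | D = j) P(D = j) / sum_m P(S | D = m) P(D = m)
#
# with S the joint response pattern on clusters of items.  Four design axes
# define the variant space: cluster size (10 vs 1), cause-model mode (one
# binary cause-vs-not-cause model per cause vs one model over all causes),
# item set (all items vs each cause's top-K by |tariff|), and prior
# (uniform vs King-Lu direct CSMF estimate).  Top-K item selection is only
# meaningful for single-cause models, leaving 12 legal variants.

#' SSP variant configuration
#'
#' @param cluster_size items per symptom cluster (default 10; 1 gives the
#'   independence model).
#' @param cause_mode `"single"` (one binary cause-vs-not-cause model per
#'   cause; the final cause is the one with the highest posterior across
#'   models) or `"multiple"` (one model over all causes at once).
#' @param item_set `"all"` or `"top_k"` (each cause model restricted to the
#'   cause's top `top_k` items by absolute tariff; single mode only).
#' @param top_k items per cause when `item_set = "top_k"` (default 40).
#' @param prior `"uniform"` or `"kinglu"` (a King-Lu direct CSMF estimate
#'   supplied at fit time).
#' @param n_partitions random cluster partitions averaged over (default 50;
#'   forced to 1 when `cluster_size = 1`).
#' @param alpha additive smoothing per pattern cell (default 0.001).
#' @param missing missing-response rule at pattern formation: `"no"` or
#'   `"third"` (see [estimate_pattern_probabilities()]).
#' @param seed integer seed controlling the random partitions.
#' @return An object of class `ssp_config`.
#' @export
ssp_config <- function(cluster_size = 10L, cause_mode = c("single", "multiple"),
                       item_set = c("all", "top_k"), top_k = 40L,
                       prior = c("uniform", "kinglu"), n_partitions = 50L,
                       alpha = 0.001, missing = c("no", "third"), seed = 1L) {
  cause_mode <- match.arg(cause_mode)
  item_set <- match.arg(item_set)
  prior <- match.arg(prior)
  missing <- match.arg(missing)
  stopifnot(cluster_size >= 1, top_k >= 1, n_partitions >= 1, alpha >= 0)
  if (item_set == "top_k" && cause_mode != "single")
    stop("item_set = \"top_k\" is only meaningful for single-cause models")
  if (cluster_size == 1) n_partitions <- 1L
  structure(list(cluster_size = as.integer(cluster_size),
                 cause_mode = cause_mode, item_set = item_set,
                 top_k = as.integer(top_k), prior = prior,
                 n_partitions = as.integer(n_partitions), alpha = alpha,
                 missing = missing, seed = as.integer(seed)),
            class = "ssp_config")
}

#' @export
print.ssp_config <- function(x, ...) {
  cat(sprintf("SSP variant: cluster %d | %s-cause | %s%s | %s prior\n",
              x$cluster_size, x$cause_mode,
              if (x$item_set == "top_k") paste0("top ", x$top_k, " items")
              else "all items", "", x$prior))
  cat(sprintf("  n_partitions %d, alpha %g, missing->%s, seed %d\n",
              x$n_partitions, x$alpha, x$missing, x$seed))
  invisible(x)
}

#' All 12 legal SSP variants
#'
#' Enumerates the design grid: cluster size {10, 1} x cause mode
#' {single, multiple} x item set {all, top_k} x prior {uniform, kinglu},
#' dropping the four illegal top_k-with-multiple combinations.
#'
#' @param cluster_sizes the two cluster sizes contrasted (default `c(10, 1)`).
#' @param ... overrides passed to every [ssp_config()] (e.g.
#'   `n_partitions`, `alpha`, `seed`).
#' @return Named list of 12 `ssp_config` objects.
#' @export
ssp_variants <- function(cluster_sizes = c(10L, 1L), ...) {
  out <- list()
  for (cl in cluster_sizes) for (mode in c("single", "multiple"))
    for (items in c("top_k", "all")) for (pr in c("uniform", "kinglu")) {
      if (items == "top_k" && mode == "multiple") next
      nm <- sprintf("c%d_%s_%s_%s", cl, mode,
                    if (items == "top_k") "top40" else "all", pr)
      out[[nm]] <- ssp_config(cluster_size = cl, cause_mode = mode,
                              item_set = items, prior = pr, ...)
    }
  out
}

#' Fit a Simplified Symptom Pattern model
#'
#' Learns the empirical cluster-pattern probabilities `P(S | D = j)` from a
#' gold-standard training dataset under one variant configuration.  Causes
#' present on the cause list but absent from training are retained: their
#' likelihood falls back to the uniform distribution over each cluster's
#' pattern space, leaving them effectively prior-driven rather than
#' silently excluded.
#'
#' @param train a labeled [va_dataset()].
#' @param config an [ssp_config()].
#' @param prior_csmf a CSMF simplex over the training cause list (or a
#'   [kinglu_csmf()] result); required iff `config$prior == "kinglu"`.
#' @return An object of class `ssp`.
#' @seealso [predict.ssp()], [assign_causes()]
#' @export
ssp <- function(train, config = ssp_config(), prior_csmf = NULL) {
  stopifnot(inherits(train, "va_dataset"), inherits(config, "ssp_config"))
  if (n_deaths(train) == 0 || all(is.na(train$gold_cause)))
    stop("training data must be nonempty and labeled")
  causes <- train$cause_list
  N <- length(causes)
  n_by_cause <- tabulate(match(train$gold_cause, causes), nbins = N)
  if (any(n_by_cause == 0))
    warning("cause(s) with zero training deaths (prior-driven): ",
            paste(causes[n_by_cause == 0], collapse = ", "))

  if (config$prior == "kinglu") {
    if (inherits(prior_csmf, "kinglu_estimate")) prior_csmf <- prior_csmf$csmf
    if (is.null(prior_csmf) || length(prior_csmf) != N)
      stop("prior = \"kinglu\" requires a prior_csmf over the cause list")
    prior <- as.numeric(prior_csmf) / sum(prior_csmf)
  } else {
    # uniform: 1/N over causes in the joint model; a 50/50 class prior in
    # each binary cause-vs-not-cause model
    prior <- if (config$cause_mode == "single") rep(0.5, N) else rep(1 / N, N)
  }
  names(prior) <- causes

  top_sets <- NULL
  if (config$item_set == "top_k")
    top_sets <- select_top_items(tariff_scores(endorsement_rates(train)),
                                 config$top_k)

  if (config$item_set == "all") {
    # one partition set shared by every cause model: in single mode the
    # per-cause models differ only in the class split, not the item set
    parts <- make_partitions(train$catalog$item_id, config$cluster_size,
                             config$n_partitions, derive_seed(config$seed, 0))
    table <- estimate_pattern_probabilities(train, parts, mode = "multiple",
                                            alpha = config$alpha,
                                            missing = config$missing)
    tables <- NULL
  } else {
    table <- NULL
    tables <- lapply(seq_len(N), function(j) {
      parts <- make_partitions(top_sets[[j]], config$cluster_size,
                               config$n_partitions,
                               derive_seed(config$seed, j))
      estimate_pattern_probabilities(train, parts, mode = "single",
                                     cause = causes[j], alpha = config$alpha,
                                     missing = config$missing)
    })
    names(tables) <- causes
  }

  structure(list(config = config, cause_list = causes, catalog = train$catalog,
                 prior = prior, n_by_cause = n_by_cause,
                 n_train = sum(n_by_cause), table = table, tables = tables,
                 top_item_sets = top_sets),
            class = "ssp")
}

#' @export
print.ssp <- function(x, ...) {
  cat("Simplified Symptom Pattern model\n")
  print(x$config)
  cat(sprintf("  trained on %d deaths, %d causes, %d items (%s module)\n",
              x$n_train, length(x$cause_list), nrow(x$catalog),
              x$catalog$module[1]))
  invisible(x)
}

#' @export
summary.ssp <- function(object, ...) {
  out <- list(config = object$config,
              train_composition = object$n_by_cause / object$n_train,
              prior = object$prior, n_train = object$n_train)
  names(out$train_composition) <- object$cause_list
  class(out) <- "summary.ssp"
  out
}

#' @export
print.summary.ssp <- function(x, ...) {
  print(x$config)
  cat(sprintf("Training deaths: %d\n", x$n_train))
  cat("Training composition vs prior:\n")
  print(round(rbind(train = x$train_composition, prior = x$prior), 4))
  invisible(x)
}

## ---- posterior computation -----------------------------------------------

## Single-cause posteriors from a shared multi-class table: for each cause j
## the complement counts are total - count_j, so one pass over the
## (partition, cluster) tables serves all N binary models at once.
single_mode_posteriors_shared <- function(resp, table, prior) {
  R <- length(table$partitions)
  n <- nrow(resp); N <- length(table$classes)
  n_lab <- sum(table$class_n)
  acc_j <- array(0, c(n, N, R))
  acc_not <- array(0, c(n, N, R))
  alpha <- table$alpha
  for (r in seq_len(R)) {
    part <- table$partitions[[r]]
    pid <- partition_pattern_ids(resp, part, table$missing)
    for (k in seq_along(part)) {
      cnt <- table$tables[[r]]$counts[[k]]
      np <- table$tables[[r]]$n_patterns[k]
      tot <- rowSums(cnt)
      lpj <- log(cnt + alpha) -
        rep(log(table$class_n + alpha * np), each = np)
      lpn <- log(tot - cnt + alpha) -
        rep(log(n_lab - table$class_n + alpha * np), each = np)
      empty <- table$class_n == 0
      if (any(empty)) lpj[, empty] <- -log(np)
      full <- table$class_n == n_lab
      if (any(full)) lpn[, full] <- -log(np)
      idx <- pid$ids[, k] + 1L
      acc_j[, , r] <- acc_j[, , r] + lpj[idx, , drop = FALSE]
      acc_not[, , r] <- acc_not[, , r] + lpn[idx, , drop = FALSE]
    }
  }
  collapse <- function(acc, m) {
    M <- acc[, m, , drop = FALSE]; dim(M) <- c(n, R); log_row_mean_exp(M)
  }
  score <- matrix(NA_real_, n, N, dimnames = list(NULL, table$classes))
  for (m in seq_len(N)) {
    llj <- collapse(acc_j, m); lln <- collapse(acc_not, m)
    score[, m] <- binary_posterior(llj, lln, prior[m])
  }
  score
}

## posterior of the positive class of a binary model on the log scale
binary_posterior <- function(ll_pos, ll_neg, prior_pos) {
  if (prior_pos <= 0) return(rep(0, length(ll_pos)))
  if (prior_pos >= 1) return(rep(1, length(ll_pos)))
  d <- (log(1 - prior_pos) + ll_neg) - (log(prior_pos) + ll_pos)
  out <- 1 / (1 + exp(d))
  out[is.nan(out)] <- NA_real_  # both likelihoods zero: degenerate signal
  out
}

#' Per-death cause posteriors, assignments and CSMF from an SSP model
#'
#' In multiple mode, scores are the normalized posterior over the cause
#' list.  In single mode each cause's score is the posterior of its own
#' binary cause-vs-not-cause model; scores are compared across causes
#' without renormalization, and the assigned cause is the one with the
#' highest posterior.  Ties are broken by cause-list order.  The estimated
#' CSMF is the fraction of test deaths assigned to each cause (top-1),
#' including zero entries for causes never assigned.
#'
#' @param object an [ssp()] model.
#' @param newdata a [va_dataset()] over the model's catalog.
#' @param type `"posterior"` (score matrix), `"class"` (top-1 assignment),
#'   `"csmf"` (estimated cause fractions) or `"full"` (all three plus the
#'   full ranking).
#' @param ... ignored.
#' @return See `type`.
#' @export
predict.ssp <- function(object, newdata,
                        type = c("posterior", "class", "csmf", "full"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "va_dataset"))
  if (n_deaths(newdata) == 0) stop("empty test set")
  need <- if (object$config$item_set == "all") object$catalog$item_id
          else unique(unlist(object$top_item_sets))
  miss <- setdiff(need, colnames(newdata$responses))
  if (length(miss)) stop("test data missing model items: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  resp <- newdata$responses
  causes <- object$cause_list
  if (object$config$cause_mode == "multiple") {
    ll <- dataset_log_likelihood(resp, object$table)
    lu <- sweep(ll, 2, log(object$prior), `+`)
    mx <- apply(lu, 1, max)
    bad <- !is.finite(mx)
    mx[bad] <- 0
    w <- exp(lu - mx)
    score <- w / rowSums(w)
    if (any(bad)) score[bad, ] <- NA_real_  # degenerate: all likelihoods zero
    colnames(score) <- causes
  } else if (object$config$item_set == "all") {
    score <- single_mode_posteriors_shared(resp, object$table, object$prior)
  } else {
    score <- matrix(NA_real_, nrow(resp), length(causes),
                    dimnames = list(NULL, causes))
    for (j in seq_along(causes)) {
      ll <- dataset_log_likelihood(resp, object$tables[[j]])
      score[, j] <- binary_posterior(ll[, 1], ll[, 2], object$prior[j])
    }
  }
  if (type == "posterior") return(score)
  assign1 <- assign_causes(score, 1L)[, 1]
  if (type == "class") return(assign1)
  csmf <- tabulate(match(assign1, causes), nbins = length(causes)) /
    length(assign1)
  names(csmf) <- causes
  if (type == "csmf") return(csmf)
  list(posterior = score, assignment = assign1, csmf = csmf,
       ranking = assign_causes(score, length(causes)))
}

#' Posterior scores for a single record
#'
#' @param record a single-record [va_dataset()].
#' @param model an [ssp()] model.
#' @return List with `score` (named per-cause scores) and `ranked_causes`.
#' @export
posterior_for_record <- function(record, model) {
  sc <- predict(model, record, type = "posterior")
  list(score = sc[1, ],
       ranked_causes = colnames(sc)[order(-sc[1, ], seq_len(ncol(sc)))])
}

#' Assign the top-n causes of death from posterior scores
#'
#' The highest posterior is assigned first, the second highest next, and so
#' on; ties are broken deterministically by cause-list order.
#'
#' @param posteriors score matrix (deaths x causes) as returned by
#'   `predict(model, data, type = "posterior")`.
#' @param n_causes_to_assign how many causes to assign per death.
#' @return Character matrix, deaths x `n_causes_to_assign`, ranked.
#' @export
assign_causes <- function(posteriors, n_causes_to_assign = 1L) {
  posteriors <- as.matrix(posteriors)
  N <- ncol(posteriors)
  if (n_causes_to_assign > N) stop("cannot assign more causes than exist")
  causes <- colnames(posteriors)
  out <- apply(posteriors, 1, function(s) {
    s[is.na(s)] <- -Inf
    causes[order(-s, seq_len(N))[seq_len(n_causes_to_assign)]]
  })
  if (is.null(dim(out))) matrix(out, ncol = 1) else t(out)
}
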