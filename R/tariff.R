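# Tariff item ranking: robust Z scores of item endorsement by cause.
#
# The tariff of item i for cause j measures how unusual cause j's
# endorsement of item i is relative to the other causes:
#   tariff[i, j] = (x[i, j] - median_j' x[i, j']) / IQR_j' x[i, j'])
# where x is the endorsement fraction.  Large |tariff| marks an item as
# informative for that cause; the single-cause SSP variants can restrict
# each cause model to the cause's top-K items by |tariff|.

#' Cause-conditional endorsement fractions
#'
#' `x[i, j]` is the fraction of gold-standard cause-j training deaths that
#' endorsed item i, among deaths with a non-missing response on item i.
#' Causes with zero training deaths, and (item, cause) cells whose responses
#' are all missing, are `NaN` (an explicit undefined marker, never 0).
#'
#' @param train a labeled [va_dataset()].
#' @return A list of class `endorsement_matrix`: `x` (items x causes) and
#'   `n_by_cause` (training deaths per cause).
#' @export
endorsement_rates <- function(train) {
  stopifnot(inherits(train, "va_dataset"))
  if (all(is.na(train$gold_cause))) stop("training data has no gold causes")
  causes <- train$cause_list
  resp <- train$responses
  x <- matrix(NaN, ncol(resp), length(causes),
              dimnames = list(colnames(resp), causes))
  n_by_cause <- integer(length(causes))
  names(n_by_cause) <- causes
  for (j in seq_along(causes)) {
    rows <- which(!is.na(train$gold_cause) & train$gold_cause == causes[j])
    n_by_cause[j] <- length(rows)
    if (!length(rows)) next
    sub <- resp[rows, , drop = FALSE]
    yes <- colSums(sub == 1L, na.rm = TRUE)
    denom <- colSums(!is.na(sub))
    x[, j] <- ifelse(denom > 0, yes / denom, NaN)
  }
  structure(list(x = x, n_by_cause = n_by_cause),
            class = "endorsement_matrix")
}

#' Tariff scores from an endorsement matrix
#'
#' Centers each item row at its median across causes and scales by the
#' interquartile range, computed with linear interpolation between order
#' statistics (the convention is recorded in the output).  Undefined
#' endorsement cells are excluded from their row's median and IQR and get
#' tariff 0.  Rows with zero IQR (the item does not discriminate between
#' causes) get tariff 0 throughout.
#'
#' @param x an [endorsement_rates()] result, or a plain items-by-causes
#'   matrix of endorsement fractions.
#' @return A list of class `tariff_matrix`: `tariff` (items x causes) and
#'   `quantile_convention`.
#' @export
tariff_scores <- function(x) {
  m <- if (inherits(x, "endorsement_matrix")) x$x else as.matrix(x)
  if (ncol(m) < 2) stop("tariff needs at least 2 causes")
  tariff <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    row <- m[i, ]
    ok <- is.finite(row)
    if (sum(ok) < 2) next
    med <- stats::median(row[ok])
    iqr <- diff(stats::quantile(row[ok], c(0.25, 0.75), names = FALSE,
                                type = 7))
    if (iqr > 0) tariff[i, ok] <- (row[ok] - med) / iqr
  }
  structure(list(tariff = tariff, quantile_convention = "type7_linear_interpolation"),
            class = "tariff_matrix")
}

#' Top-K informative items per cause
#'
#' Ranks items for each cause by descending |tariff|; ties are broken by
#' catalog (row) order, so the output is stable across runs and record
#' orderings.  If fewer than `k` items exist, all are returned.
#'
#' @param t a [tariff_scores()] result.
#' @param k number of items to keep per cause (default 40).
#' @return A list of class `top_item_sets`: per cause, an ordered character
#'   vector of item ids; attribute `k`.
#' @export
select_top_items <- function(t, k = 40L) {
  stopifnot(inherits(t, "tariff_matrix"), k >= 1)
  tt <- t$tariff
  sets <- lapply(seq_len(ncol(tt)), function(j) {
    ord <- order(-abs(tt[, j]), seq_len(nrow(tt)))
    rownames(tt)[ord[seq_len(min(k, nrow(tt)))]]
  })
  names(sets) <- colnames(tt)
  structure(sets, k = as.integer(k), class = "top_item_sets")
}

#' Export tariff scores as a data frame
#'
#' @param x a `tariff_matrix`.
#' @param ... ignored.
#' @export
as.data.frame.tariff_matrix <- function(x, ...) {
  out <- as.data.frame(x$tariff)
  out <- cbind(data.frame(item_id = rownames(x$tariff),
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}
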