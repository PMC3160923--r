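# Performance metrics for verbal-autopsy validation.
#
# Individual-level: chance-corrected concordance (CCC), per-cause
# sensitivity rescaled so random assignment over N causes scores 0 and
# perfect assignment 100%.  Population-level: CSMF accuracy, normalized so
# the worst possible estimate (all mass on the rarest true cause) scores 0;
# Lin's concordance correlation between estimated and true cause fractions
# across splits; and the estimated-versus-true CSMF regression whose slope,
# intercept and RMSE characterise systematic over/under-estimation by cause.

#' Chance-corrected concordance
#'
#' For cause j with at least one true death, `CCC_j = (C_j - 1/N) /
#' (1 - 1/N)` where `C_j` is the sensitivity `TP_j / (TP_j + FN_j)` and N
#' the cause-list size.  Causes with zero true deaths are excluded from the
#' average (their sensitivity is undefined).  Reported in percent.
#'
#' @param truth character vector of true causes.
#' @param predicted character vector of predicted causes, aligned with
#'   `truth`.
#' @param cause_list the full cause list (defines N).
#' @return List: `per_cause` (named percent values, NA where no true
#'   deaths) and `mean` (average percent over causes with true deaths).
#' @export
chance_corrected_concordance <- function(truth, predicted, cause_list) {
  if (!length(truth) || length(truth) != length(predicted))
    stop("truth and predicted must be nonempty and aligned")
  bad <- setdiff(truth, cause_list)
  if (length(bad)) stop("cause in truth not on cause list: ",
                        paste(bad, collapse = ", "))
  N <- length(cause_list)
  per <- stats::setNames(rep(NA_real_, N), cause_list)
  for (j in seq_len(N)) {
    is_j <- truth == cause_list[j]
    if (!any(is_j)) next
    C_j <- mean(predicted[is_j] == cause_list[j])
    per[j] <- 100 * (C_j - 1 / N) / (1 - 1 / N)
  }
  list(per_cause = per, mean = mean(per, na.rm = TRUE))
}

#' CSMF accuracy
#'
#' `1 - sum_j |true_j - est_j| / (2 * (1 - min_j true_j))`: 1 when the
#' estimated cause fractions equal the truth, 0 for the worst possible
#' estimate (all mass on the cause with the smallest true fraction).
#' Reported as a proportion.
#'
#' @param true_csmf,est_csmf simplex vectors over the same cause list (if
#'   both are named, names must match).
#' @return Numeric in \[0, 1\].
#' @export
csmf_accuracy <- function(true_csmf, est_csmf) {
  if (length(true_csmf) != length(est_csmf))
    stop("CSMF vectors must cover the same cause list")
  if (!is.null(names(true_csmf)) && !is.null(names(est_csmf))) {
    if (!setequal(names(true_csmf), names(est_csmf)))
      stop("CSMF vectors must cover the same cause list")
    est_csmf <- est_csmf[names(true_csmf)]
  }
  1 - sum(abs(true_csmf - est_csmf)) / (2 * (1 - min(true_csmf)))
}

#' Lin's concordance correlation of estimated vs true CSMFs, by cause
#'
#' Across validation splits, measures per cause how closely the estimated
#' fraction tracks the true fraction along the identity line:
#' `ccc = 2 s_xy / (s_x^2 + s_y^2 + (mean_x - mean_y)^2)` with moments on
#' the 1/n convention.  Causes whose two series are both constant get `NA`
#' (undefined).
#'
#' @param true_series,est_series matrices, splits x causes.
#' @return Named numeric vector, one coefficient per cause.
#' @export
concordance_correlation_by_cause <- function(true_series, est_series) {
  true_series <- as.matrix(true_series); est_series <- as.matrix(est_series)
  if (!all(dim(true_series) == dim(est_series)))
    stop("series must have identical dimensions")
  if (nrow(true_series) < 2) stop("need at least 2 splits")
  n <- nrow(true_series)
  out <- vapply(seq_len(ncol(true_series)), function(j) {
    x <- true_series[, j]; y <- est_series[, j]
    sx <- mean((x - mean(x))^2); sy <- mean((y - mean(y))^2)
    sxy <- mean((x - mean(x)) * (y - mean(y)))
    denom <- sx + sy + (mean(x) - mean(y))^2
    if (denom == 0) NA_real_ else 2 * sxy / denom
  }, numeric(1))
  names(out) <- colnames(true_series)
  out
}

#' Regression of estimated on true CSMF, by cause
#'
#' Ordinary least squares of the estimated fraction on the true fraction
#' across splits, per cause.  The intercept is the fraction the method
#' would report for a cause with no true deaths; a slope below 1 marks
#' systematic underestimation of large fractions; the RMSE (root mean
#' squared residual, 1/n convention) measures the spread of estimates at a
#' given true fraction.
#'
#' @param true_series,est_series matrices, splits x causes (at least 3
#'   splits).
#' @return A `data.frame` with columns `cause`, `slope`, `intercept`,
#'   `rmse`; slope/intercept are NA when the true series is constant.
#' @export
fit_csmf_regression <- function(true_series, est_series) {
  true_series <- as.matrix(true_series); est_series <- as.matrix(est_series)
  if (!all(dim(true_series) == dim(est_series)))
    stop("series must have identical dimensions")
  if (nrow(true_series) < 3) stop("need at least 3 splits")
  causes <- colnames(true_series)
  if (is.null(causes)) causes <- sprintf("cause_%02d", seq_len(ncol(true_series)))
  rows <- lapply(seq_len(ncol(true_series)), function(j) {
    x <- true_series[, j]; y <- est_series[, j]
    if (stats::var(x) == 0)
      return(data.frame(cause = causes[j], slope = NA_real_,
                        intercept = NA_real_,
                        rmse = sqrt(mean((y - mean(y))^2))))
    fit <- stats::lm(y ~ x)
    data.frame(cause = causes[j], slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               rmse = sqrt(mean(stats::residuals(fit)^2)))
  })
  do.call(rbind, rows)
}

#' Median and 95% uncertainty interval over splits
#'
#' Summarizes split-level metric values with the median and the 2.5th and
#' 97.5th percentiles (linear-interpolation quantiles, type 7).
#'
#' @param values numeric vector of per-split values.
#' @return List with `median`, `ui_low`, `ui_high`.
#' @export
summarize_over_splits <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("no values to summarize")
  q <- stats::quantile(values, c(0.025, 0.975), names = FALSE, type = 7,
                       na.rm = TRUE)
  list(median = stats::median(values, na.rm = TRUE),
       ui_low = q[1], ui_high = q[2])
}
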