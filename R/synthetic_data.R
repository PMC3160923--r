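# Synthetic verbal-autopsy populations with known cause-conditional
# symptom structure.
#
# The generator emulates the structure of a dichotomized multi-site
# gold-standard VA study: a fixed item catalog per age module, a true CSMF
# over the cause list, cause-conditional endorsement probabilities per item,
# and optional within-block item dependence driven by a latent per-death
# "syndrome" indicator.  Dependence is what makes joint response patterns on
# clusters of items more informative than items taken one at a time, which
# is precisely the contrast the cluster-size axis of the SSP design space
# probes.

#' Specify a synthetic VA population
#'
#' @param endorsement numeric matrix `p[item, cause]` of endorsement
#'   probabilities in \[0,1\]: the chance a death from that cause endorses
#'   the item, marginally.
#' @param true_csmf simplex vector of cause fractions (sums to 1).
#' @param n_deaths number of deaths to generate.
#' @param blocks integer vector, one entry per item, assigning items to
#'   dependence blocks; items sharing a block co-endorse through a shared
#'   latent state. Defaults to every item in its own block (independence).
#' @param rho dependence weight in \[0,1) shared by all blocks, or one value
#'   per block. `rho = 0` gives conditionally independent Bernoulli items;
#'   as `rho` approaches 1 items in a block become copies of the latent state.
#' @param hce_items character or integer vector naming the items to flag as
#'   health-care experience in the generated catalog.
#' @param cause_list,item_id optional labels; defaults are generated.
#' @param module age module tag for the generated catalog.
#' @param seed integer seed; the whole population is reproducible from it.
#' @return An object of class `population_spec`.
#' @seealso [generate_population()], [phmrc_like_spec()]
#' @export
population_spec <- function(endorsement, true_csmf, n_deaths,
                            blocks = NULL, rho = 0, hce_items = NULL,
                            cause_list = NULL, item_id = NULL,
                            module = "adult", seed = 1L) {
  endorsement <- as.matrix(endorsement)
  p <- nrow(endorsement); n_causes <- ncol(endorsement)
  if (any(endorsement < 0 | endorsement > 1))
    stop("endorsement probabilities must lie in [0,1]")
  true_csmf <- as.numeric(true_csmf)
  if (length(true_csmf) != n_causes) stop("true_csmf length must match causes")
  if (any(true_csmf < 0) || abs(sum(true_csmf) - 1) > 1e-12)
    stop("true_csmf must be a simplex (nonnegative, summing to 1)")
  if (is.null(blocks)) blocks <- seq_len(p)
  blocks <- as.integer(factor(blocks))
  if (length(blocks) != p) stop("blocks must have one entry per item")
  n_blocks <- max(blocks)
  if (length(rho) == 1) rho <- rep(rho, n_blocks)
  if (length(rho) != n_blocks) stop("rho must be scalar or one value per block")
  if (any(rho < 0 | rho >= 1)) stop("rho must lie in [0,1)")
  if (is.null(item_id)) item_id <- sprintf("s%03d", seq_len(p))
  if (is.null(cause_list)) cause_list <- sprintf("cause_%02d", seq_len(n_causes))
  dimnames(endorsement) <- list(item_id, cause_list)
  hce <- rep(FALSE, p)
  if (!is.null(hce_items)) {
    hce[if (is.character(hce_items)) match(hce_items, item_id) else hce_items] <- TRUE
  }
  structure(list(endorsement = endorsement, true_csmf = true_csmf,
                 n_deaths = as.integer(n_deaths), blocks = blocks, rho = rho,
                 hce_flag = hce, cause_list = cause_list, item_id = item_id,
                 module = module, seed = as.integer(seed)),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("Synthetic VA population spec (%s module)\n", x$module))
  cat(sprintf("  %d deaths, %d items, %d causes, %d dependence blocks\n",
              x$n_deaths, length(x$item_id), length(x$cause_list),
              max(x$blocks)))
  cat(sprintf("  rho range [%.2f, %.2f]; HCE items: %d; seed %d\n",
              min(x$rho), max(x$rho), sum(x$hce_flag), x$seed))
  invisible(x)
}

#' Generate a synthetic VA dataset from a population spec
#'
#' Causes are drawn from the true CSMF.  Given cause j, each dependence
#' block b draws a latent syndrome indicator `Z_b ~ Bernoulli(pbar)` with
#' `pbar` the block's mean endorsement under cause j; item i in block b is
#' then endorsed with probability `(1 - rho) * p[i,j] + rho * Z_b`.  At
#' `rho = 0` this is the conditionally independent Bernoulli model with
#' marginal `p[i,j]`; at large `rho` items in a block co-endorse.  The
#' marginal endorsement target of item i under cause j is
#' `(1 - rho) * p[i,j] + rho * pbar`, which equals `p[i,j]` whenever a
#' block's items share a common endorsement probability.
#'
#' @param spec a [population_spec()].
#' @return A [va_dataset()] with gold-standard causes filled in.
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  p <- length(spec$item_id); n <- spec$n_deaths
  with_seed(spec$seed, {
    cause_idx <- sample.int(length(spec$cause_list), n, replace = TRUE,
                            prob = spec$true_csmf)
    resp <- matrix(0L, n, p, dimnames = list(NULL, spec$item_id))
    if (n > 0) {
      # block means per cause, for the latent syndrome probability
      pbar <- apply(spec$endorsement, 2, function(col)
        tapply(col, spec$blocks, mean))
      pbar <- matrix(pbar, nrow = max(spec$blocks))  # block x cause
      z <- matrix(stats::runif(n * max(spec$blocks)), n) <
        t(pbar[, cause_idx, drop = FALSE])           # death x block
      rho_i <- spec$rho[spec$blocks]                  # per item
      pmat <- t(spec$endorsement[, cause_idx, drop = FALSE])  # death x item
      prob <- sweep(pmat, 2, 1 - rho_i, `*`) +
        z[, spec$blocks, drop = FALSE] * rep(rho_i, each = n)
      resp[] <- as.integer(matrix(stats::runif(n * p), n) < prob)
    }
    cat <- va_catalog(spec$item_id, module = spec$module,
                      hce_flag = spec$hce_flag)
    va_dataset(resp, cat, spec$cause_list,
               gold_cause = spec$cause_list[cause_idx])
  })
}

# item counts of the dichotomized instrument by age module
MODULE_N_ITEMS <- c(adult = 194L, child = 104L, neonate = 137L)

#' A PHMRC-like population spec for an age module
#'
#' Builds a population spec with the item count of the chosen age module
#' (adult 194, child 104, neonate 137) and a signal structure in which each
#' cause elevates the endorsement of its own set of signal items above a low
#' background rate by `separation`.  Signal items for a cause are grouped in
#' one dependence block, so with `rho > 0` a cause's signature symptoms
#' co-occur as a syndrome; at `separation = 0` all causes share one
#' endorsement profile and no classifier can beat chance.
#'
#' A fixed fraction (15%) of items is flagged as health-care experience so
#' the with/without-HCE pipeline can be exercised on generated data.
#'
#' @param module `"adult"`, `"child"` or `"neonate"`.
#' @param n_causes number of causes (at least 2, at most the module's
#'   signal-item capacity).
#' @param separation added endorsement probability on a cause's signal
#'   items, in \[0,1\].
#' @param seed integer seed.
#' @param n_deaths population size (default 2000).
#' @param rho dependence weight for the signal blocks (default 0.3).
#' @param true_csmf optional simplex; defaults to uniform over causes.
#' @param background baseline endorsement probability (default 0.05).
#' @param signal_items signal items per cause (default: floor of items/causes,
#'   capped at 10).
#' @return A [population_spec()].
#' @export
phmrc_like_spec <- function(module = c("adult", "child", "neonate"),
                            n_causes, separation, seed = 1L,
                            n_deaths = 2000L, rho = 0.3,
                            true_csmf = NULL, background = 0.05,
                            signal_items = NULL) {
  module <- match.arg(module)
  n_items <- MODULE_N_ITEMS[[module]]
  if (n_causes < 2) stop("n_causes must be at least 2")
  if (separation < 0 || separation > 1) stop("separation must lie in [0,1]")
  if (is.null(signal_items)) signal_items <- min(10L, n_items %/% n_causes)
  if (signal_items < 1 || n_causes * signal_items > n_items)
    stop("n_causes exceeds the module's signal-item capacity")
  if (is.null(true_csmf)) true_csmf <- rep(1 / n_causes, n_causes)
  p <- with_seed(derive_seed(seed, 1), {
    base <- matrix(stats::runif(n_items * n_causes, 0.5 * background,
                                1.5 * background),
                   n_items, n_causes)
    for (j in seq_len(n_causes)) {
      sig <- ((j - 1) * signal_items + 1):(j * signal_items)
      base[sig, j] <- pmin(1, base[sig, j] + separation)
    }
    base
  })
  # dependence blocks are disease-family syndromes: causes are grouped into
  # families of `family_size` and one latent syndrome spans the family's
  # pooled signal items, so related causes co-endorse each other's signature
  # symptoms when the syndrome fires.  Background items form blocks of the
  # same width (context syndromes).  This makes the dependence both
  # pervasive (a random 10-item cluster usually holds several same-block
  # items) and cause-asymmetric, as in real questionnaires.
  family_size <- 3L
  blocks <- integer(n_items)
  cause_family <- ceiling(seq_len(n_causes) / family_size)
  blocks[seq_len(n_causes * signal_items)] <-
    rep(cause_family, each = signal_items)
  n_fam <- max(cause_family)
  leftover <- which(blocks == 0L)
  if (length(leftover))
    blocks[leftover] <- n_fam +
      ceiling(seq_along(leftover) / max(family_size * signal_items, 1L))
  rho_by_block <- rep(rho, max(blocks))
  # flag a deterministic 15% of items, spread across signal and background
  hce <- seq_len(n_items) %% 7L == 0L
  population_spec(p, true_csmf, n_deaths, blocks = blocks, rho = rho_by_block,
                  hce_items = which(hce), module = module, seed = seed)
}
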