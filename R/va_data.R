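# Data model and IO for verbal-autopsy (VA) datasets.
#
# A VA dataset is one row per death over a catalog of dichotomous
# symptom/sign items.  Responses are stored losslessly as 1 (yes), 0 (no)
# and NA (missing / don't know); how missing responses enter likelihoods is
# decided at pattern-formation time, not here.

#' Construct a verbal-autopsy item catalog
#'
#' The catalog lists the dichotomous items of one age module (adult, child
#' or neonate) and flags the items that record the household's recall of
#' health-care experience (HCE): hospitalisations, medical records, death
#' certificates and the like.  Analyses are run with and without HCE items
#' to mimic populations without access to care.
#'
#' @param item_id character vector of unique item identifiers.
#' @param module one of `"adult"`, `"child"`, `"neonate"`.
#' @param label human-readable item labels (defaults to `item_id`).
#' @param hce_flag logical vector; `TRUE` marks an HCE item.
#' @return A `data.frame` of class `va_catalog` with columns
#'   `item_id`, `label`, `module`, `hce_flag`.
#' @seealso [va_dataset()], [apply_hce_filter()]
#' @export
va_catalog <- function(item_id, module, label = item_id,
                       hce_flag = logical(length(item_id))) {
  item_id <- as.character(item_id)
  module <- match.arg(module, c("adult", "child", "neonate"))
  if (anyDuplicated(item_id))
    stop("duplicate item_id in catalog: ",
         paste(unique(item_id[duplicated(item_id)]), collapse = ", "))
  if (length(label) != length(item_id) || length(hce_flag) != length(item_id))
    stop("label and hce_flag must have one entry per item")
  out <- data.frame(item_id = item_id, label = as.character(label),
                    module = module, hce_flag = as.logical(hce_flag),
                    stringsAsFactors = FALSE)
  class(out) <- c("va_catalog", "data.frame")
  out
}

#' Construct a verbal-autopsy dataset
#'
#' Bundles a response matrix with its item catalog and the cause list.  The
#' cause list is carried explicitly (not inferred from observed gold-standard
#' causes) so that causes with zero deaths in a particular split still exist
#' downstream, e.g. for the estimated-versus-true CSMF regression.
#'
#' @param responses integer/numeric matrix, one row per death and one column
#'   per catalog item; entries 1 (yes), 0 (no) or NA (missing).
#' @param catalog a [va_catalog()].
#' @param cause_list character vector of cause labels (the full cause list).
#' @param death_id character vector of unique death identifiers.
#' @param gold_cause optional character vector of gold-standard causes
#'   (NA where unlabeled); every non-NA entry must be in `cause_list`.
#' @return An object of class `va_dataset`: a list with elements `catalog`,
#'   `responses`, `death_id`, `gold_cause`, `cause_list`, `module`.
#' @export
va_dataset <- function(responses, catalog, cause_list,
                       death_id = NULL, gold_cause = NULL) {
  if (!inherits(catalog, "va_catalog")) stop("catalog must be a va_catalog")
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  n <- nrow(responses)
  if (ncol(responses) != nrow(catalog))
    stop("responses must have one column per catalog item")
  if (is.null(colnames(responses))) colnames(responses) <- catalog$item_id
  if (!identical(colnames(responses), catalog$item_id))
    stop("response columns do not match catalog item_ids")
  bad <- responses[!is.na(responses)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    stop("responses must be 0, 1 or NA")
  if (is.null(death_id)) death_id <- sprintf("d%d", seq_len(n))
  death_id <- as.character(death_id)
  if (length(death_id) != n) stop("death_id must have one entry per record")
  if (anyDuplicated(death_id)) stop("duplicate death_id")
  cause_list <- as.character(cause_list)
  if (anyDuplicated(cause_list)) stop("duplicate cause in cause_list")
  if (is.null(gold_cause)) gold_cause <- rep(NA_character_, n)
  gold_cause <- as.character(gold_cause)
  if (length(gold_cause) != n) stop("gold_cause must have one entry per record")
  unknown <- setdiff(gold_cause[!is.na(gold_cause)], cause_list)
  if (length(unknown))
    stop("gold_cause not in cause list: ", paste(unknown, collapse = ", "))
  structure(list(catalog = catalog, responses = responses,
                 death_id = death_id, gold_cause = gold_cause,
                 cause_list = cause_list, module = catalog$module[1]),
            class = "va_dataset")
}

#' @export
print.va_dataset <- function(x, ...) {
  n_lab <- sum(!is.na(x$gold_cause))
  cat(sprintf("Verbal-autopsy dataset (%s module)\n", x$module))
  cat(sprintf("  %d deaths x %d items; %d gold-standard labels; %d causes\n",
              nrow(x$responses), ncol(x$responses), n_lab,
              length(x$cause_list)))
  cat(sprintf("  HCE items: %d\n", sum(x$catalog$hce_flag)))
  invisible(x)
}

#' Subset the records of a VA dataset
#'
#' Row indices may repeat, so resampling with replacement (as in the
#' Dirichlet-composition test sets) yields a valid dataset; duplicated
#' death ids are disambiguated with a suffix.
#'
#' @param x a `va_dataset`.
#' @param i record index vector.
#' @param ... ignored.
#' @export
`[.va_dataset` <- function(x, i, ...) {
  id <- x$death_id[i]
  if (anyDuplicated(id)) id <- make.unique(id, sep = "#")
  va_dataset(x$responses[i, , drop = FALSE], x$catalog, x$cause_list,
             death_id = id, gold_cause = x$gold_cause[i])
}

#' Number of deaths in a VA dataset
#' @param x a `va_dataset`.
#' @export
n_deaths <- function(x) nrow(x$responses)

## ---- IO ------------------------------------------------------------------
##
## Encoding contract (bit-exact): in data CSVs a response cell holds "1"
## (yes), "0" (no) or "" (missing).  Reserved columns: death_id, module,
## gold_cause (gold_cause empty where unlabeled).  The catalog CSV has
## columns item_id,label,module,hce_flag and travels with a cause-list
## sidecar, one cause label per line.

default_causes_path <- function(catalog_path) {
  paste0(sub("\\.[Cc][Ss][Vv]$", "", catalog_path), "_causes.txt")
}

#' Read an item catalog and its cause-list sidecar
#'
#' @param catalog_path CSV with columns `item_id,label,module,hce_flag`.
#' @param causes_path plain-text file with one cause label per line;
#'   defaults to the catalog path with a `_causes.txt` suffix.
#' @return list with elements `catalog` (a [va_catalog()]) and
#'   `cause_list` (character).
#' @export
read_va_catalog <- function(catalog_path,
                            causes_path = default_causes_path(catalog_path)) {
  tab <- utils::read.csv(catalog_path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("item_id", "label", "module", "hce_flag")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("catalog missing columns: ", paste(miss, collapse = ", "))
  cat <- va_catalog(tab$item_id, module = tab$module[1], label = tab$label,
                    hce_flag = tab$hce_flag %in% c("TRUE", "true", "1"))
  causes <- readLines(causes_path, warn = FALSE)
  causes <- causes[nzchar(causes)]
  list(catalog = cat, cause_list = causes)
}

#' Write an item catalog and its cause-list sidecar
#'
#' @param catalog a [va_catalog()].
#' @param cause_list character vector of cause labels.
#' @param catalog_path destination CSV path.
#' @param causes_path destination for the cause-list sidecar.
#' @return `catalog_path`, invisibly.
#' @export
write_va_catalog <- function(catalog, cause_list, catalog_path,
                             causes_path = default_causes_path(catalog_path)) {
  utils::write.csv(as.data.frame(catalog), catalog_path, row.names = FALSE,
                   quote = TRUE)
  writeLines(cause_list, causes_path)
  invisible(catalog_path)
}

#' Read a verbal-autopsy dataset from CSV
#'
#' The data file has one row per death with reserved columns
#' `death_id,module,gold_cause` followed by one column per catalog item.
#' Response cells are `"1"` (yes), `"0"` (no) or empty (missing).
#'
#' @param data_path data CSV path.
#' @param catalog_path catalog CSV path (see [read_va_catalog()]).
#' @param causes_path cause-list sidecar path.
#' @return A [va_dataset()].
#' @export
read_va_dataset <- function(data_path, catalog_path,
                            causes_path = default_causes_path(catalog_path)) {
  cc <- read_va_catalog(catalog_path, causes_path)
  tab <- utils::read.csv(data_path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  reserved <- c("death_id", "module", "gold_cause")
  miss <- setdiff(reserved, names(tab))
  if (length(miss)) stop("data missing columns: ", paste(miss, collapse = ", "))
  unknown <- setdiff(names(tab), c(reserved, cc$catalog$item_id))
  if (length(unknown)) stop("unknown column(s): ", paste(unknown, collapse = ", "))
  miss_items <- setdiff(cc$catalog$item_id, names(tab))
  if (length(miss_items))
    stop("data missing item column(s): ", paste(miss_items, collapse = ", "))
  n <- nrow(tab)
  if (n > 0 && any(tab$module != cc$catalog$module[1]))
    stop("module mismatch between data and catalog")
  resp <- matrix(NA_integer_, n, nrow(cc$catalog),
                 dimnames = list(NULL, cc$catalog$item_id))
  for (it in cc$catalog$item_id) {
    v <- tab[[it]]
    out <- rep(NA_integer_, n)
    out[v == "1"] <- 1L
    out[v == "0"] <- 0L
    bad <- !(v %in% c("", "0", "1"))
    if (any(bad)) stop("unparseable response value in item ", it, ": ",
                       v[which(bad)[1]])
    resp[, it] <- out
  }
  gold <- tab$gold_cause
  gold[gold == ""] <- NA_character_
  va_dataset(resp, cc$catalog, cc$cause_list,
             death_id = if (n) tab$death_id else character(0),
             gold_cause = if (n) gold else character(0))
}

#' Write a verbal-autopsy dataset to CSV
#'
#' Uses the same encoding [read_va_dataset()] parses, so a write/read round
#' trip reproduces the dataset exactly.
#'
#' @param dataset a [va_dataset()].
#' @param data_path destination CSV path.
#' @return `data_path`, invisibly.
#' @export
write_va_dataset <- function(dataset, data_path) {
  resp <- dataset$responses
  chr <- matrix("", nrow(resp), ncol(resp), dimnames = dimnames(resp))
  chr[!is.na(resp) & resp == 1L] <- "1"
  chr[!is.na(resp) & resp == 0L] <- "0"
  gold <- dataset$gold_cause
  gold[is.na(gold)] <- ""
  out <- data.frame(death_id = dataset$death_id,
                    module = rep(dataset$module, nrow(resp)),
                    gold_cause = gold, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (nrow(resp) == 0)
    out <- out[0, , drop = FALSE]
  out <- cbind(out, as.data.frame(chr, stringsAsFactors = FALSE,
                                  check.names = FALSE))
  utils::write.csv(out, data_path, row.names = FALSE, quote = TRUE)
  invisible(data_path)
}

#' Include or exclude health-care experience items
#'
#' With `include_hce = FALSE`, drops every catalog item flagged as household
#' recall of health-care experience, together with the corresponding response
#' columns; records, gold causes and their order are untouched.  With
#' `include_hce = TRUE` the dataset is returned unchanged.
#'
#' @param dataset a [va_dataset()].
#' @param include_hce logical.
#' @return A [va_dataset()].
#' @export
apply_hce_filter <- function(dataset, include_hce) {
  if (include_hce) return(dataset)
  keep <- !dataset$catalog$hce_flag
  if (!any(keep)) stop("all items are HCE-flagged; nothing left after filtering")
  cat <- dataset$catalog[keep, , drop = FALSE]
  rownames(cat) <- NULL
  class(cat) <- c("va_catalog", "data.frame")
  va_dataset(dataset$responses[, keep, drop = FALSE], cat,
             dataset$cause_list, death_id = dataset$death_id,
             gold_cause = dataset$gold_cause)
}

## internal: run expr under a temporary RNG state so library functions with a
## seed argument do not clobber the caller's stream
with_seed <- function(seed, expr) {
  if (!is.null(old <- globalenv()$.Random.seed)) {
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## internal: derive a stream-specific 31-bit seed from a base seed.  The
## large odd multiplier on k spreads consecutive stream indices across the
## seed space (consecutive seeds give correlated first Mersenne-Twister
## draws).
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 +
                (as.double(k) * 1103515245) %% 2147483647) %% 2147483647)
}
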