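# Model persistence and prediction export.
#
# A fitted SSP model is a set of count tables plus its configuration, so it
# serializes cleanly to JSON: this supports the deployment mode where a
# model trained once on a large gold-standard dataset is shipped and
# applied to unlabeled questionnaires elsewhere.

pt_to_list <- function(pt) {
  if (is.null(pt)) return(NULL)
  list(classes = pt$classes, class_n = pt$class_n, alpha = pt$alpha,
       missing = pt$missing, item_ids = pt$item_ids,
       cluster_size = attr(pt$partitions, "cluster_size"),
       seed = attr(pt$partitions, "seed"),
       partitions = lapply(pt$partitions, function(p) unname(lapply(p, c))),
       tables = lapply(pt$tables, function(tab)
         list(n_patterns = tab$n_patterns,
              counts = lapply(tab$counts, function(m) list(dim = dim(m),
                                                           x = as.integer(m))))))
}

pt_from_list <- function(l) {
  if (is.null(l)) return(NULL)
  parts <- lapply(l$partitions, function(p) lapply(p, as.character))
  parts <- structure(parts, item_ids = as.character(l$item_ids),
                     cluster_size = as.integer(l$cluster_size),
                     seed = as.integer(l$seed), class = "cluster_partitions")
  tabs <- lapply(l$tables, function(tab)
    list(counts = lapply(tab$counts, function(m)
           matrix(as.integer(m$x), m$dim[1], m$dim[2])),
         n_patterns = as.integer(tab$n_patterns)))
  structure(list(partitions = parts, classes = as.character(l$classes),
                 class_n = as.integer(l$class_n), tables = tabs,
                 alpha = as.numeric(l$alpha), missing = l$missing,
                 item_ids = as.character(l$item_ids)),
            class = "pattern_table")
}

#' Save a fitted SSP model as JSON
#'
#' @param model an [ssp()] model.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_ssp_model <- function(model, path) {
  stopifnot(inherits(model, "ssp"))
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("model persistence requires the jsonlite package")
  obj <- list(config = unclass(model$config), cause_list = model$cause_list,
              prior = unname(model$prior), n_by_cause = model$n_by_cause,
              n_train = model$n_train,
              catalog = as.list(as.data.frame(model$catalog)),
              top_item_sets = if (is.null(model$top_item_sets)) NULL else
                lapply(model$top_item_sets, c),
              top_k = attr(model$top_item_sets, "k"),
              table = pt_to_list(model$table),
              tables = lapply(model$tables %||% list(), pt_to_list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a fitted SSP model saved by [write_ssp_model()]
#'
#' @param path JSON file path.
#' @return An [ssp()] model.
#' @export
read_ssp_model <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("model persistence requires the jsonlite package")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                             simplifyDataFrame = FALSE)
  cfg <- obj$config
  config <- ssp_config(cluster_size = cfg$cluster_size,
                       cause_mode = cfg$cause_mode, item_set = cfg$item_set,
                       top_k = cfg$top_k, prior = cfg$prior,
                       n_partitions = cfg$n_partitions, alpha = cfg$alpha,
                       missing = cfg$missing, seed = cfg$seed)
  cat <- va_catalog(obj$catalog$item_id, module = obj$catalog$module[1],
                    label = obj$catalog$label,
                    hce_flag = as.logical(obj$catalog$hce_flag))
  top <- NULL
  if (!is.null(obj$top_item_sets) && length(obj$top_item_sets)) {
    top <- lapply(obj$top_item_sets, as.character)
    top <- structure(top, k = as.integer(obj$top_k), class = "top_item_sets")
  }
  tables <- NULL
  if (length(obj$tables)) {
    tables <- lapply(obj$tables, pt_from_list)
    names(tables) <- obj$cause_list
  }
  structure(list(config = config, cause_list = as.character(obj$cause_list),
                 catalog = cat,
                 prior = stats::setNames(as.numeric(obj$prior), obj$cause_list),
                 n_by_cause = as.integer(obj$n_by_cause),
                 n_train = as.integer(obj$n_train),
                 table = pt_from_list(obj$table), tables = tables,
                 top_item_sets = top),
            class = "ssp")
}

#' Write per-death predictions to CSV
#'
#' One row per death: `death_id`, the top three ranked causes and their
#' posterior scores.
#'
#' @param model an [ssp()] model.
#' @param test a [va_dataset()].
#' @param path destination CSV.
#' @return The prediction `data.frame`, invisibly.
#' @export
write_predictions <- function(model, test, path) {
  sc <- predict(model, test, type = "posterior")
  k <- min(3L, ncol(sc))
  rk <- assign_causes(sc, k)
  scr <- t(vapply(seq_len(nrow(sc)), function(i)
    sc[i, match(rk[i, ], colnames(sc))], numeric(k)))
  if (k == 1) scr <- matrix(scr, ncol = 1)
  out <- data.frame(death_id = test$death_id, stringsAsFactors = FALSE)
  for (m in seq_len(k)) {
    out[[paste0("cause", m)]] <- rk[, m]
    out[[paste0("score", m)]] <- scr[, m]
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
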