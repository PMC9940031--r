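# Metric keys where smaller values indicate better models (used for the
# default ranking order).
LOWER_IS_BETTER <- c("FID")

#' Flatten a metadata entry to its searchable strings
#'
#' Depth-first collection of every string-valued leaf and every key name in
#' the entry, lowercased. Numeric leaves are excluded (their key names, such
#' as `"fid"`, remain searchable).
#'
#' @param entry A `model_metadata` object.
#' @return Lowercase character vector of searchable strings.
#' @export
flatten_metadata <- function(entry) {
  out <- character(0)
  walk <- function(x) {
    if (is.list(x)) {
      nm <- names(x)
      if (!is.null(nm)) out <<- c(out, nm[nzchar(nm)])
      lapply(x, walk)
    } else if (is.character(x)) {
      out <<- c(out, x[nzchar(x)])
    }
    invisible(NULL)
  }
  walk(list(model_id = entry$model_id,
            execution = entry$execution,
            selection = entry$selection,
            description = entry$description))
  tolower(out)
}

#' Search the registry for models matching query values
#'
#' Each query value matches a model when it occurs as a case-insensitive
#' substring of at least one flattened metadata string (see
#' [flatten_metadata()]). With k = number of matching query values, the
#' operator decides: `AND` requires k equal to the query length, `OR` requires
#' k >= 1, `XOR` requires exactly k = 1. Results keep registry order.
#'
#' @param registry A `synthzoo_registry`.
#' @param values Non-empty character vector of query values.
#' @param operator One of `"AND"`, `"OR"`, `"XOR"`.
#' @return A list of matched entries, each a list with `model_id`,
#'   `matched_values`, and `is_match = TRUE`.
#' @export
find_matching_models <- function(registry, values, operator = "OR") {
  if (length(values) == 0L || any(!nzchar(values))) {
    stop_synthzoo("query values must be a non-empty character vector",
                  "synthzoo_argument_error")
  }
  if (!operator %in% c("AND", "OR", "XOR")) {
    stop_synthzoo(sprintf("unknown search operator %s (expected AND, OR, or XOR)",
                          deparse(operator)), "synthzoo_argument_error")
  }
  values_lc <- tolower(values)
  matched <- list()
  for (id in names(registry$entries)) {
    haystack <- flatten_metadata(registry$entries[[id]])
    hit <- vapply(values_lc, function(v) {
      any(grepl(v, haystack, fixed = TRUE))
    }, logical(1))
    k <- sum(hit)
    ok <- switch(operator,
      AND = k == length(values),
      OR  = k >= 1L,
      XOR = k == 1L
    )
    if (ok) {
      matched[[length(matched) + 1L]] <- list(
        model_id = id,
        matched_values = values[hit],
        is_match = TRUE
      )
    }
  }
  matched
}

# Resolve a dotted metric path (e.g. "FID" or "downstream.dice") inside
# selection.performance; NA when absent or non-numeric.
metric_value <- function(entry, metric_key) {
  node <- entry$selection$performance
  for (part in strsplit(metric_key, ".", fixed = TRUE)[[1]]) {
    if (!is.list(node)) return(NA_real_)
    node <- node[[part]]
    if (is.null(node)) return(NA_real_)
  }
  if (is.numeric(node) && length(node) == 1L) as.numeric(node) else NA_real_
}

#' Rank models by a performance metric
#'
#' Sorts the models carrying the metric by its value, breaking ties by model
#' id (lexicographic ascending). Models lacking the metric are appended at
#' the end in registry order and flagged via `has_metric = FALSE` so the
#' caller still sees the full candidate set.
#'
#' @param registry A `synthzoo_registry`.
#' @param model_ids Character vector of ids to rank, or `NULL` for all models.
#' @param metric_key Dotted path into `selection.performance`, e.g. `"FID"`.
#' @param order `"ascending"`, `"descending"`, or `NULL` for the metric's
#'   default (ascending for lower-is-better metrics such as FID, descending
#'   otherwise).
#' @return Data frame with columns `model_id`, `value`, `has_metric`, in rank
#'   order. Zero eligible models triggers a warning, not an error.
#' @export
rank_models_by_performance <- function(registry, model_ids = NULL,
                                       metric_key = "FID", order = NULL) {
  if (!nzchar(metric_key %||% "")) {
    stop_synthzoo("metric_key must be a non-empty string", "synthzoo_argument_error")
  }
  ids <- model_ids %||% names(registry$entries)
  ids <- ids[ids %in% names(registry$entries)]
  if (is.null(order)) {
    leaf <- utils::tail(strsplit(metric_key, ".", fixed = TRUE)[[1]], 1)
    order <- if (leaf %in% LOWER_IS_BETTER) "ascending" else "descending"
  }
  vals <- vapply(ids, function(id) metric_value(registry$entries[[id]], metric_key),
                 numeric(1))
  has <- !is.na(vals)
  if (!any(has)) {
    warn_synthzoo(sprintf("no model carries metric %s; result contains only flagged entries",
                          deparse(metric_key)), "synthzoo_empty_rank_warning")
  }
  ranked_ids <- ids[has][order(vals[has],
                               ids[has],
                               decreasing = c(order == "descending", FALSE),
                               method = "radix")]
  data.frame(
    model_id = c(ranked_ids, ids[!has]),
    value = c(vals[ranked_ids], vals[ids[!has]]),
    has_metric = c(rep(TRUE, sum(has)), rep(FALSE, sum(!has))),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Search, then rank the matches by a performance metric
#'
#' Composition of [find_matching_models()] and [rank_models_by_performance()];
#' errors from either step propagate.
#'
#' @inheritParams find_matching_models
#' @inheritParams rank_models_by_performance
#' @return Rank data frame restricted to the matching models (empty when the
#'   query matches nothing).
#' @export
find_and_rank <- function(registry, values, operator = "OR",
                          metric_key = "FID", order = NULL) {
  matches <- find_matching_models(registry, values, operator)
  ids <- vapply(matches, `[[`, character(1), "model_id")
  if (length(ids) == 0L) {
    return(data.frame(model_id = character(0), value = numeric(0),
                      has_metric = logical(0), stringsAsFactors = FALSE))
  }
  rank_models_by_performance(registry, model_ids = ids,
                             metric_key = metric_key, order = order)
}
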