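#' Load the model-metadata registry
#'
#' The registry is a single UTF-8 JSON object whose top-level keys are model
#' ids and whose values carry the three metadata sections `execution`,
#' `selection`, and `description`. Entry order is preserved from the file.
#' When the same id occurs twice in the byte stream, the last occurrence wins
#' and a warning is emitted. Ids that do not match the canonical uppercase
#' pattern are tolerated at load time with a warning (they are rejected at
#' contribution time).
#'
#' @param source Path to (or `file://` URI of) the registry JSON file.
#' @return An object of class `synthzoo_registry`: a list with `entries`
#'   (named list of metadata entries in file order), `source`, and
#'   `schema_version`.
#' @seealso [get_metadata()], [validate_metadata()], [write_registry()]
#' @export
load_registry <- function(source) {
  path <- sub("^file://", "", source)
  if (!file.exists(path)) {
    stop_synthzoo(sprintf("registry file not found: %s", path), "synthzoo_io_error")
  }
  txt <- readChar(path, file.info(path)$size, useBytes = TRUE)
  Encoding(txt) <- "UTF-8"
  raw <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) {
      stop_synthzoo(sprintf("malformed registry JSON in %s: %s", path,
                            conditionMessage(e)), "synthzoo_parse_error")
    }
  )
  if (!is.list(raw)) {
    stop_synthzoo("registry top level must be a JSON object keyed by model ids",
                  "synthzoo_validation_error")
  }
  ids <- names(raw)
  if (length(raw) > 0L && (is.null(ids) || any(!nzchar(ids)))) {
    stop_synthzoo("registry top level must be a JSON object keyed by model ids",
                  "synthzoo_validation_error")
  }
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    warn_synthzoo(sprintf("duplicate model id(s) in registry, keeping last occurrence: %s",
                          paste(dups, collapse = ", ")),
                  "synthzoo_duplicate_id_warning")
    keep <- !duplicated(ids, fromLast = TRUE)
    raw <- raw[keep]
    ids <- names(raw)
  }
  bad_ids <- ids[!vapply(ids, is_valid_model_id, logical(1))]
  if (length(bad_ids) > 0L) {
    warn_synthzoo(sprintf("model id(s) not in canonical form (tolerated at load time): %s",
                          paste(bad_ids, collapse = ", ")),
                  "synthzoo_id_form_warning")
  }
  entries <- lapply(ids, function(id) as_model_metadata(id, raw[[id]]))
  names(entries) <- ids
  violations <- unlist(lapply(entries, function(e) {
    v <- validate_metadata(e)
    if (length(v) > 0L) paste0(e$model_id, ": ", v) else character(0)
  }), use.names = FALSE)
  # id-form problems already warned about above; all other schema violations
  # are load-time errors listing the offending ids and fields
  hard <- violations[!grepl("model_id: must match", violations)]
  if (length(hard) > 0L) {
    stop_synthzoo(paste0("registry schema violation(s):\n  ",
                         paste(hard, collapse = "\n  ")),
                  "synthzoo_validation_error")
  }
  structure(
    list(entries = entries, source = source, schema_version = "1.0"),
    class = "synthzoo_registry"
  )
}

as_model_metadata <- function(id, sections) {
  if (!is.list(sections)) sections <- list()
  structure(
    list(
      model_id = id,
      execution = sections$execution,
      selection = sections$selection,
      description = sections$description
    ),
    class = "model_metadata"
  )
}

#' Validate one registry entry
#'
#' Checks the concrete metadata schema: id pattern; presence of the three
#' sections; a non-empty `generate_method_name` and well-formed dependency
#' names under `execution`; finite performance values and non-empty keywords
#' under `selection`; a non-empty `title` under `description`. Violations are
#' returned, not raised, so callers can aggregate them.
#'
#' @param entry A `model_metadata` object (one registry entry).
#' @return Character vector of violation messages; empty when the entry is
#'   valid. Each message names the offending field and rule.
#' @export
validate_metadata <- function(entry) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)

  if (!is_valid_model_id(entry$model_id %||% "")) {
    add(sprintf("model_id: must match pattern %s (got %s)",
                MODEL_ID_PATTERN, deparse(entry$model_id %||% "NULL")))
  }
  for (sec in c("execution", "selection", "description")) {
    if (is.null(entry[[sec]])) add(sprintf("%s: section missing", sec))
  }

  ex <- entry$execution
  if (!is.null(ex)) {
    gmn <- ex$generate_method_name
    if (is.null(gmn) || !is.character(gmn) || !nzchar(gmn)) {
      add("execution.generate_method_name: must be a non-empty string")
    }
    deps <- ex$dependencies
    if (!is.null(deps)) {
      nm <- vapply(deps, function(d) {
        if (is.list(d)) as.character(d$name %||% "") else as.character(d)
      }, character(1))
      if (any(!nzchar(nm))) add("execution.dependencies: names must be non-empty strings")
    }
  }

  sel <- entry$selection
  if (!is.null(sel)) {
    perf <- unlist(sel$performance)
    if (length(perf) > 0L) {
      num <- suppressWarnings(as.numeric(perf))
      if (any(is.na(num) | !is.finite(num))) {
        add("selection.performance: all metric values must be finite numbers")
      }
    }
    kw <- sel$keywords
    if (!is.null(kw)) {
      kw <- unlist(kw)
      if (any(!nzchar(kw))) add("selection.keywords: keywords must be non-empty strings")
    }
  }

  de <- entry$description
  if (!is.null(de)) {
    if (is.null(de$title) || !nzchar(de$title %||% "")) {
      add("description.title: must be a non-empty string")
    }
  }
  v
}

#' Retrieve one model's metadata by id
#'
#' Constant-time named lookup. Ids are case-sensitive; an unknown id raises a
#' key error naming the three closest known ids by edit distance.
#'
#' @param registry A `synthzoo_registry`.
#' @param model_id Model id string.
#' @return The `model_metadata` entry.
#' @export
get_metadata <- function(registry, model_id) {
  entry <- registry$entries[[model_id]]
  if (is.null(entry)) {
    ids <- names(registry$entries)
    near <- character(0)
    if (length(ids) > 0L) {
      d <- utils::adist(model_id, ids)[1, ]
      near <- ids[order(d)][seq_len(min(3L, length(ids)))]
    }
    stop_synthzoo(sprintf("unknown model id %s; closest known ids: %s",
                          deparse(model_id),
                          if (length(near)) paste(near, collapse = ", ") else "(registry empty)"),
                  "synthzoo_key_error")
  }
  entry
}

#' Write a registry back to JSON
#'
#' Serializes with the three fixed section keys in normalized order
#' (`execution`, `selection`, `description`) and numbers at their full printed
#' precision, so that load/write round-trips are semantically identical.
#'
#' @param registry A `synthzoo_registry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  out <- lapply(registry$entries, function(e) {
    list(execution = e$execution, selection = e$selection, description = e$description)
  })
  if (length(out) == 0L) out <- structure(list(), names = character(0))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @export
print.synthzoo_registry <- function(x, ...) {
  cat(sprintf("<synthzoo registry: %d model(s), source: %s>\n",
              length(x$entries), x$source))
  for (id in names(x$entries)) {
    cat(sprintf("  %s  %s\n", id, x$entries[[id]]$description$title %||% ""))
  }
  invisible(x)
}
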