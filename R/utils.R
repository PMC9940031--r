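#' @keywords internal
"_PACKAGE"

# Pattern for valid model ids: a 5-digit zero-padded ordinal followed by one or
# more underscore-separated uppercase alphanumeric tokens, e.g. 00001_DCGAN_MMG.
MODEL_ID_PATTERN <- "^[0-9]{5}(_[A-Z0-9]+)+$"

is_valid_model_id <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && grepl(MODEL_ID_PATTERN, x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_synthzoo <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "synthzoo_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

warn_synthzoo <- function(msg, class) {
  warning(structure(
    class = c(class, "synthzoo_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Deterministic RNG scope: run `expr` under a given seed without disturbing the
# caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(expr)
}

ensure_dir <- function(path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE, showWarnings = FALSE)
  invisible(path)
}
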